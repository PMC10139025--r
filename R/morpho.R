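# Cauchy-Crofton perimeter estimator: over the four digital line families
# (0, 45, 90, 135 degrees) count boundary crossings, scale each count by
# its line spacing (1 for axis directions, 1/sqrt(2) for diagonals), and
# average; the perimeter is pi/2 times that average. Far less rasterization
# bias than counting boundary pixels, which matters because circularity
# enters a hard classification threshold. Assumes the object does not touch
# the image frame (the precondition and the generator keep it away).
.crofton_perimeter <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  n0   <- sum(m[, -1] != m[, -nc])      # crossings along rows
  n90  <- sum(m[-1, ] != m[-nr, ])      # crossings along columns
  n45  <- sum(m[-1, -1] != m[-nr, -nc]) # crossings along one diagonal
  n135 <- sum(m[-1, -nc] != m[-nr, -1]) # and the other
  (pi / 2) * mean(c(n0, n90, n45 / sqrt(2), n135 / sqrt(2)))
}

# second-moment ellipse of a pixel set: centroid, axis lengths (semi-axes),
# orientation (radians, direction of the major axis)
.mask_moments <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  cx <- mean(x); cy <- mean(y)
  cxx <- mean((x - cx)^2); cyy <- mean((y - cy)^2)
  cxy <- mean((x - cx) * (y - cy))
  cov <- matrix(c(cxx, cxy, cxy, cyy), 2)
  eg <- eigen(cov, symmetric = TRUE)
  list(centroid = c(x = cx, y = cy),
       eigenvalues = eg$values,
       major_dir = eg$vectors[, 1],
       semi_major = 2 * sqrt(eg$values[1]),
       semi_minor = 2 * sqrt(eg$values[2]))
}

#' Morphometry and morphology class of one cell mask
#'
#' Computes area, Crofton-estimated perimeter, best-fit-ellipse axes (from
#' second image moments), circularity = 4 pi area / perimeter^2 (capped at
#' 1.05 for digitization) and aspect ratio = major/minor axis, then applies
#' the morphology rule: a cell is fibroblastic-like only when circularity
#' < 0.5 AND aspect ratio > 2.5; otherwise epithelial-like.
#'
#' @param mask binary matrix (0/1 or logical); exactly one connected
#'   component of at least 100 px, not line-like
#' @return list: \code{area}, \code{perimeter}, \code{major_axis},
#'   \code{minor_axis} (full axes, px), \code{circularity},
#'   \code{aspect_ratio}, \code{morph_class}
#'   ("fibroblastic"/"epithelial")
#' @examples
#' img <- simulateCellImage(axes = c(40, 40), size = c(128, 128), seed = 1)
#' shapeMetrics(img$mask)$morph_class
#' @export
shapeMetrics <- function(mask) {
  m <- (mask != 0) * 1
  lab <- EBImage::bwlabel(m)
  ncomp <- max(lab)
  if (ncomp != 1)
    stop(sprintf("mask must contain exactly one connected component (found %d)",
                 ncomp))
  area <- sum(m)
  if (area < 100)
    stop("component too small: at least 100 px required")
  mom <- .mask_moments(m)
  if (mom$semi_minor < 1)
    stop("degenerate (line-like) mask")
  per <- .crofton_perimeter(m)
  circ <- min(4 * pi * area / per^2, 1.05)
  ar <- mom$semi_major / mom$semi_minor
  list(area = area,
       perimeter = per,
       major_axis = 2 * mom$semi_major,
       minor_axis = 2 * mom$semi_minor,
       circularity = circ,
       aspect_ratio = ar,
       morph_class = if (circ < 0.5 && ar > 2.5) "fibroblastic"
                     else "epithelial")
}

#' 10-bin fluorescence profile along the centroid crossline
#'
#' The crossline is the major axis of the mask's best-fit ellipse through
#' its centroid, clipped to the mask. It is divided into 10 equal-length
#' segments; bin i is the mean pixel intensity of the in-mask pixels lying
#' within \code{halfWidth} px of the line and projecting onto segment i.
#' Bins 4-7 are the cell center, bins 1-3 and 8-10 the periphery.
#'
#' @param image numeric matrix of intensities, same shape as \code{mask}
#' @param mask binary matrix, one component
#' @param halfWidth band half-width around the crossline, px (default 3)
#' @return object of class \code{IntensityProfile}: list with \code{bins}
#'   (10 mean intensities), \code{counts} (pixels per bin),
#'   \code{center_bins}, \code{periphery_bins}, \code{length_px}
#' @export
crosslineProfile <- function(image, mask, halfWidth = 3) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have the same shape")
  m <- mask != 0
  mom <- .mask_moments(m)
  u <- mom$major_dir        # (x, y) unit vector
  # fix the arbitrary eigenvector sign so that profiles of mirrored images
  # reverse deterministically
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  cx <- mom$centroid["x"]; cy <- mom$centroid["y"]
  idx <- which(m, arr.ind = TRUE)
  dx <- idx[, 2] - cx; dy <- idx[, 1] - cy
  t <- dx * u[1] + dy * u[2]
  perp <- abs(-dx * u[2] + dy * u[1])
  near <- perp <= halfWidth
  if (!any(near)) stop("crossline shorter than 10 px")
  # in-mask extent of the crossline, taken from the band pixels themselves
  tmin <- min(t[near]); tmax <- max(t[near])
  if (tmax - tmin < 10)
    stop("crossline shorter than 10 px")
  band <- near & t >= tmin & t <= tmax
  tb <- t[band]
  vals <- image[m][band]
  bin <- pmin(pmax(ceiling((tb - tmin) / (tmax - tmin) * 10), 1), 10)
  bins <- vapply(1:10, function(b) {
    v <- vals[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  counts <- vapply(1:10, function(b) sum(bin == b), 0L)
  structure(list(bins = bins, counts = counts,
                 center_bins = 4:7, periphery_bins = c(1:3, 8:10),
                 length_px = tmax - tmin,
                 t_range = c(tmin, tmax),
                 centroid = c(cx, cy),
                 direction = u),
            class = "IntensityProfile")
}

#' Average intensity profiles across cells
#'
#' @param profiles list of \code{IntensityProfile} objects (one per cell)
#' @param conf confidence level for the per-bin interval (default 0.95)
#' @return list: \code{bins} (mean of per-cell bin values), \code{ci95}
#'   (2 x 10 matrix, lower/upper), \code{n_cells}
#' @export
averageProfiles <- function(profiles, conf = 0.95) {
  mat <- do.call(rbind, lapply(profiles, `[[`, "bins"))
  n <- nrow(mat)
  mu <- colMeans(mat, na.rm = TRUE)
  se <- apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(n)
  q <- stats::qt(1 - (1 - conf) / 2, df = max(n - 1, 1))
  list(bins = mu,
       ci95 = rbind(lower = mu - q * se, upper = mu + q * se),
       n_cells = n)
}

#' Intracellular / background uptake ratio
#'
#' Ratio of the mean pixel intensity (m.p.i.) inside the cell mask to the
#' m.p.i. of the background region. When no background mask is supplied, a
#' 10 px frame along the image border is used.
#'
#' @param image numeric intensity matrix
#' @param cellMask binary matrix marking the cell
#' @param backgroundMask optional binary matrix, disjoint from
#'   \code{cellMask}
#' @param border frame width for the default background, px
#' @return list: \code{cell_mpi}, \code{background_mpi}, \code{ratio}
#' @export
uptakeRatio <- function(image, cellMask, backgroundMask = NULL,
                        border = 10) {
  cm <- cellMask != 0
  if (is.null(backgroundMask)) {
    bg <- matrix(FALSE, nrow(image), ncol(image))
    bg[c(seq_len(border), nrow(image) - seq_len(border) + 1), ] <- TRUE
    bg[, c(seq_len(border), ncol(image) - seq_len(border) + 1)] <- TRUE
    bg <- bg & !cm
  } else {
    bg <- backgroundMask != 0
  }
  if (any(cm & bg)) stop("cell and background masks must be disjoint")
  if (!any(cm) || !any(bg)) stop("both masks must be non-empty")
  cmpi <- mean(image[cm])
  bmpi <- mean(image[bg])
  if (bmpi <= 0) stop("background mean pixel intensity must be positive")
  list(cell_mpi = cmpi, background_mpi = bmpi, ratio = cmpi / bmpi)
}
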