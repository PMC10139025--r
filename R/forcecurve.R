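#' Baseline-correct an approach curve
#'
#' Fits a straight line to the pre-contact region (by default the first 30%
#' of points, which must lie before contact) and subtracts it from the whole
#' deflection channel, removing constant offset and optical-lever tilt.
#'
#' @param curve a \linkS4class{ForceCurve}
#' @param fraction fraction of leading points taken as baseline (default
#'   0.3); must contain at least 20 points
#' @return the corrected \linkS4class{ForceCurve}
#' @export
correctBaseline <- function(curve, fraction = 0.3) {
  n <- length(curve@z)
  nb <- floor(n * fraction)
  if (nb < 20)
    stop("processing error: fewer than 20 points available for the baseline")
  idx <- seq_len(nb)
  fit <- stats::lm.fit(cbind(1, curve@z[idx]), curve@deflection[idx])
  curve@deflection <- curve@deflection -
    (fit$coefficients[1] + fit$coefficients[2] * curve@z)
  curve
}

# Piecewise objective: flat zero baseline before zc, Hertz-shaped deflection
# after. Returns total RSS in deflection units (nm^2); the Hertz amplitude is
# profiled out in closed form. Inf when the post segment is unusable.
.contact_rss <- function(z, d, zc) {
  post <- z > zc
  rss <- sum(d[!post]^2)
  if (sum(post) < 5) return(Inf)
  delta <- pmax((z[post] - zc) * 1000 - d[post], 0)
  x <- delta^1.5
  sxx <- sum(x * x)
  if (sxx <= 0) return(Inf)
  a <- sum(d[post] * x) / sxx
  if (a <= 0) return(Inf)
  rss + sum((d[post] - a * x)^2)
}

#' Detect the tip-sample contact point
#'
#' Scans candidate contact positions and, at each, scores a piecewise model
#' (flat baseline before, Hertz-shaped deflection after, amplitude profiled
#' out by least squares); the candidate minimizing total RSS wins. A coarse
#' grid scan is followed by a fine scan and, by default, a continuous 1-D
#' refinement between the bracketing grid points. The curve must already be
#' baseline-corrected.
#'
#' @param curve a baseline-corrected \linkS4class{ForceCurve}
#' @param minPre minimum number of points required before a candidate
#' @param refine logical; continuous refinement of the grid optimum
#' @return contact position, um
#' @export
detectContactPoint <- function(curve, minPre = 20, refine = TRUE) {
  z <- curve@z
  d <- curve@deflection
  n <- length(z)
  cand <- seq(minPre, n - 10)
  if (length(cand) < 3)
    stop("processing error: too few points to search for contact")
  rss0 <- sum(d^2)
  # coarse scan every 4th candidate, then fine scan around the best
  coarse <- cand[seq(1, length(cand), by = 4)]
  r_coarse <- vapply(coarse, function(i) .contact_rss(z, d, z[i]), 0)
  if (!any(is.finite(r_coarse)))
    stop("no-contact error: no candidate contact point is admissible")
  best <- coarse[which.min(r_coarse)]
  fine <- cand[cand >= best - 4 & cand <= best + 4]
  r_fine <- vapply(fine, function(i) .contact_rss(z, d, z[i]), 0)
  i_best <- fine[which.min(r_fine)]
  best_rss <- min(r_fine)
  if (!is.finite(best_rss) || best_rss >= rss0 * (1 - 1e-9))
    stop("no-contact error: flat baseline explains the curve")
  zc <- z[i_best]
  if (refine) {
    lo <- z[max(i_best - 1, 1)]
    hi <- z[min(i_best + 1, n)]
    opt <- stats::optimize(function(v) .contact_rss(z, d, v),
                           interval = c(lo, hi), tol = 1e-7)
    if (is.finite(opt$objective) && opt$objective <= best_rss) zc <- opt$minimum
  }
  unname(zc)
}

#' Fit the Hertz spherical-contact model to one curve
#'
#' With the contact point fixed, force F = k d and indentation
#' delta = (z - contactZ) - d are formed and E is estimated by least squares
#' on F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2), restricted to
#' 0 < delta <= \code{maxIndent}. The model is linear in E, so the estimate
#' is closed-form. Curves whose usable indentation never reaches
#' \code{minIndent} are flagged non-converged (quality filter).
#'
#' @param curve a baseline-corrected \linkS4class{ForceCurve}
#' @param contactZ contact position, um (from
#'   \code{\link{detectContactPoint}})
#' @param maxIndent fit-window cap, nm (default 500)
#' @param minIndent minimum usable indentation for a trustworthy fit, nm
#' @return a \linkS4class{HertzFit}
#' @export
fitHertz <- function(curve, contactZ, maxIndent = 500, minIndent = 100) {
  probe <- curve@probe
  post <- curve@z > contactZ
  delta <- (curve@z[post] - contactZ) * 1000 - curve@deflection[post]
  force <- probe@springConstant * curve@deflection[post]
  win <- delta > 0 & delta <= maxIndent
  if (sum(win) < 10)
    stop("fit error: fewer than 10 points in the indentation window")
  delta <- delta[win]; force <- force[win]
  x <- delta^1.5
  slope <- sum(force * x) / sum(x * x)
  E <- slope * (1 - probe@poissonRatio^2) /
    ((4 / 3) * sqrt(probe@beadRadius) * 10^-4.5)
  rss <- sum((force - slope * x)^2)
  deep_enough <- max(delta) >= minIndent
  new("HertzFit",
      contactZ = contactZ,
      youngsModulus = E,
      maxIndentationUsed = max(delta),
      rss = rss,
      nFitPoints = sum(win),
      converged = is.finite(E) && E > 0 && deep_enough)
}

#' Aggregate per-curve moduli into one cell stiffness
#'
#' @param fits list of \linkS4class{HertzFit}; at least 5 must be converged
#' @param cellId identifier
#' @param method "mean" (default, as stiffness is conventionally reported)
#'   or "median"
#' @return a \linkS4class{CellStiffness}
#' @export
aggregateCell <- function(fits, cellId = "cell",
                          method = c("mean", "median")) {
  method <- match.arg(method)
  ok <- vapply(fits, function(f) isTRUE(f@converged), TRUE)
  if (sum(ok) < 5)
    stop(sprintf("cell %s excluded: only %d converged curves (need 5)",
                 cellId, sum(ok)))
  E <- vapply(fits[ok], youngsModulus, 0)
  agg <- if (method == "mean") mean(E) else stats::median(E)
  new("CellStiffness", cellId = as.character(cellId), perCurveModuli = E,
      aggregateModulus = agg, nCurves = length(E))
}

#' Full per-cell pipeline: baseline, contact, Hertz fit, aggregation
#'
#' @param curves list of \linkS4class{ForceCurve} from one cell
#' @param cellId identifier (default taken from the first curve)
#' @param maxIndent,minIndent Hertz window, nm
#' @param method aggregation method, see \code{\link{aggregateCell}}
#' @return a \linkS4class{CellStiffness}
#' @export
fitCellStiffness <- function(curves, cellId = NULL, maxIndent = 500,
                             minIndent = 100, method = "mean") {
  if (is.null(cellId)) cellId <- curves[[1]]@cellId
  fits <- lapply(curves, function(cv) {
    tryCatch({
      cv <- correctBaseline(cv)
      zc <- detectContactPoint(cv)
      fitHertz(cv, zc, maxIndent = maxIndent, minIndent = minIndent)
    }, error = function(e)
      new("HertzFit", contactZ = NA_real_, youngsModulus = NA_real_,
          maxIndentationUsed = 0, rss = NA_real_, nFitPoints = 0L,
          converged = FALSE))
  })
  aggregateCell(fits, cellId = cellId, method = method)
}

#' Analyze a simulated (or loaded) population of cells
#'
#' Runs \code{\link{fitCellStiffness}} on every cell and collects the
#' results into a \linkS4class{StiffnessPopulation} plus a per-cell summary
#' table. Cells failing the quality filter (< 5 converged curves) are
#' excluded and listed with the reason.
#'
#' @param cells list as returned by \code{\link{simulatePopulation}}, or any
#'   list whose elements have \code{$cellId} and \code{$curves}
#' @param lineId,condition identifiers for the resulting population
#' @param ... passed to \code{\link{fitCellStiffness}}
#' @return list: \code{population} (\linkS4class{StiffnessPopulation}),
#'   \code{cells} (data.frame: cell_id, n_curves, E_kPa_mean, E_kPa_sd),
#'   \code{excluded} (character, reasons)
#' @examples
#' pop <- simulatePopulation(0.4, 0.1, nCells = 3, seed = 7)
#' res <- analyzePopulation(pop, lineId = "demo")
#' res$cells
#' @export
analyzePopulation <- function(cells, lineId = "line",
                              condition = "control", ...) {
  excluded <- character()
  rows <- list()
  for (cell in cells) {
    cs <- tryCatch(fitCellStiffness(cell$curves, cellId = cell$cellId, ...),
                   error = function(e) conditionMessage(e))
    if (is.character(cs)) {
      excluded <- c(excluded, cs)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cs@cellId, n_curves = cs@nCurves,
        E_kPa_mean = cs@aggregateModulus,
        E_kPa_sd = stats::sd(cs@perCurveModuli))
    }
  }
  if (!length(rows))
    stop("no cell passed the quality filter")
  tab <- do.call(rbind, rows)
  list(
    population = new("StiffnessPopulation", lineId = lineId,
                     condition = condition, cellModuli = tab$E_kPa_mean),
    cells = tab,
    excluded = excluded)
}
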