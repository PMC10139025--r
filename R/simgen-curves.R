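# Deflection of the lever in contact: solves k d = F_hertz(travel - d) for
# each post-contact point by vectorized bisection on [0, travel].
# travel in nm, returns d in nm.
.contact_deflection <- function(travel_nm, modulus_kPa, probe) {
  k <- probe@springConstant
  lo <- rep(0, length(travel_nm))
  hi <- travel_nm
  for (i in seq_len(70)) {
    mid <- (lo + hi) / 2
    g <- k * mid - hertzForce(travel_nm - mid, modulus_kPa, probe)
    up <- g < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Simulate one AFM approach curve
#'
#' Forward model of a Hertzian microindentation record: zero (optionally
#' tilted) baseline before the contact point, then the deflection implied by
#' the spherical-contact force balance k d = F(delta) with
#' delta = (z - contactZ) - d, plus additive Gaussian deflection noise.
#' The approach stops where the force exceeds the probe's trigger setpoint,
#' as on the instrument.
#'
#' @param trueModulus ground-truth Young's modulus, kPa (> 0)
#' @param contactZ piezo position of tip-sample contact, um; must lie inside
#'   \code{zRange}
#' @param zRange approach range, um, length-2 increasing
#' @param nPoints number of samples along z (>= 50)
#' @param noiseSd deflection noise SD, nm (instrument noise; default 2)
#' @param baselineSlope residual optical-lever tilt, nm per um of z
#' @param probe a \linkS4class{ProbeSpec}
#' @param cellId,curveId identifiers stored on the curve
#' @param seed RNG seed (NULL: use current stream)
#' @return a \linkS4class{ForceCurve} carrying \code{groundTruth}
#' @examples
#' fc <- simulateForceCurve(0.5, contactZ = 2, noiseSd = 0)
#' fc
#' @export
simulateForceCurve <- function(trueModulus, contactZ = 2, zRange = c(0, 4),
                               nPoints = 400, noiseSd = 2,
                               baselineSlope = 0, probe = probeSpec(),
                               cellId = "cell", curveId = "curve",
                               seed = NULL) {
  stopifnot(trueModulus > 0, nPoints >= 50, noiseSd >= 0,
            length(zRange) == 2, zRange[1] < zRange[2])
  if (contactZ <= zRange[1] || contactZ >= zRange[2])
    stop("invalid config: zRange must contain contactZ")
  with_seed(seed, {
    z <- seq(zRange[1], zRange[2], length.out = nPoints)
    d <- baselineSlope * (z - z[1])
    post <- z > contactZ
    travel <- (z[post] - contactZ) * 1000            # nm
    d[post] <- d[post] + .contact_deflection(travel, trueModulus, probe)
    # stop at the force trigger, as the instrument would
    force <- probe@springConstant * (d - baselineSlope * (z - z[1]))
    over <- which(force > probe@triggerForce)
    if (length(over)) {
      keep <- seq_len(over[1])
      z <- z[keep]; d <- d[keep]
    }
    if (noiseSd > 0) d <- d + stats::rnorm(length(d), 0, noiseSd)
    new("ForceCurve", z = z, deflection = d, probe = probe,
        cellId = as.character(cellId), curveId = as.character(curveId),
        groundTruth = list(trueModulus = trueModulus, contactZ = contactZ))
  })
}

# One draw from a positive-truncated Gaussian mixture; component index
# attached as an attribute. Errors after 100 rejection attempts.
.rtrunc_mixture <- function(means, sds, weights) {
  for (attempt in seq_len(100)) {
    comp <- sample.int(length(weights), 1, prob = weights)
    x <- stats::rnorm(1, means[comp], sds[comp])
    if (x > 0) return(structure(x, component = comp))
  }
  stop("generation error: no positive modulus draw in 100 attempts")
}

#' Simulate a single-cell stiffness population with its force curves
#'
#' Draws each cell's true modulus from a positive-truncated Gaussian mixture
#' (one or two components), then generates \code{curvesPerCell} approach
#' curves per cell whose per-curve true moduli scatter around the cell value
#' with a configurable within-cell coefficient of variation. Contact points
#' are drawn uniformly within \code{contactRange} so that detection is
#' exercised. Ground-truth labels (cell modulus, mixture component) are
#' retained.
#'
#' @param means,sds component means and SDs, kPa (1 or 2 components)
#' @param weights component weights summing to 1 (default equal)
#' @param nCells number of cells
#' @param curvesPerCell curves per cell (>= 5, as in the measurement
#'   protocol)
#' @param withinCellCV within-cell curve-to-curve modulus CV (default 0.1)
#' @param contactRange um interval the per-curve contact point is drawn from
#' @param probe a \linkS4class{ProbeSpec}
#' @param noiseSd,baselineSlope,zRange,nPoints passed to
#'   \code{\link{simulateForceCurve}}
#' @param seed RNG seed
#' @return list with one element per cell: \code{cellId},
#'   \code{trueModulus} (kPa), \code{component}, and \code{curves} (list of
#'   \linkS4class{ForceCurve})
#' @examples
#' pop <- simulatePopulation(0.28, 0.12, nCells = 3, seed = 1)
#' pop[[1]]$trueModulus
#' @export
simulatePopulation <- function(means, sds, weights = NULL, nCells = 100,
                               curvesPerCell = 5, withinCellCV = 0.1,
                               contactRange = c(1.5, 2.5),
                               probe = probeSpec(), noiseSd = 2,
                               baselineSlope = 0, zRange = c(0, 4),
                               nPoints = 400, seed = NULL) {
  k <- length(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(k %in% 1:2, length(sds) == k, length(weights) == k,
            all(means > 0), all(sds >= 0), curvesPerCell >= 5,
            abs(sum(weights) - 1) < 1e-9)
  with_seed(seed, {
    lapply(seq_len(nCells), function(i) {
      E_cell <- .rtrunc_mixture(means, sds, weights)
      curves <- lapply(seq_len(curvesPerCell), function(j) {
        E_curve <- E_cell * max(1 + stats::rnorm(1, 0, withinCellCV), 0.05)
        cz <- stats::runif(1, contactRange[1], contactRange[2])
        simulateForceCurve(E_curve, contactZ = cz, zRange = zRange,
                           nPoints = nPoints, noiseSd = noiseSd,
                           baselineSlope = baselineSlope, probe = probe,
                           cellId = sprintf("cell%03d", i),
                           curveId = sprintf("curve%d", j))
      })
      list(cellId = sprintf("cell%03d", i),
           trueModulus = as.numeric(E_cell),
           component = attr(E_cell, "component"),
           curves = curves)
    })
  })
}
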