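#' Simulate an MTT viability table
#'
#' Four-parameter logistic viability at the given concentrations, plus
#' additive Gaussian noise, clipped to [0, 110] percent (readout can
#' slightly exceed the untreated reference). The default concentration grid
#' is the seven-step treatment series 1-2-4-10-20-40-80 uM.
#'
#' @param ic50 ground-truth IC50, uM (> 0)
#' @param hill Hill slope (> 0; viability decreases with concentration)
#' @param concentrations uM, positive
#' @param top,bottom asymptotes, percent (default 100 / 0)
#' @param noiseSd additive noise SD, viability points
#' @param seed RNG seed
#' @return data.frame: concentration_uM, viability_pct
#' @examples
#' simulateViability(30.58, noiseSd = 0)
#' @export
simulateViability <- function(ic50, hill = 1,
                              concentrations = c(1, 2, 4, 10, 20, 40, 80),
                              top = 100, bottom = 0, noiseSd = 0,
                              seed = NULL) {
  stopifnot(ic50 > 0, hill > 0, all(concentrations > 0), bottom <= top)
  with_seed(seed, {
    v <- bottom + (top - bottom) / (1 + (concentrations / ic50)^hill)
    if (noiseSd > 0) v <- v + stats::rnorm(length(v), 0, noiseSd)
    data.frame(concentration_uM = concentrations,
               viability_pct = pmin(pmax(v, 0), 110))
  })
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on log-concentration:
#' v(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill). By default both
#' asymptotes are fixed (top = 100, bottom = 0), the convention for
#' viability normalized to the untreated control: when the tested
#' concentrations do not reach the lower plateau, a free bottom is weakly
#' identified and its non-negativity constraint drags the IC50 estimate
#' down by 10-15% at realistic noise. \code{freeBottom = TRUE} frees the
#' bottom within \code{bottomRange}; \code{freeTop = TRUE} additionally
#' frees the top.
#'
#' @param table data.frame with columns concentration_uM and viability_pct
#'   (replicate-averaged), or a numeric concentration vector when
#'   \code{viability} is given
#' @param viability optional viability vector (percent) matching
#'   \code{table} as concentrations
#' @param topFixed top asymptote when not free (default 100)
#' @param bottomFixed bottom asymptote when not free (default 0)
#' @param freeBottom free the bottom within \code{bottomRange}
#' @param bottomRange allowed bottom interval when free (default c(0, 50))
#' @param freeTop free the top (implies a free bottom)
#' @return a \linkS4class{DoseResponseFit}
#' @examples
#' fitIC50(simulateViability(55, noiseSd = 0))
#' @export
fitIC50 <- function(table, viability = NULL, topFixed = 100,
                    bottomFixed = 0, freeBottom = FALSE,
                    bottomRange = c(0, 50), freeTop = FALSE) {
  if (!is.null(viability)) {
    conc <- as.numeric(table); v <- as.numeric(viability)
  } else {
    conc <- table$concentration_uM; v <- table$viability_pct
  }
  if (length(conc) < 5)
    stop("fit error: at least 5 concentrations are required")
  if (any(conc <= 0) || is.unsorted(conc, strictly = TRUE))
    stop("concentrations must be positive and strictly increasing")
  if (any(!is.finite(v))) stop("viability must be finite")
  if (diff(range(v)) < 1)
    stop("no-IC50 error: viability is flat across the tested range")
  if (stats::cor(log(conc), v) >= 0)
    stop("no-IC50 error: viability does not decrease with concentration")
  lc <- log10(conc)
  lic0 <- stats::approx(v, lc, xout = mean(range(v)), ties = mean)$y
  if (!is.finite(lic0)) lic0 <- mean(lc)
  if (freeTop) freeBottom <- TRUE
  b0 <- min(max(min(v), bottomRange[1]), bottomRange[2])
  # parameters: (log10 IC50, hill[, bottom[, top]]); bounded
  # Levenberg-Marquardt on the residual function directly
  model <- function(p) {
    bot <- if (length(p) >= 3) p[3] else bottomFixed
    top <- if (length(p) >= 4) p[4] else topFixed
    bot + (top - bot) / (1 + 10^((lc - p[1]) * p[2]))
  }
  start <- c(lic0, 1)
  lower <- c(min(lc) - 3, 0.05)
  upper <- c(max(lc) + 3, 20)
  if (freeBottom) {
    start <- c(start, b0)
    lower <- c(lower, bottomRange[1]); upper <- c(upper, bottomRange[2])
  }
  if (freeTop) {
    start <- c(start, max(v))
    lower <- c(lower, 50); upper <- c(upper, 150)
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) v - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  new("DoseResponseFit",
      ic50 = 10^p[1],
      hill = p[2],
      top = if (freeTop) p[4] else topFixed,
      bottom = if (freeBottom) p[3] else bottomFixed,
      rss = fit$deviance,
      converged = fit$info %in% 1:4)
}

#' Stiffness-response metric (CV%) of a treatment
#'
#' The treatment-response metric comparing a treated stiffness population
#' with its control. Two readings are computed and stored; \code{mode}
#' selects which one populates \code{cv_percent}:
#' \itemize{
#'   \item \code{"relative-change"} (default): 100 * (mean_E_control -
#'     mean_E_treated) / mean_E_control — the extent to which treatment
#'     softened the cells;
#'   \item \code{"treated-dispersion"}: 100 * sd / mean of the treated
#'     per-cell moduli — a literal coefficient of variation.
#' }
#'
#' @param control,treated \linkS4class{StiffnessPopulation} objects
#' @param mode which reading is reported as \code{cv_percent}
#' @return list: \code{line_id}, \code{mean_E_control},
#'   \code{mean_E_treated} (kPa), \code{cv_percent} (selected mode, may be
#'   negative in relative-change mode when treatment stiffened the cells),
#'   \code{cv_mode}, \code{relative_change_pct},
#'   \code{treated_dispersion_pct}
#' @export
cvPercent <- function(control, treated,
                      mode = c("relative-change", "treated-dispersion")) {
  mode <- match.arg(mode)
  if (!nCells(control) || !nCells(treated))
    stop("both populations must be non-empty")
  mc <- mean(cellModuli(control))
  mt <- mean(cellModuli(treated))
  rel <- 100 * (mc - mt) / mc
  disp <- 100 * stats::sd(cellModuli(treated)) / mt
  list(line_id = control@lineId,
       mean_E_control = mc, mean_E_treated = mt,
       cv_percent = if (mode == "relative-change") rel else disp,
       cv_mode = mode,
       relative_change_pct = rel,
       treated_dispersion_pct = disp)
}

#' Per-subpopulation stiffness response
#'
#' For a line that is bimodal before and after treatment, the relative
#' change of each rank-matched component mean, softer and stiffer reported
#' separately (percent).
#'
#' @param control,treated Bimodal \linkS4class{MixtureFit} objects
#' @return named numeric: \code{softer}, \code{stiffer} (percent change of
#'   the component mean, positive = softened)
#' @export
perComponentCV <- function(control, treated) {
  if (classification(control) != "Bimodal" ||
      classification(treated) != "Bimodal")
    stop("perComponentCV needs Bimodal fits for both conditions")
  c(softer = 100 * (control@means[1] - treated@means[1]) / control@means[1],
    stiffer = 100 * (control@means[2] - treated@means[2]) / control@means[2])
}
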