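# ---- 1-D Gaussian mixture machinery (authored here; the deconvolution of
# stiffness histograms into subpopulations is the core of the package) ----

.gauss_loglik <- function(x, means, sds, weights) {
  dens <- vapply(seq_along(means),
                 function(j) weights[j] * stats::dnorm(x, means[j], sds[j]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

# EM for k = 2 from one starting partition; sds floored to avoid the
# degenerate spike solution.
.em_2comp <- function(x, means0, sds0, weights0, maxIter = 500,
                      tol = 1e-9) {
  n <- length(x)
  sd_floor <- max(stats::sd(x), 1e-12) * 1e-3
  means <- means0; sds <- pmax(sds0, sd_floor); weights <- weights0
  ll_old <- -Inf
  for (it in seq_len(maxIter)) {
    # E step
    r1 <- weights[1] * stats::dnorm(x, means[1], sds[1])
    r2 <- weights[2] * stats::dnorm(x, means[2], sds[2])
    tot <- pmax(r1 + r2, 1e-300)
    g <- r1 / tot
    # M step
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    means <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sds <- pmax(c(sqrt(sum(g * (x - means[1])^2) / n1),
                  sqrt(sum((1 - g) * (x - means[2])^2) / n2)), sd_floor)
    weights <- c(n1, n2) / n
    ll <- .gauss_loglik(x, means, sds, weights)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(means)
  list(means = means[ord], sds = sds[ord], weights = weights[ord],
       logLik = .gauss_loglik(x, means, sds, weights))
}

# Least-squares Gaussian peak fit on a Freedman-Diaconis histogram
# (figure-style deconvolution); returns parameters on the same scale as the
# likelihood route plus the histogram RSS.
.peakfit_hist <- function(x, k, start) {
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids; counts <- h$counts
  bw <- mids[2] - mids[1]
  n <- length(x)
  df <- data.frame(mids = mids, counts = counts)
  if (k == 1) {
    fit <- minpack.lm::nlsLM(
      counts ~ n * bw * w1 * stats::dnorm(mids, m1, s1),
      data = df, start = list(w1 = 1, m1 = start$means[1],
                              s1 = start$sds[1]),
      lower = c(1e-3, min(x), 1e-6 + diff(range(x)) * 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    w <- 1
    means <- cf[["m1"]]; sds <- cf[["s1"]]
  } else {
    fit <- minpack.lm::nlsLM(
      counts ~ n * bw * (w1 * stats::dnorm(mids, m1, s1) +
                           w2 * stats::dnorm(mids, m2, s2)),
      data = df,
      start = list(w1 = start$weights[1], m1 = start$means[1],
                   s1 = start$sds[1], w2 = start$weights[2],
                   m2 = start$means[2], s2 = start$sds[2]),
      lower = c(1e-3, min(x), diff(range(x)) * 1e-4,
                1e-3, min(x), diff(range(x)) * 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    w <- c(cf[["w1"]], cf[["w2"]])
    means <- c(cf[["m1"]], cf[["m2"]]); sds <- c(cf[["s1"]], cf[["s2"]])
  }
  ord <- order(means)
  list(means = means[ord], sds = sds[ord], weights = (w / sum(w))[ord],
       logLik = NA_real_, rss = sum(stats::resid(fit)^2))
}

#' Fit a k-component Gaussian model to a stiffness distribution
#'
#' Deconvolves the per-cell modulus distribution into k = 1 or 2 Gaussian
#' peaks. The default route is maximum likelihood: for k = 1 the closed-form
#' MLE; for k = 2 an EM algorithm with \code{restarts} starts (one
#' quantile-split start in the k-means spirit plus random partitions) keeping
#' the best likelihood. \code{method = "histogram"} instead least-squares
#' fits Gaussian peaks to a Freedman-Diaconis histogram, mirroring
#' figure-style peak deconvolution; it is offered for fidelity, not as
#' default.
#'
#' @param pop a \linkS4class{StiffnessPopulation} (>= 20 cells) or numeric
#'   vector of moduli
#' @param k 1 or 2 components
#' @param method "mle" (default) or "histogram"
#' @param restarts EM restarts for k = 2
#' @param seed RNG seed for the random restarts (default 0, so fits are
#'   reproducible by default)
#' @return list: \code{means}, \code{sds}, \code{weights} (sorted by mean),
#'   \code{logLik}, \code{bic}, \code{k}; histogram mode adds \code{rss}
#' @export
fitComponents <- function(pop, k, method = c("mle", "histogram"),
                          restarts = 10, seed = 0) {
  method <- match.arg(method)
  x <- if (is(pop, "StiffnessPopulation")) pop@cellModuli else as.numeric(pop)
  if (length(x) < 20)
    stop("insufficient data: distribution fitting needs at least 20 cells")
  stopifnot(k %in% 1:2)
  n <- length(x)
  if (k == 1) {
    fit <- list(means = mean(x), sds = sqrt(sum((x - mean(x))^2) / n),
                weights = 1,
                logLik = .gauss_loglik(x, mean(x),
                                       sqrt(sum((x - mean(x))^2) / n), 1))
    npar <- 2
  } else {
    fit <- with_seed(seed, {
      best <- NULL
      for (r in seq_len(restarts)) {
        if (r == 1) {
          # quantile split start
          grp <- x > stats::median(x)
        } else {
          grp <- sample(c(TRUE, FALSE), n, replace = TRUE)
          if (all(grp) || all(!grp)) grp[1] <- !grp[1]
        }
        m0 <- c(mean(x[!grp]), mean(x[grp]))
        s0 <- c(stats::sd(x[!grp]), stats::sd(x[grp]))
        s0[!is.finite(s0) | s0 <= 0] <- stats::sd(x) / 2
        cand <- tryCatch(
          .em_2comp(x, m0, s0, c(mean(!grp), mean(grp))),
          error = function(e) NULL)
        if (!is.null(cand) && is.finite(cand$logLik) &&
            (is.null(best) || cand$logLik > best$logLik))
          best <- cand
      }
      if (is.null(best)) stop("fit error: EM failed to converge")
      best
    })
    npar <- 5
  }
  if (method == "histogram") {
    hf <- .peakfit_hist(x, k, fit)
    hf$bic <- NA_real_
    hf$k <- k
    hf$mle <- fit
    return(hf)
  }
  fit$bic <- -2 * fit$logLik + npar * log(n)
  fit$k <- k
  fit
}

#' Classify a stiffness distribution as unimodal or bimodal
#'
#' Fits the one- and two-component Gaussian models and labels the population
#' "Bimodal" only when the two-component model earns it: BIC(k=2) must
#' undercut BIC(k=1) by more than \code{bicThreshold}, both component
#' weights must reach \code{minWeight}, and the component means must be
#' separated by more than \code{minSeparation} pooled SDs. The guards
#' prevent heavy tails from being declared a second subpopulation.
#'
#' @param pop a \linkS4class{StiffnessPopulation} or numeric vector (>= 20
#'   values)
#' @param bicThreshold BIC margin required (default 2)
#' @param minWeight minimum weight of each component (default 0.1)
#' @param minSeparation required mean separation in pooled-SD units
#'   (default 1); pooled SD = sqrt(w1 s1^2 + w2 s2^2)
#' @param method,restarts,seed passed to \code{\link{fitComponents}}
#' @return a \linkS4class{MixtureFit}
#' @examples
#' set.seed(1)
#' classifyPattern(c(rnorm(100, 0.3, 0.08), rnorm(100, 0.9, 0.15)))
#' @export
classifyPattern <- function(pop, bicThreshold = 2, minWeight = 0.1,
                            minSeparation = 1, method = "mle",
                            restarts = 10, seed = 0) {
  f1 <- fitComponents(pop, 1, method = "mle", seed = seed)
  f2 <- fitComponents(pop, 2, method = "mle", restarts = restarts,
                      seed = seed)
  pooled <- sqrt(sum(f2$weights * f2$sds^2))
  bimodal <- (f2$bic < f1$bic - bicThreshold) &&
    all(f2$weights >= minWeight) &&
    (diff(f2$means) > minSeparation * pooled)
  scores <- list(logLik1 = f1$logLik, logLik2 = f2$logLik,
                 bic1 = f1$bic, bic2 = f2$bic)
  if (bimodal) {
    new("MixtureFit", nComponents = 2L, means = f2$means, sds = f2$sds,
        weights = f2$weights, modelScores = scores,
        classification = "Bimodal", softerIndex = 1L, stifferIndex = 2L)
  } else {
    new("MixtureFit", nComponents = 1L, means = f1$means, sds = f1$sds,
        weights = 1, modelScores = scores, classification = "Gaussian",
        softerIndex = NA_integer_, stifferIndex = NA_integer_)
  }
}

#' Stiffness ratio of the two subpopulations
#'
#' @param fit a Bimodal \linkS4class{MixtureFit}
#' @return mean of the stiffer component divided by mean of the softer one
#'   (> 1 by construction)
#' @export
peakRatio <- function(fit) {
  if (classification(fit) != "Bimodal")
    stop("peakRatio is defined only for Bimodal fits")
  fit@means[fit@stifferIndex] / fit@means[fit@softerIndex]
}

#' Compare the deconvolution of two conditions of one line
#'
#' Reports the label transition (e.g. treatment collapsing a bimodal
#' distribution to a Gaussian) and, when both fits have the same number of
#' components, the rank-matched per-component parameter changes.
#'
#' @param control,treated \linkS4class{MixtureFit} objects
#' @return list: \code{transition} (string, e.g. "Bimodal->Gaussian"),
#'   \code{labelChanged}, and \code{componentChanges} (data.frame of mean/sd
#'   deltas, treated minus control, when components can be rank-matched;
#'   NULL otherwise)
#' @export
compareConditions <- function(control, treated) {
  trans <- paste0(classification(control), "->", classification(treated))
  changed <- classification(control) != classification(treated)
  changes <- NULL
  if (!changed) {
    changes <- data.frame(
      component = seq_len(control@nComponents),
      delta_mean_kPa = treated@means - control@means,
      delta_sd_kPa = treated@sds - control@sds,
      delta_weight = treated@weights - control@weights)
  }
  list(transition = trans, labelChanged = changed,
       componentChanges = changes)
}
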