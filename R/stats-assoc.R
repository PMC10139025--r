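#' Ordinary least-squares association between two line-level variables
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return list of class \code{AssociationResult}: \code{kind}
#'   ("regression"), \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{statistic} (t of the slope), \code{p_value} (two-sided, slope),
#'   \code{n}
#' @examples
#' t1 <- ovarianLineTable()
#' linearAssociation(t1$mean_E_kPa, t1$ic50_uM)$r_squared
#' @export
linearAssociation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(kind = "regression",
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 statistic = sm$coefficients[2, "t value"],
                 p_value = sm$coefficients[2, "Pr(>|t|)"],
                 n = length(x)),
            class = "AssociationResult")
}

#' Compare a numeric variable between groups
#'
#' Two groups: t-test (parametric) or Wilcoxon rank-sum; more than two:
#' one-way ANOVA or Kruskal-Wallis. In \code{"auto"} mode the parametric
#' branch is taken when the Shapiro-Wilk test on the within-group-centered
#' residuals does not reject normality at alpha = 0.05.
#'
#' @param values numeric vector
#' @param labels group labels, same length; >= 2 groups of >= 2 values
#' @param method "auto", "t", "ranksum", "kruskal" or "anova"
#' @return list of class \code{AssociationResult}: \code{kind}
#'   ("group-comparison"), \code{statistic}, \code{p_value},
#'   \code{group_means} (named), \code{method_used}, \code{n}
#' @examples
#' t1 <- ovarianLineTable()
#' compareGroups(t1$invasiveness, t1$pattern)$group_means
#' @export
compareGroups <- function(values, labels,
                          method = c("auto", "t", "ranksum", "kruskal",
                                     "anova")) {
  method <- match.arg(method)
  labels <- as.factor(labels)
  stopifnot(length(values) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2 || any(counts < 2))
    stop("need at least 2 groups with at least 2 values each")
  two <- length(counts) == 2
  if (method == "auto") {
    resid <- values - stats::ave(values, labels)
    normal <- tryCatch(stats::shapiro.test(resid)$p.value >= 0.05,
                       error = function(e) FALSE)
    method <- if (two) (if (normal) "t" else "ranksum")
              else (if (normal) "anova" else "kruskal")
  }
  if (!two && method %in% c("t", "ranksum"))
    method <- if (method == "t") "anova" else "kruskal"
  res <- switch(method,
    t = {
      ht <- stats::t.test(values ~ labels)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    ranksum = {
      ht <- stats::wilcox.test(values ~ labels, exact = FALSE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    anova = {
      ht <- summary(stats::aov(values ~ labels))[[1]]
      list(statistic = ht[["F value"]][1], p_value = ht[["Pr(>F)"]][1])
    },
    kruskal = {
      ht <- stats::kruskal.test(values, labels)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    })
  structure(list(kind = "group-comparison",
                 statistic = res$statistic,
                 p_value = res$p_value,
                 group_means = c(tapply(values, labels, mean)),
                 method_used = method,
                 n = length(values)),
            class = "AssociationResult")
}

#' Median dichotomization into high/low groups
#'
#' Cutoff is the sample median (mean of the central pair for even n).
#' Values above the cutoff are "high"; values at or below it (including
#' ties at the cutoff) are "low".
#'
#' @param values numeric, n >= 2
#' @return list: \code{labels} (character, "high"/"low"), \code{cutoff}
#' @examples
#' dichotomize(ovarianLineTable()$ic50_uM)$cutoff
#' @export
dichotomize <- function(values) {
  stopifnot(length(values) >= 2)
  cutoff <- stats::median(values)
  list(labels = ifelse(values > cutoff, "high", "low"), cutoff = cutoff)
}

#' Pearson chi-squared association of two categorical variables
#'
#' Uncorrected Pearson statistic on a contingency table (no Yates
#' continuity correction, so the statistic matches the textbook formula).
#'
#' @param table matrix of non-negative integer counts (typically 2 x 2)
#' @return list of class \code{AssociationResult}: \code{kind}
#'   ("chi-squared"), \code{statistic}, \code{p_value}, \code{n}
#' @examples
#' associationChisq(matrix(c(10, 0, 0, 10), 2))$statistic
#' @export
associationChisq <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0),
            all(table == round(table)))
  if (all(stats::chisq.test(table, correct = FALSE)$expected > 0)) {
    ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  } else stop("table has empty margins")
  structure(list(kind = "chi-squared",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 n = sum(table)),
            class = "AssociationResult")
}

#' Normalize expression against housekeeping genes
#'
#' Divides every gene's value by the geometric mean of the three
#' housekeeping genes in the same sample, so housekeeping-stable signal
#' cancels out sample-depth and efficiency differences.
#'
#' @param se a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   linear-scale assay (first assay used)
#' @param housekeeping gene ids used as the reference (default HPRT1, HMBS,
#'   PPIB); all must be present with positive values in every sample
#' @return the SummarizedExperiment with a new assay \code{normalized}
#' @export
normalizeExpression <- function(se,
                                housekeeping = c("HPRT1", "HMBS", "PPIB")) {
  expr <- SummarizedExperiment::assay(se, 1)
  missing <- setdiff(housekeeping, rownames(expr))
  if (length(missing))
    stop("housekeeping genes missing from the table: ",
         paste(missing, collapse = ", "))
  hk <- expr[housekeeping, , drop = FALSE]
  if (any(!is.finite(hk)) || any(hk <= 0))
    stop("housekeeping genes must have positive finite values everywhere")
  ref <- apply(hk, 2, geomMean)
  SummarizedExperiment::assay(se, "normalized") <-
    sweep(expr, 2, ref, "/")
  se
}

#' Per-gene differential expression between two groups
#'
#' Welch t-test per gene on log2 normalized values, with the log2 fold
#' change of group means. Multiple-testing correction is off by default
#' (uncorrected alpha = 0.05 flags), with Benjamini-Hochberg available.
#'
#' @param se a SummarizedExperiment containing a \code{normalized} assay
#'   (see \code{\link{normalizeExpression}}) or, failing that, the first
#'   assay; \code{colData} must carry the group column
#' @param group name of the colData column with exactly two levels
#'   (default "group")
#' @param correction "none" (default) or "BH"
#' @param alpha significance level for the flag
#' @return data.frame: \code{gene}, \code{log2fc} (second level over
#'   first), \code{p_value}, \code{significant}
#' @export
diffExpression <- function(se, group = "group", correction = c("none", "BH"),
                           alpha = 0.05) {
  correction <- match.arg(correction)
  g <- factor(SummarizedExperiment::colData(se)[[group]])
  if (nlevels(g) != 2) stop("the group column must have exactly two levels")
  if (any(table(g) < 2)) stop("need at least 2 samples per group")
  a <- if ("normalized" %in% SummarizedExperiment::assayNames(se))
    SummarizedExperiment::assay(se, "normalized")
  else SummarizedExperiment::assay(se, 1)
  lx <- log2(a)
  i1 <- g == levels(g)[1]
  res <- t(apply(lx, 1, function(v) {
    ht <- tryCatch(stats::t.test(v[!i1], v[i1]),
                   error = function(e) list(p.value = NA_real_))
    c(log2fc = mean(v[!i1]) - mean(v[i1]), p_value = ht$p.value)
  }))
  p <- if (correction == "BH") stats::p.adjust(res[, "p_value"], "BH")
       else res[, "p_value"]
  data.frame(gene = rownames(lx),
             log2fc = unname(res[, "log2fc"]),
             p_value = unname(res[, "p_value"]),
             significant = !is.na(p) & p < alpha,
             row.names = NULL)
}
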