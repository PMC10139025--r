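#' Published per-line summary of the eight ovarian cancer lines
#'
#' The packaged line-level summary table of the eight epithelial ovarian
#' cancer cell lines: morphology class, mean and SD of the cellular Young's
#' modulus (kPa), stiffness-distribution pattern (Gaussian/Bimodal),
#' invasiveness score (mean invading cells per 10x optical field), 2c IC50
#' (uM) and the CV% stiffness-response metric after 20 uM 2c treatment.
#' All line-level association statistics in this package are recomputed
#' from this table rather than hard-coded.
#'
#' @return data.frame with columns \code{line_id}, \code{morphology},
#'   \code{mean_E_kPa}, \code{sd_E_kPa}, \code{pattern},
#'   \code{invasiveness}, \code{invasiveness_sd}, \code{ic50_uM},
#'   \code{cv_percent}
#' @examples
#' head(ovarianLineTable())
#' @export
ovarianLineTable <- function() {
  path <- system.file("extdata", "ovarian_lines_summary.csv",
                      package = "cellmech", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute the line-level association statistics
#'
#' Runs the association layer on a line summary table: regressions of
#' invasiveness and IC50 on mean stiffness, group comparisons of
#' invasiveness and CV% by distribution pattern, and the median
#' dichotomization cutoffs of IC50 and CV%.
#'
#' @param table a line summary data.frame as returned by
#'   \code{\link{ovarianLineTable}}
#' @return list: \code{r2_invasiveness_vs_E}, \code{r2_ic50_vs_E}
#'   (\code{AssociationResult}s), \code{invasiveness_by_pattern},
#'   \code{cv_by_pattern} (group comparisons),
#'   \code{ic50_cutoff}, \code{cv_cutoff} (medians)
#' @examples
#' s <- associationSummary(ovarianLineTable())
#' round(s$r2_ic50_vs_E$r_squared, 2)
#' @export
associationSummary <- function(table = ovarianLineTable()) {
  list(
    r2_invasiveness_vs_E = linearAssociation(table$mean_E_kPa,
                                             table$invasiveness),
    r2_ic50_vs_E = linearAssociation(table$mean_E_kPa, table$ic50_uM),
    invasiveness_by_pattern = compareGroups(table$invasiveness,
                                            table$pattern),
    cv_by_pattern = compareGroups(table$cv_percent, table$pattern),
    ic50_cutoff = dichotomize(table$ic50_uM)$cutoff,
    cv_cutoff = dichotomize(table$cv_percent)$cutoff)
}
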