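#' Simulate a two-group expression table with housekeeping genes
#'
#' Log-normal expression for \code{nGenes} genes over two groups of
#' \code{nReps} samples each. Selected genes carry configured between-group
#' fold changes; the three housekeeping genes HPRT1, HMBS and PPIB are
#' always present and carry no effect, so normalizing against them leaves
#' true effects intact. Returned as a
#' \link[SummarizedExperiment]{SummarizedExperiment} with the group label in
#' \code{colData}.
#'
#' @param nGenes number of non-housekeeping genes (>= 1)
#' @param groupEffects named numeric vector of fold changes (group B over
#'   group A) for a subset of genes ("gene001", ...); unnamed genes have
#'   fold change 1
#' @param nReps samples per group
#' @param baseMeanLog2 mean log2 expression of a gene (drawn per gene
#'   around this level)
#' @param sdLog2 biological + technical log2 SD within a group
#' @param seed RNG seed
#' @return a SummarizedExperiment; assay "expr" (linear scale), rownames =
#'   gene ids (housekeeping first), colData column \code{group} ("A"/"B")
#'   and \code{rowData} column \code{true_fold_change}
#' @examples
#' se <- simulateExpression(20, c(gene001 = 4), nReps = 4, seed = 1)
#' SummarizedExperiment::colData(se)$group
#' @export
simulateExpression <- function(nGenes = 80, groupEffects = NULL, nReps = 3,
                               baseMeanLog2 = 8, sdLog2 = 0.5,
                               seed = NULL) {
  stopifnot(nGenes >= 1, nReps >= 2)
  hk <- c("HPRT1", "HMBS", "PPIB")
  genes <- c(hk, sprintf("gene%03d", seq_len(nGenes)))
  fold <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(groupEffects)) {
    unknown <- setdiff(names(groupEffects), genes)
    if (length(unknown))
      stop("groupEffects names not in the gene set: ",
           paste(unknown, collapse = ", "))
    if (any(names(groupEffects) %in% hk))
      stop("housekeeping genes cannot carry effects")
    fold[names(groupEffects)] <- groupEffects
  }
  with_seed(seed, {
    base <- stats::rnorm(length(genes), baseMeanLog2, 1.5)
    group <- rep(c("A", "B"), each = nReps)
    lmat <- sapply(seq_along(group), function(j) {
      mu <- base + if (group[j] == "B") log2(fold) else 0
      stats::rnorm(length(genes), mu, sdLog2)
    })
    expr <- 2^lmat
    dimnames(expr) <- list(genes,
                           sprintf("%s%d", group, rep(seq_len(nReps), 2)))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = expr),
      colData = S4Vectors::DataFrame(group = group,
                                     row.names = colnames(expr)),
      rowData = S4Vectors::DataFrame(true_fold_change = unname(fold),
                                     housekeeping = genes %in% hk,
                                     row.names = genes))
  })
}
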