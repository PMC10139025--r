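#' @rdname accessors
#' @export
setGeneric("youngsModulus", function(x) standardGeneric("youngsModulus"))

#' @rdname accessors
#' @export
setGeneric("contactZ", function(x) standardGeneric("contactZ"))

#' @rdname accessors
#' @export
setGeneric("cellModuli", function(x) standardGeneric("cellModuli"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname accessors
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))

#' Accessors for cellmech S4 objects
#'
#' Small read-only accessors: \code{youngsModulus()} and \code{contactZ()}
#' on a \linkS4class{HertzFit} or \linkS4class{CellStiffness};
#' \code{cellModuli()} and \code{nCells()} on a
#' \linkS4class{StiffnessPopulation}; \code{classification()} and
#' \code{componentTable()} on a \linkS4class{MixtureFit}; \code{ic50()} on a
#' \linkS4class{DoseResponseFit}.
#'
#' @param x the object
#' @return the slot value; \code{componentTable()} returns a data.frame with
#'   one row per mixture component (mean, sd, weight, kPa scale)
#' @name accessors
NULL

#' @rdname accessors
setMethod("youngsModulus", "HertzFit", function(x) x@youngsModulus)

#' @rdname accessors
setMethod("youngsModulus", "CellStiffness", function(x) x@aggregateModulus)

#' @rdname accessors
setMethod("contactZ", "HertzFit", function(x) x@contactZ)

#' @rdname accessors
setMethod("cellModuli", "StiffnessPopulation", function(x) x@cellModuli)

#' @rdname accessors
setMethod("nCells", "StiffnessPopulation", function(x) length(x@cellModuli))

#' @rdname accessors
setMethod("classification", "MixtureFit", function(x) x@classification)

#' @rdname accessors
setMethod("componentTable", "MixtureFit", function(x) {
  data.frame(
    component = seq_len(x@nComponents),
    mean_kPa  = x@means,
    sd_kPa    = x@sds,
    weight    = x@weights
  )
})

#' @rdname accessors
setMethod("ic50", "DoseResponseFit", function(x) x@ic50)

setMethod("show", "ProbeSpec", function(object) {
  cat("ProbeSpec: k =", object@springConstant, "N/m, R =", object@beadRadius,
      "um, nu =", object@poissonRatio, ", trigger =", object@triggerForce,
      "nN\n")
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve %s/%s: %d points, z in [%.3f, %.3f] um\n",
              object@cellId, object@curveId, length(object@z),
              min(object@z), max(object@z)))
  if (length(object@groundTruth))
    cat(sprintf("  ground truth: E = %.4g kPa, contact at %.4g um\n",
                object@groundTruth$trueModulus, object@groundTruth$contactZ))
})

setMethod("show", "HertzFit", function(object) {
  cat(sprintf(
    "HertzFit: E = %.4g kPa, contact at %.4g um, %d points (<= %.0f nm), %s\n",
    object@youngsModulus, object@contactZ, object@nFitPoints,
    object@maxIndentationUsed,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "CellStiffness", function(object) {
  cat(sprintf("CellStiffness %s: E = %.4g kPa (%d curves, range %.4g-%.4g)\n",
              object@cellId, object@aggregateModulus, object@nCurves,
              min(object@perCurveModuli), max(object@perCurveModuli)))
})

setMethod("show", "StiffnessPopulation", function(object) {
  cat(sprintf(
    "StiffnessPopulation %s (%s): %d cells, mean E = %.3g kPa, sd = %.3g\n",
    object@lineId, object@condition, length(object@cellModuli),
    mean(object@cellModuli), stats::sd(object@cellModuli)))
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: %s (%d component%s)\n", object@classification,
              object@nComponents, if (object@nComponents > 1) "s" else ""))
  tab <- componentTable(object)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  component %d: %.3g +/- %.3g kPa, weight %.2f\n",
                i, tab$mean_kPa[i], tab$sd_kPa[i], tab$weight[i]))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "DoseResponseFit: IC50 = %.4g uM, hill = %.3g, top = %.3g, bottom = %.3g (%s)\n",
    object@ic50, object@hill, object@top, object@bottom,
    if (object@converged) "converged" else "NOT converged"))
})
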