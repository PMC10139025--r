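#' @import methods
NULL

#' AFM probe description
#'
#' Metadata of the cantilever/bead assembly used for microindentation. The
#' spring constant converts optical-lever deflection (nm) into force (nN);
#' the bead radius enters the Hertz spherical-contact model. Defaults follow
#' a soft triangular lever (0.08 N/m) functionalized with a 4.5 um silica
#' bead, indenting with a 2 nN deflection trigger.
#'
#' @slot springConstant cantilever spring constant, N/m; must lie in (0, 10]
#' @slot beadRadius colloidal-probe bead radius, um
#' @slot poissonRatio Poisson ratio of the sample; 0.5 treats the cell as
#'   incompressible
#' @slot triggerForce force setpoint at which the approach stops, nN
#' @slot indentVelocity approach velocity, um/s (metadata only; the static
#'   Hertz fit does not use it)
#' @export
setClass("ProbeSpec",
  representation(
    springConstant = "numeric",
    beadRadius     = "numeric",
    poissonRatio   = "numeric",
    triggerForce   = "numeric",
    indentVelocity = "numeric"
  ),
  prototype(
    springConstant = 0.08,
    beadRadius     = 2.25,
    poissonRatio   = 0.5,
    triggerForce   = 2,
    indentVelocity = 2
  )
)

setValidity("ProbeSpec", function(object) {
  msg <- character()
  if (length(object@springConstant) != 1 || is.na(object@springConstant) ||
      object@springConstant <= 0 || object@springConstant > 10)
    msg <- c(msg, "springConstant must be a single value in (0, 10] N/m")
  if (length(object@beadRadius) != 1 || is.na(object@beadRadius) ||
      object@beadRadius <= 0)
    msg <- c(msg, "beadRadius must be positive (um)")
  if (length(object@poissonRatio) != 1 || is.na(object@poissonRatio) ||
      object@poissonRatio < 0 || object@poissonRatio > 0.5)
    msg <- c(msg, "poissonRatio must lie in [0, 0.5]")
  if (length(object@triggerForce) != 1 || is.na(object@triggerForce) ||
      object@triggerForce <= 0)
    msg <- c(msg, "triggerForce must be positive (nN)")
  if (length(msg)) msg else TRUE
})

#' One AFM approach curve
#'
#' A single force-displacement record: piezo extension (um, strictly
#' increasing along the approach) against cantilever deflection (nm), plus
#' the probe metadata needed to convert deflection to force. Simulated
#' curves carry their generating truth (modulus, contact point) in
#' \code{groundTruth} so that recovery can be tested.
#'
#' @slot z piezo extension, um; strictly monotone increasing; >= 50 points
#' @slot deflection cantilever deflection, nm; same length as \code{z}
#' @slot probe a \linkS4class{ProbeSpec}
#' @slot cellId,curveId identifiers
#' @slot groundTruth list; for synthetic curves, \code{trueModulus} (kPa) and
#'   \code{contactZ} (um); empty for measured data
#' @export
setClass("ForceCurve",
  representation(
    z           = "numeric",
    deflection  = "numeric",
    probe       = "ProbeSpec",
    cellId      = "character",
    curveId     = "character",
    groundTruth = "list"
  ),
  prototype(cellId = "cell", curveId = "curve", groundTruth = list())
)

setValidity("ForceCurve", function(object) {
  msg <- character()
  n <- length(object@z)
  if (n < 50)
    msg <- c(msg, "curve must have at least 50 points")
  if (length(object@deflection) != n)
    msg <- c(msg, "z and deflection must have equal length")
  if (n >= 2 && any(diff(object@z) <= 0))
    msg <- c(msg, "z must be strictly increasing (approach direction)")
  if (length(msg)) msg else TRUE
})

#' Hertz-model fit of one curve
#'
#' Result of fitting F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2) to the
#' post-contact segment of a force curve, with the indentation window capped
#' (default 500 nm).
#'
#' @slot contactZ estimated contact point, um
#' @slot youngsModulus apparent Young's modulus E, kPa
#' @slot maxIndentationUsed deepest indentation entering the fit, nm
#' @slot rss residual sum of squares of force, nN^2
#' @slot nFitPoints number of points in the fit window
#' @slot converged logical; FALSE when the fit failed or E <= 0
#' @export
setClass("HertzFit",
  representation(
    contactZ           = "numeric",
    youngsModulus      = "numeric",
    maxIndentationUsed = "numeric",
    rss                = "numeric",
    nFitPoints         = "integer",
    converged          = "logical"
  )
)

setValidity("HertzFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged) && object@youngsModulus <= 0)
    msg <- c(msg, "converged fit must have positive youngsModulus")
  if (length(msg)) msg else TRUE
})

#' Per-cell stiffness
#'
#' Aggregate of at least five converged per-curve moduli measured at
#' different peri-nuclear locations of one cell.
#'
#' @slot cellId identifier
#' @slot perCurveModuli per-curve Young's moduli, kPa
#' @slot aggregateModulus the cell's stiffness (mean or median of the
#'   per-curve values), kPa
#' @slot nCurves number of curves aggregated
#' @export
setClass("CellStiffness",
  representation(
    cellId           = "character",
    perCurveModuli   = "numeric",
    aggregateModulus = "numeric",
    nCurves          = "integer"
  )
)

setValidity("CellStiffness", function(object) {
  msg <- character()
  if (object@nCurves < 5)
    msg <- c(msg, "a cell needs at least 5 curves")
  if (length(object@perCurveModuli) != object@nCurves)
    msg <- c(msg, "nCurves must match length(perCurveModuli)")
  rng <- range(object@perCurveModuli)
  if (object@aggregateModulus < rng[1] - 1e-12 ||
      object@aggregateModulus > rng[2] + 1e-12)
    msg <- c(msg, "aggregate must lie within the per-curve range")
  if (length(msg)) msg else TRUE
})

#' Single-cell stiffness distribution of one line/condition
#'
#' @slot lineId cell-line identifier
#' @slot condition "control" or "treated"
#' @slot cellModuli per-cell Young's moduli, kPa; all positive
#' @export
setClass("StiffnessPopulation",
  representation(
    lineId     = "character",
    condition  = "character",
    cellModuli = "numeric"
  ),
  prototype(lineId = "line", condition = "control")
)

setValidity("StiffnessPopulation", function(object) {
  msg <- character()
  if (!object@condition %in% c("control", "treated"))
    msg <- c(msg, "condition must be 'control' or 'treated'")
  if (any(!is.finite(object@cellModuli)) || any(object@cellModuli <= 0))
    msg <- c(msg, "all cell moduli must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Gaussian deconvolution of a stiffness distribution
#'
#' One- or two-component Gaussian model of the per-cell modulus
#' distribution, with the model-selection scores and the resulting
#' unimodal/bimodal label. Components are stored sorted by mean, so the
#' softer subpopulation is always component 1.
#'
#' @slot nComponents 1 or 2
#' @slot means,sds,weights component parameters, kPa / kPa / probabilities
#' @slot modelScores named list of per-model goodness values (log-likelihood
#'   and BIC for k = 1 and k = 2)
#' @slot classification "Gaussian" (unimodal) or "Bimodal"
#' @slot softerIndex,stifferIndex component indices (2-component fits)
#' @export
setClass("MixtureFit",
  representation(
    nComponents    = "integer",
    means          = "numeric",
    sds            = "numeric",
    weights        = "numeric",
    modelScores    = "list",
    classification = "character",
    softerIndex    = "integer",
    stifferIndex   = "integer"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  k <- object@nComponents
  if (!k %in% c(1L, 2L))
    msg <- c(msg, "nComponents must be 1 or 2")
  if (length(object@means) != k || length(object@sds) != k ||
      length(object@weights) != k)
    msg <- c(msg, "means, sds, weights must each have nComponents entries")
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1 (tolerance 1e-9)")
  if (is.unsorted(object@means))
    msg <- c(msg, "components must be sorted by ascending mean")
  if (!identical(object@classification == "Bimodal", k == 2L))
    msg <- c(msg, "classification must be 'Bimodal' iff nComponents == 2")
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' @slot ic50 half-maximal inhibitory concentration, uM
#' @slot hill Hill slope (dimensionless)
#' @slot top,bottom upper/lower viability asymptotes, percent
#' @slot rss residual sum of squares (viability percent^2)
#' @slot converged logical
#' @export
setClass("DoseResponseFit",
  representation(
    ic50      = "numeric",
    hill      = "numeric",
    top       = "numeric",
    bottom    = "numeric",
    rss       = "numeric",
    converged = "logical"
  )
)

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged) && object@ic50 <= 0)
    msg <- c(msg, "ic50 must be positive")
  if (object@bottom > object@top)
    msg <- c(msg, "bottom must not exceed top")
  if (length(msg)) msg else TRUE
})
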