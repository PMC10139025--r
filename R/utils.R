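# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

geomMean <- function(x) exp(mean(log(x)))

#' Build an AFM probe specification
#'
#' @param springConstant cantilever spring constant, N/m
#' @param beadRadius bead radius, um (default 2.25, i.e. a 4.5 um bead)
#' @param poissonRatio sample Poisson ratio (default 0.5, incompressible)
#' @param triggerForce approach force setpoint, nN
#' @param indentVelocity approach speed, um/s (metadata)
#' @return a \linkS4class{ProbeSpec}
#' @examples
#' probeSpec()
#' probeSpec(springConstant = 0.32)
#' @export
probeSpec <- function(springConstant = 0.08, beadRadius = 2.25,
                      poissonRatio = 0.5, triggerForce = 2,
                      indentVelocity = 2) {
  new("ProbeSpec",
      springConstant = springConstant, beadRadius = beadRadius,
      poissonRatio = poissonRatio, triggerForce = triggerForce,
      indentVelocity = indentVelocity)
}

#' Hertz spherical-contact force
#'
#' Forward model F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2) for a rigid
#' sphere indenting an elastic half-space, in the package's working units.
#'
#' @param indentation_nm indentation depth delta, nm (vectorized; values
#'   <= 0 give zero force)
#' @param modulus_kPa Young's modulus E, kPa
#' @param probe a \linkS4class{ProbeSpec} (bead radius, Poisson ratio)
#' @return force in nN
#' @examples
#' hertzForce(500, 1, probeSpec())  # ~0.943 nN
#' @export
hertzForce <- function(indentation_nm, modulus_kPa, probe = probeSpec()) {
  d <- pmax(indentation_nm, 0)
  # unit bridge: kPa * sqrt(um) * nm^(3/2) -> nN carries a factor 10^-4.5
  (4 / 3) * (modulus_kPa / (1 - probe@poissonRatio^2)) *
    sqrt(probe@beadRadius) * d^1.5 * 10^-4.5
}
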