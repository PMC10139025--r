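# Shared fixture builders; everything is generated in code.

# Closed-form Hertz force, written out independently of the package's
# helper so the forward model has an external oracle:
# F[nN] = (4/3) * (E*1e3 / (1-nu^2)) * sqrt(R*1e-6) * (d*1e-9)^1.5 / 1e-9
oracle_hertz_nN <- function(delta_nm, E_kPa, R_um = 2.25, nu = 0.5) {
  (4 / 3) * (E_kPa * 1e3 / (1 - nu^2)) * sqrt(R_um * 1e-6) *
    (delta_nm * 1e-9)^1.5 / 1e-9
}

# a clean noiseless curve for unit tests
clean_curve <- function(E = 0.5, contactZ = 2, ...) {
  simulateForceCurve(E, contactZ = contactZ, noiseSd = 0, ...)
}

# positive-truncated normal sample (rejection), for population fixtures
rtnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
  x
}

stiff_pop <- function(moduli, lineId = "line", condition = "control") {
  new("StiffnessPopulation", lineId = lineId, condition = condition,
      cellModuli = moduli)
}
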