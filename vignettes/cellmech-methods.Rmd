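---
title: "Methods: single-cell nanomechanics with cellmech"
author: "cellmech authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell nanomechanics with cellmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
```

# Scope

cellmech analyzes AFM colloidal-probe microindentation experiments on
living cells, of the kind used to characterize the mechanical
heterogeneity of cancer cell lines: per-curve Young's moduli from
force-displacement records, per-cell aggregates, Gaussian deconvolution of
the per-cell stiffness distribution into subpopulations, drug-response
metrics (IC50 from MTT viability, CV% stiffness response), morphology
classification from cell masks, fluorescence crossline profiles and a
line-level association layer. A synthetic-data generator produces every
input with known ground truth, so the whole inverse pipeline is testable
end to end.

Working units are fixed throughout: kPa for moduli, nN for force, nm for
deflection and indentation, um for piezo position. Readers convert at the
boundaries.

# The contact model and the inverse pipeline

A rigid sphere of radius $R$ pressed a depth $\delta$ into an elastic
half-space of Young's modulus $E$ and Poisson ratio $\nu$ experiences the
Hertz force

$$F \;=\; \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}.$$

On the instrument one records piezo extension $z$ and cantilever
deflection $d$; force is $F = k\,d$ with spring constant $k$, and the
indentation is the piezo travel not taken up by the lever,
$\delta = (z - z_c) - d$, measured from the contact point $z_c$. The
inverse pipeline is three separable stages:

1. **Baseline correction** (`correctBaseline`): a straight line fitted to
   the leading 30% of points (which must lie before contact; at least 20
   points) is subtracted, removing offset and optical-lever tilt.
2. **Contact-point detection** (`detectContactPoint`): candidate contact
   positions are scored by the total RSS of a piecewise model — flat zero
   baseline before, Hertz-shaped deflection after, with the Hertz
   amplitude profiled out in closed form. A coarse scan (every 4th
   candidate) is refined by a fine scan and then by a continuous 1-D
   `optimize` between the bracketing grid points. If no candidate with a
   positive Hertz amplitude beats the flat-only model, a no-contact error
   is raised.
3. **Hertz fit** (`fitHertz`): with $z_c$ fixed, the model is linear in
   $E$, so the least-squares estimate on $F$ versus $\delta^{3/2}$ is
   closed-form. The fit window is $0 < \delta \le 500$ nm, the depth range
   in which cells of different heights still respond linearly; curves
   whose usable indentation never reaches 100 nm are flagged
   non-converged (quality filter).

Per-cell stiffness (`aggregateCell`, `fitCellStiffness`) is the
arithmetic mean of at least five converged per-curve moduli, matching the
measurement protocol of five or more indentations per cell in the
peri-nuclear region; the median is available as an option. Cells with
fewer than five converged curves are excluded with a logged reason.

A joint refinement of $(E, z_c)$ after detection was considered and is
deliberately not the default: the separable stages are individually
testable, and on noiseless curves the staged estimator already recovers
$(E, z_c)$ to better than 0.1% relative error.

## Probe defaults

* Spring constant $k = 0.08$ N/m. The triangular levers used for cell
  indentation carry nominal constants of 0.32 and 0.08 N/m; the softer
  lever is the appropriate choice for kPa-scale samples because the
  deflection signal per unit force is four times larger.
* Bead radius $R = 2.25$ um (a 4.5 um silica microsphere).
* Poisson ratio $\nu = 0.5$ (incompressible cell).
* Trigger force 2 nN: the simulated approach stops where the force
  exceeds the setpoint, as the instrument does to avoid cell damage. For
  a 1 kPa cell the force at 500 nm indentation is only 0.94 nN, so the
  full fit window remains available for all but the stiffest cells.
* Indentation velocity (2 um/s) is metadata only; the static Hertz fit
  does not use it.

## What the curve generator emulates — and what it does not

`simulateForceCurve` solves the force balance $k d = F(\delta)$ exactly
(vectorized bisection) on a uniform $z$ grid, adds an optional baseline
tilt and white Gaussian deflection noise, and truncates at the trigger.
Defaults: 400 points over 4 um (10 nm spacing), noise SD 2 nm. The noise
level of a deflection channel is instrument-dependent and is exposed as a
parameter; 2 nm is deliberately pessimistic. The generator does **not**
simulate viscoelastic relaxation, hydrodynamic drag, cantilever dynamics,
thermal drift, or bottom-effect stiffening on thin samples — so passing
recovery tests demonstrate correctness of the inverse machinery under the
Hertzian model, not robustness to every artifact of real data.

`simulatePopulation` draws each cell's modulus from a one- or
two-component Gaussian mixture truncated to positive values (rejection
sampling, error after 100 attempts); Gaussian components match the
peak-deconvolution view of stiffness histograms. Within a cell,
curve-to-curve moduli scatter with a 10% CV by default (cells are
mechanically inhomogeneous across indentation sites; the value is a
package choice, configurable, as published tables do not report
intra-cell spread).

Two statistical consequences of these prescribed conditions are worth
recording. First, positive truncation raises the expected sample mean
slightly (about +1% when the mean sits 2.3 SDs above zero). Second, cells
drawn in the far-soft tail (below roughly 0.1 kPa) produce deflections
comparable to the 2 nm noise floor; some of their curves fail detection
or converge to non-positive moduli, the five-converged-curves rule then
excludes the cell, and the surviving sample is slightly stiff-biased
(about +2-3% for a 0.28 +/- 0.12 kPa population, negligible for stiffer
lines). This mirrors the physical reality that unmeasurably soft cells do
not contribute to AFM summary statistics. With 100 cells the standard
error of a grand mean is ~4% of its value, so recovery checks in the test
suite average three fixed-seed runs to separate this sampling scatter
from bias.

Contact-detection precision at 2 nm noise is limited by the information
density near the contact point: median absolute error is ~75 nm at the
default 10 nm grid and ~35 nm at 3-4 nm grids typical of instrument
acquisition rates (kHz sampling at 2 um/s). The detection property test
therefore uses 1200-point records and states so.

# Deconvolution of stiffness distributions

`fitComponents` fits $k = 1$ or $2$ Gaussian components to the per-cell
moduli of a line (at least 20 cells). The default route is maximum
likelihood: closed form for $k=1$; for $k=2$ an EM algorithm with 10
restarts (one median-split start plus random partitions), SDs floored at
$10^{-3}$ of the sample SD to exclude the degenerate spike solution. A
histogram mode (`method = "histogram"`, Freedman-Diaconis bins,
least-squares Gaussian peaks via Levenberg-Marquardt) mirrors
figure-style peak deconvolution and is offered for fidelity, not as
default.

`classifyPattern` labels a distribution **Bimodal** only when the
two-component model earns it:

* $\mathrm{BIC}_2 < \mathrm{BIC}_1 - 2$ (positive evidence, not a tie);
* both weights $\ge 0.1$ (a "subpopulation" below 10% of cells is noise);
* mean separation larger than one pooled SD,
  $\sqrt{w_1\sigma_1^2 + w_2\sigma_2^2}$ (guards against heavy tails
  masquerading as a second peak).

The published analyses name only "peak deconvolution" for this step; the
selection rule is this package's documented choice. Under it, simulated
unimodal populations of 100 cells are mislabeled in about 1% of seeds and
3:1-separated equal mixtures are detected in ~100%, comfortably inside
the 10%/90% targets the test suite asserts. The label is invariant under
sample permutation and under unit rescaling (kPa to Pa), because BIC
differences, weights and separation-in-SD-units are all scale-free.
Components are reported sorted by mean, so "softer" is always component
1; `peakRatio` returns stiffer/softer mean. Log-transforming moduli
before fitting is available but off by default (published fits are on the
linear scale).

# Dose-response and stiffness-response metrics

`fitIC50` fits the four-parameter logistic
$v(c) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1+(c/\mathrm{IC50})^h)$
by bounded Levenberg-Marquardt on $\log_{10} c$. Defaults fix top = 100
and bottom = 0, the convention for viability normalized to an untreated
control. The choice is deliberate: on the seven-concentration design
(1-80 uM), compounds with IC50 in the upper half of the range never reach
their lower plateau, a free bottom is then weakly identified, and its
non-negativity constraint drags the IC50 estimate down by 10-15% at
realistic noise (5 viability points SD). With both asymptotes fixed the
median bias is below 3% for every IC50 in the published range, and
noiseless tables refit exactly. The free-bottom (bounded to [0, 50]) and
free-top variants remain available for data where a resistant fraction is
real. Monotone-increasing or flat viability raises a no-IC50 error rather
than returning a meaningless extrapolation.

The stiffness-response metric CV% (`cvPercent`) is computed in two
readings, both stored: the default **relative change**
$100\,(\bar E_{\mathrm{ctrl}} - \bar E_{\mathrm{treat}})/\bar E_{\mathrm{ctrl}}$
— chosen because the published usage describes the *extent* to which
treatment changed stiffness — and the literal **treated dispersion**
$100\,s/\bar E$ of the treated per-cell moduli. Which reading populates
the reported value is a switch, and analyses that dichotomize CV% log a
note when the two rankings disagree. `perComponentCV` applies the
relative-change reading to rank-matched mixture components of bimodal
lines. CV% is computed on per-cell aggregates, not per-curve moduli.

# Morphometry and fluorescence profiles

`shapeMetrics` computes, from a single-component binary mask (>= 100 px,
not line-like): area; perimeter by a four-direction Cauchy-Crofton
estimator (boundary crossings of the 0/45/90/135-degree digital line
families, spacing-weighted and averaged, times $\pi/2$) — chosen because
naive boundary-pixel counting biases circularity well below 1 for a
perfect disk; circularity $4\pi A/P^2$, capped at 1.05 to absorb residual
digitization; and aspect ratio from the second-moment best-fit ellipse.
The morphology rule is conjunctive: **fibroblastic-like requires both
circularity < 0.5 and aspect ratio > 2.5**, otherwise epithelial-like. A
rasterized disk scores circularity ~0.99; a 5:1 ellipse scores ~0.45
against the Ramanujan-perimeter value 0.447.

`crosslineProfile` takes the major axis of the best-fit ellipse through
the mask centroid as the "centroid crossline" (the published macro's
geometry is not reproducible from its description; the major axis is the
natural reading), clips it to the mask, divides it into 10 equal-length
segments, and averages pixel intensity in a band of half-width 3 px
around each segment — a single-pixel line would be needlessly
noise-sensitive. Bins 4-7 are the cell center, 1-3 and 8-10 the
periphery. Two exact invariants are tested: the count-weighted mean of
the 10 bins equals the band's overall mean pixel intensity
(conservation), and mirroring the image reverses the profile. The
reversal is exact for generic geometry; when the mask is axis-aligned
*and* its centroid falls exactly on the pixel grid, pixels can project
exactly onto bin boundaries and the deterministic tie-break shifts single
pixel columns between adjacent bins — a measure-zero configuration noted
here for users constructing synthetic fixtures. The eigenvector sign of
the axis is normalized (positive x-component) so profile direction is
deterministic.

`uptakeRatio` is the ratio of mean pixel intensity inside the cell mask
to that of a background mask (default: a 10 px frame along the image
border, minus the cell).

# Association layer

Line-level statistics operate on the packaged summary table
(`ovarianLineTable`); every published statistic is recomputed from it at
run time, never hard-coded. `linearAssociation` is OLS with $R^2$ and the
two-sided slope test. `compareGroups` picks t/Wilcoxon (two groups) or
ANOVA/Kruskal-Wallis (more) automatically via Shapiro-Wilk on centered
residuals at $\alpha = 0.05$. `dichotomize` cuts at the sample median,
ties assigned to "low" (a package choice; published analyses do not
state tie handling). `associationChisq` is the uncorrected Pearson
statistic, so hand-computable values (e.g. 20 for a perfectly
discordant 10/10 table) match. Group means are reported unrounded;
consumers round to the integer convention of the published text
(89 vs 29, 32% vs 54%, cutoffs 22 and 42).

Expression tables (SummarizedExperiment) are normalized per sample by the
geometric mean of the three housekeeping genes HPRT1, HMBS and PPIB;
`diffExpression` then runs per-gene Welch t-tests on log2 normalized
values with uncorrected $\alpha = 0.05$ flags by default — mirroring the
multiple-t-test convention of the source analyses — with
Benjamini-Hochberg available. On null simulations the mean significant
fraction sits at ~0.04-0.05; note that the shared housekeeping normalizer
correlates genes within a sample, so the *dispersion* of the per-dataset
false-positive fraction is wider than binomial.

# Problem sizes and seeds in the shipped checks

The test suite and the acceptance script size their simulations as the
package's own choices: population-recovery checks run 100 cells x 5
curves per line and average three fixed seeds; classifier operating
characteristics use 100 seeds at 100 cells; IC50 noise studies use 100
replicate tables; null expression calibration averages 10 datasets of 400
genes. All generators accept a `seed` and are bit-reproducible under it.

# Known limitations

* The Hertz model assumes an elastic half-space: no thin-sample
  correction, no tip-shape calibration, no viscoelasticity. Moduli are
  "apparent" in the usual AFM sense.
* Vendor force-curve formats are out of scope; curves enter as TSV with a
  JSON probe sidecar (`writeForceCurves`/`readForceCurves`).
* The deconvolution considers at most two components; dip tests or k >= 3
  models are possible extensions, not implemented.
* Cell segmentation from raw fluorescence is out of scope: masks are
  inputs (or synthetic).
* Very soft cells near the noise floor are excluded by the quality
  filter rather than imputed; summary statistics inherit the small
  resulting stiff-bias discussed above.
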