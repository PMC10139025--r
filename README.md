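# cellmech

Single-cell nanomechanics from AFM force curves — an R package for
characterizing the mechanical heterogeneity of cultured cells (ovarian
cancer cell lines being the motivating system) and relating it to drug
response and invasiveness.

Atomic force microscopy with a colloidal probe indents a living cell and
records piezo extension *z* against cantilever deflection *d*. With
spring constant *k*, force is *F = k d*, indentation is
*δ = (z − z_c) − d* from the contact point *z_c*, and the apparent
Young's modulus *E* follows from the Hertz spherical-contact model

    F = (4/3) · E/(1 − ν²) · √R · δ^(3/2)

fitted for 0 < δ ≤ 500 nm. Each cell is summarized by the mean modulus of
≥ 5 indentations; each cell line by the distribution of per-cell moduli,
which is deconvolved into one or two Gaussian subpopulations (EM fit,
BIC-guarded selection) to label the line **unimodal (Gaussian)** or
**bimodal** — a marker of intra-line mechanical heterogeneity. Around
this core the package provides 4PL dose–response fits (IC50), the CV%
stiffness-response metric, mask-based morphology classification
(circularity/aspect-ratio rule), 10-bin centroid-crossline fluorescence
profiles and uptake ratios, and the line-level association statistics.
Synthetic generators with known ground truth cover every input: Hertzian
force curves with instrument noise, mixture stiffness populations,
viability tables, elliptical cell images, expression matrices.

## Worked example

Simulate a bimodal cell line, run the full inverse pipeline, and
classify its stiffness distribution:

```r
library(cellmech)

pop <- simulatePopulation(c(0.3, 0.9), c(0.08, 0.15), nCells = 60, seed = 42)
res <- analyzePopulation(pop, lineId = "demo")
res$population
#> StiffnessPopulation demo (control): 60 cells, mean E = 0.588 kPa, sd = 0.32

fit <- classifyPattern(cellModuli(res$population))
fit
#> MixtureFit: Bimodal (2 components)
#>   component 1: 0.316 +/- 0.0705 kPa, weight 0.53
#>   component 2: 0.896 +/- 0.174 kPa, weight 0.47
peakRatio(fit)
#> [1] 2.84
```

The generator planted components at 0.3 and 0.9 kPa with equal weights;
the pipeline (baseline correction → contact detection → Hertz fit →
per-cell aggregation → deconvolution) recovers both means within a few
percent and the 3:1 stiffness ratio between subpopulations.

Dose–response and the line-level associations from the packaged summary
table of the eight ovarian cancer lines:

```r
ic50(fitIC50(simulateViability(30.58, noiseSd = 0)))
#> [1] 30.58

s <- associationSummary(ovarianLineTable())
round(s$r2_ic50_vs_E$r_squared, 2)            # 0.53  (p = 0.04)
round(s$r2_invasiveness_vs_E$r_squared, 2)    # 0.05  (p = 0.61)
round(s$invasiveness_by_pattern$group_means)  # Bimodal 89 vs Gaussian 29
round(s$cv_by_pattern$group_means)            # Bimodal 32 vs Gaussian 54
round(c(s$ic50_cutoff, s$cv_cutoff))          # medians 22 and 42
```

Stiffness correlates with drug resistance (R² = 0.53) but not with
invasiveness overall (R² = 0.05); bimodal lines are more invasive and
dampen their stiffness response to treatment relative to unimodal ones.

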