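test_that("Hertz forward model matches the closed form", {
  p <- probeSpec()
  # hand value: E = 1 kPa, R = 2.25 um, nu = 0.5, delta = 500 nm -> 0.943 nN
  expect_equal(hertzForce(500, 1, p), 0.9428, tolerance = 1e-3)
  expect_equal(hertzForce(500, 1, p), oracle_hertz_nN(500, 1))
  expect_identical(hertzForce(0, 5, p), 0)
  expect_identical(hertzForce(-10, 5, p), 0)  # no contact, no force
  # linear in E
  expect_equal(hertzForce(300, 2, p), 2 * hertzForce(300, 1, p))
})

test_that("simulated curves have a clean pre-contact baseline and honor the trigger", {
  fc <- simulateForceCurve(1, contactZ = 2, noiseSd = 0, baselineSlope = 0)
  pre <- fc@z <= 2
  expect_true(all(fc@deflection[pre] == 0))
  # deflection at max indentation reproduces the closed-form force
  p <- fc@probe
  delta <- (fc@z - 2) * 1000 - fc@deflection
  f_model <- oracle_hertz_nN(max(delta), 1)
  expect_equal(p@springConstant * max(fc@deflection), f_model,
               tolerance = 1e-6)
  # a stiff cell hits the 2 nN trigger and the curve is cut there
  stiff <- simulateForceCurve(10, contactZ = 1, zRange = c(0, 4),
                              noiseSd = 0)
  expect_lt(max(stiff@z), 4)
  expect_lte(max(p@springConstant * stiff@deflection),
             p@triggerForce * 1.02)
})

test_that("invalid curve configs are rejected", {
  expect_error(simulateForceCurve(1, contactZ = 5, zRange = c(0, 4)),
               "zRange must contain contactZ")
  expect_error(simulateForceCurve(-1, contactZ = 2))
  expect_error(simulateForceCurve(1, contactZ = 2, nPoints = 30))
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulateForceCurve(0.5, contactZ = 2, noiseSd = 2, seed = 11)
  b <- simulateForceCurve(0.5, contactZ = 2, noiseSd = 2, seed = 11)
  expect_identical(a@deflection, b@deflection)
  pa <- simulatePopulation(0.4, 0.1, nCells = 2, seed = 5)
  pb <- simulatePopulation(0.4, 0.1, nCells = 2, seed = 5)
  expect_identical(pa[[1]]$curves[[3]]@deflection,
                   pb[[1]]$curves[[3]]@deflection)
  va <- simulateViability(20, noiseSd = 5, seed = 3)
  vb <- simulateViability(20, noiseSd = 5, seed = 3)
  expect_identical(va, vb)
  ia <- simulateCellImage(c(30, 20), noiseSd = 50, seed = 4)
  ib <- simulateCellImage(c(30, 20), noiseSd = 50, seed = 4)
  expect_identical(ia$image, ib$image)
  ea <- simulateExpression(10, nReps = 3, seed = 6)
  eb <- simulateExpression(10, nReps = 3, seed = 6)
  expect_identical(SummarizedExperiment::assay(ea),
                   SummarizedExperiment::assay(eb))
})

test_that("population draws follow the requested mixture", {
  # degenerate mixture: sd = 0 puts every cell at the mean
  pop <- simulatePopulation(0.5, 0, nCells = 4, curvesPerCell = 5,
                            noiseSd = 0, seed = 1)
  expect_true(all(vapply(pop, `[[`, 0, "trueModulus") == 0.5))
  # zero-weight component never drawn
  pop2 <- simulatePopulation(c(0.3, 0.9), c(0.05, 0.05), weights = c(1, 0),
                             nCells = 30, noiseSd = 0, seed = 2)
  expect_true(all(vapply(pop2, `[[`, 0L, "component") == 1L))
  # two components: empirical means within 3 SE of truth (direct draws)
  draws <- cellmech:::with_seed(3, {
    replicate(600, as.numeric(cellmech:::.rtrunc_mixture(
      c(0.3, 0.9), c(0.08, 0.15), c(0.5, 0.5))))
  })
  labels <- cellmech:::with_seed(3, {
    replicate(600, attr(cellmech:::.rtrunc_mixture(
      c(0.3, 0.9), c(0.08, 0.15), c(0.5, 0.5)), "component"))
  })
  m1 <- mean(draws[labels == 1]); n1 <- sum(labels == 1)
  m2 <- mean(draws[labels == 2]); n2 <- sum(labels == 2)
  expect_lt(abs(m1 - 0.3), 3 * 0.08 / sqrt(n1))
  expect_lt(abs(m2 - 0.9), 3 * 0.15 / sqrt(n2))
  # empirical weights: chi-squared GoF at alpha = 0.01, n = 10,000
  lab <- cellmech:::with_seed(4, {
    replicate(10000, attr(cellmech:::.rtrunc_mixture(
      c(0.3, 0.9), c(0.08, 0.15), c(0.3, 0.7)), "component"))
  })
  gof <- chisq.test(table(factor(lab, 1:2)), p = c(0.3, 0.7))
  expect_gt(gof$p.value, 0.01)
})

test_that("viability generator follows the 4PL identities", {
  # midpoint: v(ic50) = (top + bottom) / 2
  tab <- simulateViability(10, concentrations = c(1, 5, 10, 20, 80),
                           noiseSd = 0)
  expect_equal(tab$viability_pct[tab$concentration_uM == 10], 50)
  # steep-hill limit: c < ic50 -> ~top, c > ic50 -> ~bottom
  steep <- simulateViability(10, hill = 50,
                             concentrations = c(1, 5, 10, 20, 80),
                             noiseSd = 0)
  expect_equal(steep$viability_pct[1:2], c(100, 100), tolerance = 1e-6)
  expect_equal(steep$viability_pct[4:5], c(0, 0), tolerance = 1e-6)
  # noise is clipped to [0, 110]
  noisy <- simulateViability(10, noiseSd = 300, seed = 1)
  expect_true(all(noisy$viability_pct >= 0 & noisy$viability_pct <= 110))
})

test_that("cell-image generator produces the requested mask and pattern", {
  img <- simulateCellImage(c(40, 20), profile = "uniform",
                           size = c(128, 128))
  expect_true(all(img$image[img$mask == 1] == 20000))
  expect_true(all(img$image[img$mask == 0] == 2000))
  # center-weighted blob: the crossline center outshines the periphery
  blob <- simulateCellImage(c(40, 20), profile = "center",
                            size = c(128, 128))
  pr <- crosslineProfile(blob$image, blob$mask)
  expect_gt(mean(pr$bins[pr$center_bins]),
            mean(pr$bins[pr$periphery_bins]))
  # and the rim pattern inverts that
  rim <- simulateCellImage(c(40, 20), profile = "periphery",
                           size = c(128, 128))
  pr2 <- crosslineProfile(rim$image, rim$mask)
  expect_lt(mean(pr2$bins[pr2$center_bins]),
            mean(pr2$bins[pr2$periphery_bins]))
  expect_error(simulateCellImage(c(100, 20), size = c(128, 128)),
               "fit inside")
})

test_that("expression generator encodes effects and spares housekeeping", {
  se <- simulateExpression(30, c(gene001 = 4, gene002 = 0.25), nReps = 25,
                           seed = 8)
  de <- diffExpression(se)
  expect_equal(de$log2fc[de$gene == "gene001"], 2, tolerance = 0.25)
  expect_equal(de$log2fc[de$gene == "gene002"], -2, tolerance = 0.25)
  hk <- de[de$gene %in% c("HPRT1", "HMBS", "PPIB"), ]
  expect_true(all(abs(hk$log2fc) < 0.5))
  # null genes: per-gene group means equal in expectation
  null_fc <- de$log2fc[!de$gene %in% c("gene001", "gene002")]
  expect_lt(abs(mean(null_fc)), 0.1)
  expect_error(simulateExpression(5, c(HPRT1 = 2)), "housekeeping")
})
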