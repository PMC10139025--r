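test_that("baseline correction removes offsets and tilt and is idempotent", {
  fc <- clean_curve(0.5)
  # constant offset
  off <- fc; off@deflection <- off@deflection + 5
  corr <- correctBaseline(off)
  pre <- corr@z <= 1.2  # baseline window
  expect_lt(max(abs(corr@deflection[pre])), 0.1)
  # synthetic tilt
  tilt <- simulateForceCurve(0.5, contactZ = 2, noiseSd = 0,
                             baselineSlope = 0.01)
  corr2 <- correctBaseline(tilt)
  resid_fit <- lm(corr2@deflection[corr2@z <= 1.2] ~ corr2@z[corr2@z <= 1.2])
  expect_lt(abs(coef(resid_fit)[2]), 0.05)
  # already-flat curves pass through unchanged (up to numerics)
  flat <- correctBaseline(fc)
  again <- correctBaseline(flat)
  expect_equal(again@deflection, flat@deflection, tolerance = 1e-10)
  # too few baseline points
  expect_error(correctBaseline(fc, fraction = 0.01), "20 points")
})

test_that("contact detection recovers the true contact point", {
  # noiseless, off-grid contact: within one grid step (10 nm grid)
  fc <- correctBaseline(clean_curve(0.5, contactZ = 2.1234))
  zc <- detectContactPoint(fc)
  expect_lt(abs(zc - 2.1234), 0.01)
  # all-zero deflection: no contact to find
  none <- new("ForceCurve", z = seq(0, 4, length.out = 200),
              deflection = rep(0, 200), probe = probeSpec())
  expect_error(detectContactPoint(none), "no-contact")
  # with 2 nm noise at E = 0.5 kPa the median error stays below 50 nm at
  # instrument-realistic sampling (>= kHz at 2 um/s approach, here a
  # 1200-point record over 4 um); precision is set by the information in
  # the near-contact region and scales with point density
  errs <- sapply(1:100, function(s) {
    cz <- 2 + (s %% 10) / 20
    cv <- correctBaseline(simulateForceCurve(0.5, contactZ = cz,
                                             noiseSd = 2, nPoints = 1200,
                                             seed = 2000 + s))
    abs(detectContactPoint(cv) - cz) * 1000
  })
  expect_lt(median(errs), 50)
})

test_that("Hertz fit matches the generator truth on noiseless curves", {
  for (E in c(0.1, 0.3, 1, 3)) {
    fc <- correctBaseline(clean_curve(E, contactZ = 2.05))
    fit <- fitHertz(fc, detectContactPoint(fc))
    expect_true(fit@converged)
    expect_lt(abs(youngsModulus(fit) - E) / E, 1e-3)
    expect_lte(fit@maxIndentationUsed, 500)
  }
})

test_that("fitted modulus scales linearly with the spring constant", {
  fc <- correctBaseline(clean_curve(0.8, contactZ = 2))
  zc <- detectContactPoint(fc)
  E1 <- youngsModulus(fitHertz(fc, zc))
  harder <- fc
  harder@probe@springConstant <- fc@probe@springConstant * 3
  E3 <- youngsModulus(fitHertz(harder, zc))
  expect_equal(E3, 3 * E1, tolerance = 1e-12)
})

test_that("fit window obeys the 500 nm cap and the trigger example", {
  # E = 1 kPa: force at 500 nm is ~0.943 nN < 2 nN trigger, so the full
  # window is available
  fc <- correctBaseline(clean_curve(1, contactZ = 1.5, zRange = c(0, 5)))
  fit <- fitHertz(fc, detectContactPoint(fc))
  expect_gt(fit@maxIndentationUsed, 490)
  expect_lte(fit@maxIndentationUsed, 500)
  expect_equal(youngsModulus(fit), 1, tolerance = 1e-3)
  # shrinking the window still converges but uses fewer points
  small <- fitHertz(fc, detectContactPoint(fc), maxIndent = 200)
  expect_lt(small@nFitPoints, fit@nFitPoints)
  expect_equal(youngsModulus(small), 1, tolerance = 1e-3)
})

test_that("fitted modulus is invariant to pre-contact padding", {
  fc <- correctBaseline(clean_curve(0.6, contactZ = 2.5, zRange = c(0, 4),
                                    nPoints = 400))
  long <- correctBaseline(clean_curve(0.6, contactZ = 2.5,
                                      zRange = c(-2, 4), nPoints = 600))
  E1 <- youngsModulus(fitHertz(fc, detectContactPoint(fc)))
  E2 <- youngsModulus(fitHertz(long, detectContactPoint(long)))
  expect_equal(E1, E2, tolerance = 1e-4)
})

test_that("per-cell aggregation follows the >= 5 converged-curve rule", {
  mkfit <- function(E) new("HertzFit", contactZ = 2, youngsModulus = E,
                           maxIndentationUsed = 500, rss = 0,
                           nFitPoints = 50L, converged = TRUE)
  fits <- lapply(c(0.2, 0.3, 0.4, 0.5, 0.6), mkfit)
  cs <- aggregateCell(fits, "c1")
  expect_equal(youngsModulus(cs), 0.4)
  expect_equal(cs@nCurves, 5L)
  # identical moduli aggregate to themselves
  same <- aggregateCell(lapply(rep(0.4, 5), mkfit), "c2")
  expect_equal(youngsModulus(same), 0.4)
  # median option
  med <- aggregateCell(lapply(c(0.2, 0.3, 0.4, 0.5, 5), mkfit), "c3",
                       method = "median")
  expect_equal(youngsModulus(med), 0.4)
  # a failed curve among five excludes the cell
  bad <- new("HertzFit", contactZ = NA_real_, youngsModulus = NA_real_,
             maxIndentationUsed = 0, rss = NA_real_, nFitPoints = 0L,
             converged = FALSE)
  expect_error(aggregateCell(c(fits[1:4], list(bad)), "c4"), "excluded")
})

test_that("a simulated cell's aggregate modulus is recovered without material bias", {
  # 60 replicate cells at one true modulus, 5 noisy curves each
  Es <- sapply(1:60, function(s) {
    pop <- simulatePopulation(0.28, 0, nCells = 1, curvesPerCell = 5,
                              withinCellCV = 0.1, seed = 4000 + s)
    tryCatch(youngsModulus(fitCellStiffness(pop[[1]]$curves)),
             error = function(e) NA)
  })
  expect_gt(mean(!is.na(Es)), 0.95)
  expect_lt(abs(mean(Es, na.rm = TRUE) - 0.28) / 0.28, 0.02)
})

test_that("analyzePopulation collects per-cell results and logs exclusions", {
  pop <- simulatePopulation(0.5, 0.05, nCells = 6, seed = 10)
  res <- analyzePopulation(pop, lineId = "demo")
  expect_s4_class(res$population, "StiffnessPopulation")
  expect_equal(nrow(res$cells) + length(res$excluded), 6)
  expect_true(all(res$cells$n_curves >= 5))
  expect_true(all(res$cells$E_kPa_mean > 0))
  expect_equal(nCells(res$population), nrow(res$cells))
})
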