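test_that("a noise-free single logistic is recovered to numerical precision", {
  # b = 0.05, K = 1, r = 1 /h, m = 6 h  ->  S = 1, R = 0.25, L = 4
  curve <- logisticCurve(0.05, 1, 1, 6)
  f <- fitGrowth(curve, n_phases = 1)
  ph <- phaseParameters(f)
  expect_true(isConverged(f))
  expect_equal(ph$saturation, 1, tolerance = 1e-6)
  expect_equal(ph$max_rate, 0.25, tolerance = 1e-6)
  expect_equal(ph$lag_h, 4, tolerance = 1e-6)
  expect_equal(baselineOD(f), 0.05, tolerance = 1e-6)
})

test_that("segmentation proposes the right phase count with close guesses", {
  cfg0 <- simConfig(seed = 1, noise_sd = 0)
  wt <- genGrowthCurve(strainArchetype("wt"), cfg = cfg0)
  seg <- segmentPhases(wt)
  expect_equal(seg$n_phases, 2L)
  tr <- groundTruth(wt)$phases
  for (i in 1:2) {
    expect_equal(seg$guesses[[i]]$K, tr$K[i], tolerance = 0.1)
    expect_equal(seg$guesses[[i]]$m, tr$m[i], tolerance = 0.1 * tr$m[i])
  }
  mut <- genGrowthCurve(strainArchetype("sdh2"), cfg = cfg0)
  expect_equal(segmentPhases(mut)$n_phases, 1L)
  flat <- growthCurve(seq(0, 48, 0.1), rep(0.05, 481))
  expect_true(segmentPhases(flat)$no_growth)
  expect_equal(nPhases(fitGrowth(flat)), 0L)
})

test_that("auto fitting recovers both phases of a diauxic curve under noise", {
  gc <- genGrowthCurve(strainArchetype("wt"),
                       cfg = simConfig(seed = 5, noise_sd = 0.01))
  f <- fitGrowth(gc, seed = 5)
  expect_equal(nPhases(f), 2L)
  tr <- groundTruth(gc)$phases
  ph <- phaseParameters(f)
  expect_equal(ph$saturation, tr$saturation, tolerance = 0.05)
  expect_equal(ph$max_rate, tr$max_rate, tolerance = 0.05)
  expect_equal(ph$lag_h, tr$lag_h, tolerance = 0.05)
})

test_that("fitting never degrades the segmentation start", {
  for (s in c(3, 14)) {
    gc <- genGrowthCurve(strainArchetype("wt"),
                         cfg = simConfig(seed = s, noise_sd = 0.01))
    seg <- segmentPhases(gc)
    guess_pred <- rep(seg$baseline, length(timePoints(gc)))
    for (g in seg$guesses)
      guess_pred <- guess_pred + g$K / (1 + exp(-g$r * (timePoints(gc) - g$m)))
    guess_rss <- sum((odValues(gc) - guess_pred)^2)
    f <- fitGrowth(gc, n_phases = seg$n_phases, seed = s)
    expect_lte(f@rss, guess_rss)
  }
})

test_that("fits are time-shift and OD-scale equivariant", {
  gc <- genGrowthCurve(strainArchetype("sdh2"),
                       cfg = simConfig(seed = 9, noise_sd = 0.01,
                                       media_mix = 1))
  f0 <- fitGrowth(gc, n_phases = 1, seed = 2)
  ph0 <- phaseParameters(f0)

  dt <- 3.5
  shifted <- growthCurve(timePoints(gc) + dt, odValues(gc), strain = "sdh2")
  fs <- phaseParameters(fitGrowth(shifted, n_phases = 1, seed = 2))
  expect_equal(fs$lag_h, ph0$lag_h + dt, tolerance = 1e-3)
  expect_equal(fs$max_rate, ph0$max_rate, tolerance = 1e-3)
  expect_equal(fs$saturation, ph0$saturation, tolerance = 1e-3)

  cc <- 2.7
  scaled <- growthCurve(timePoints(gc), cc * odValues(gc), strain = "sdh2")
  fc <- fitGrowth(scaled, n_phases = 1, seed = 2)
  phc <- phaseParameters(fc)
  expect_equal(phc$saturation, cc * ph0$saturation, tolerance = 1e-3)
  expect_equal(phc$max_rate, cc * ph0$max_rate, tolerance = 1e-3)
  expect_equal(baselineOD(fc), cc * baselineOD(f0), tolerance = 1e-3)
  expect_equal(phc$lag_h, ph0$lag_h, tolerance = 1e-3)
})

test_that("parameter recovery and phase-count selection meet their error budget", {
  wt <- strainArchetype("wt"); mut <- strainArchetype("sdh2")
  n_sim <- 100
  np_ok <- logical(n_sim)
  errs <- list(S = c(), R = c(), L = c())
  for (s in seq_len(n_sim)) {
    arch <- if (s %% 2) wt else mut
    gc <- genGrowthCurve(arch, cfg = simConfig(seed = 100 + s,
                                               noise_sd = 0.01))
    f <- fitGrowth(gc, seed = s)
    tr <- groundTruth(gc)$phases
    np_ok[s] <- nPhases(f) == nrow(tr)
    if (!np_ok[s]) next
    ph <- phaseParameters(f)
    errs$S <- c(errs$S, abs(ph$saturation - tr$saturation) / tr$saturation)
    errs$R <- c(errs$R, abs(ph$max_rate - tr$max_rate) / tr$max_rate)
    errs$L <- c(errs$L, abs(ph$lag_h - tr$lag_h) / tr$lag_h)
  }
  expect_gte(mean(np_ok), 0.95)
  expect_lte(median(errs$S), 0.05)
  expect_lte(median(errs$R), 0.10)
  expect_lte(median(errs$L), 0.10)
  # noise-free model selection is always right
  for (s in 1:6) {
    arch <- if (s %% 2) wt else mut
    gc0 <- genGrowthCurve(arch, cfg = simConfig(seed = s, noise_sd = 0))
    expect_equal(nPhases(fitGrowth(gc0, seed = s)),
                 nrow(groundTruth(gc0)$phases))
  }
})

test_that("short or invalid curves are rejected", {
  expect_error(fitGrowth(growthCurve(1:10, rep(1, 10))), "30 points")
  expect_error(growthCurve(c(1, 1, 2), c(1, 1, 1)), "increasing")
  expect_error(growthCurve(1:3, c(1, NA, 1)), "finite")
})
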