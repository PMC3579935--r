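test_that("a perfectly linear decay gives its slope over the full window", {
  t <- seq(0, 20, 2)
  r <- initialRate(t, 1 - 0.01 * t)
  expect_equal(r$v0, 0.01, tolerance = 1e-12)
  expect_equal(r$window_used, 11)
  expect_length(r$flags, 0)
})

test_that("flat and rising traces are flagged", {
  t <- seq(0, 20, 2)
  flat <- initialRate(t, rep(0.8, 11))
  expect_equal(flat$v0, 0)
  expect_true("flat" %in% flat$flags)
  up <- initialRate(t, 0.5 + 0.02 * t)
  expect_true("increasing" %in% up$flags)
  expect_equal(up$v0, 0)  # sign convention: NADH consumption only
  expect_error(initialRate(t[1:3], rep(1, 3)), "fewer points")
  expect_error(initialRate(t, rep(1, 11), min_points = 2), "min_points")
})

test_that("the initial rate of a first-order depletion curve is accurate", {
  # read noise at the generator default; truth from the analytic slope
  for (s in 1:5) {
    rec <- genEnzymeAssay(10, dilution = serialDilution(62.5, 5, 8),
                          replicates = 1,
                          cfg = simConfig(seed = 400 + s, noise_sd = 0.003))
    tr <- attr(rec, "truth")
    d0 <- rec[rec$conc_um == 0, ]
    r <- initialRate(d0$time_min, d0$a340)
    expect_equal(r$v0, tr$v0_uninhibited, tolerance = 0.10)
  }
})

test_that("v0 is invariant to a constant absorbance offset", {
  rec <- genEnzymeAssay(5, replicates = 1, cfg = simConfig(seed = 21,
                                                           noise_sd = 0.003))
  d <- rec[rec$conc_um == 0.5, ]
  r1 <- initialRate(d$time_min, d$a340)
  r2 <- initialRate(d$time_min, d$a340 + 0.37)
  expect_equal(r1$v0, r2$v0)
  expect_equal(r1$window_used, r2$window_used)
})

test_that("relaxing the linearity floor never shortens the chosen window", {
  # strongly curved noisy trace so window selection actually varies
  t <- seq(0, 20, 2)
  y <- withr::with_seed(5, 0.05 + 1.24 * exp(-0.05 * t) + rnorm(11, 0, 0.003))
  wins <- vapply(c(0.999, 0.995, 0.99, 0.98, 0.95, 0.90), function(fl)
    initialRate(t, y, r2_floor = fl)$window_used, numeric(1))
  expect_true(all(diff(wins) >= 0))
})

test_that("enzyme inhibition IC50s are recovered from full assay simulations", {
  rec <- genEnzymeAssay(3.8, dilution = serialDilution(62.5, 5, 8),
                        replicates = 4, cfg = simConfig(seed = 12,
                                                        noise_sd = 0.003))
  res <- enzymeInhibitionIC50(rec)
  expect_true(isConverged(res$fit))
  expect_equal(ic50(res$fit), 3.8, tolerance = 0.25)
  expect_error(enzymeInhibitionIC50(rec[rec$conc_um > 0, ]), "zero-inhibitor")
})

test_that("independent assay repetitions agree within a 30 percent CV", {
  runs <- lapply(1:3, function(run) {
    rec <- genEnzymeAssay(3.8, dilution = serialDilution(62.5, 5, 8),
                          replicates = 4,
                          cfg = simConfig(seed = 600 + run, noise_sd = 0.003))
    rec$run <- run
    rec
  })
  res <- enzymeInhibitionIC50(do.call(rbind, runs))
  expect_equal(nrow(res$per_run), 3)
  cv <- sd(res$per_run$ic50) / mean(res$per_run$ic50)
  expect_lte(cv, 0.30)
  expect_equal(res$ic50_mean, 3.8, tolerance = 0.25)
})

test_that("saturating inhibition and out-of-range potency are diagnosed", {
  # every tested concentration abolishes activity
  rec <- genEnzymeAssay(1e-6, dilution = serialDilution(62.5, 5, 8),
                        replicates = 2, cfg = simConfig(seed = 9,
                                                        noise_sd = 0.001))
  res <- enzymeInhibitionIC50(rec)
  expect_false(isConverged(res$fit))
  expect_true("flat_at_zero" %in% unlist(res$fit@diag$flags))
  # truth far above the top concentration: extrapolation is flagged
  rec2 <- genEnzymeAssay(500, dilution = serialDilution(62.5, 5, 8),
                         replicates = 4, cfg = simConfig(seed = 10,
                                                         noise_sd = 0))
  res2 <- enzymeInhibitionIC50(rec2)
  expect_true(isTRUE(res2$fit@diag$extrapolated))
})
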