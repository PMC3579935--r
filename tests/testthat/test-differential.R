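test_that("delta scores vanish without differential effect and split ratios otherwise", {
  ctrl_m <- makeFit(S = 0.55, R = 0.12, L = 4)
  ctrl_r <- makeFit(S = 1.05, R = 0.12, L = 4)
  # no effect on either strain
  s0 <- deltaScores(ctrl_m, ctrl_m, ctrl_r, ctrl_r, "a", 50)
  expect_equal(c(s0$delta_S, s0$delta_R, s0$delta_L), c(0, 0, 0))
  # drug halving saturation in both strains cancels
  half_m <- makeFit(S = 0.55 / 2, R = 0.12, L = 4)
  half_r <- makeFit(S = 1.05 / 2, R = 0.12, L = 4)
  expect_equal(deltaScores(ctrl_m, half_m, ctrl_r, half_r, "b", 50)$delta_S, 0)
  # mutant-selective: mutant saturation x0.2, reference x0.9
  s1 <- deltaScores(ctrl_m, makeFit(0.55 * 0.2, 0.12, 4),
                    ctrl_r, makeFit(1.05 * 0.9, 0.12, 4), "c", 50)
  expect_equal(s1$delta_S, 0.7, tolerance = 1e-12)
  expect_equal(s1$delta_R, 0)
  expect_equal(s1$delta_L, 0)
})

test_that("delta scores are antisymmetric under strain swap and scale invariant", {
  set.seed(31)
  for (i in 1:10) {
    f <- replicate(4, makeFit(S = runif(1, 0.2, 1.2), R = runif(1, 0.05, 0.3),
                              L = runif(1, 1, 8)), simplify = FALSE)
    s_ab <- deltaScores(f[[1]], f[[2]], f[[3]], f[[4]])
    s_ba <- deltaScores(f[[3]], f[[4]], f[[1]], f[[2]])
    expect_equal(s_ab$delta_S, -s_ba$delta_S)
    expect_equal(s_ab$delta_R, -s_ba$delta_R)
    expect_equal(s_ab$delta_L, -s_ba$delta_L)
    # multiplying every saturation by a constant leaves delta_S unchanged
    cc <- runif(1, 0.5, 4)
    g <- lapply(f, function(x) makeFit(cc * x@phases$saturation,
                                       x@phases$max_rate, x@phases$lag_h))
    expect_equal(deltaScores(g[[1]], g[[2]], g[[3]], g[[4]])$delta_S,
                 s_ab$delta_S)
  }
})

test_that("lag floor and failed fits are handled explicitly", {
  zero_lag <- makeFit(S = 0.5, R = 0.12, L = 0)
  lagged <- makeFit(S = 0.5, R = 0.12, L = 1)
  s <- deltaScores(zero_lag, lagged, zero_lag, zero_lag, lag_floor = 0.25)
  expect_equal(s$delta_L, 1 / 0.25)  # control lag replaced by the floor
  bad <- makeFit(0.5, 0.12, 4)
  bad@converged <- FALSE
  si <- deltaScores(bad, lagged, zero_lag, zero_lag)
  expect_true(si$indeterminate)
  expect_equal(classifyCall(si, 0.3), "indeterminate")
})

test_that("classification respects thresholds, ties and conflicts", {
  mk <- function(dS, dR = 0, dL = 0)
    data.frame(delta_S = dS, delta_R = dR, delta_L = dL,
               indeterminate = FALSE)
  expect_equal(classifyCall(mk(0, 0, 0), 0.3), "nonselective")
  expect_equal(classifyCall(mk(0.31), 0.3), "mutant_selective")
  expect_equal(classifyCall(mk(-0.31), 0.3), "reference_selective")
  # a delta exactly at the threshold stays nonselective (strict inequality)
  expect_equal(classifyCall(mk(0.3), 0.3), "nonselective")
  # per-metric thresholds
  thr <- c(delta_S = 0.3, delta_R = 0.7, delta_L = 0.3)
  expect_equal(classifyCall(mk(0, 0.5, 0), thr), "nonselective")
  expect_equal(classifyCall(mk(0, 0.8, 0), thr), "mutant_selective")
  # conflicting directions resolve by threshold-normalized magnitude
  expect_equal(classifyCall(mk(0.9, -0.8, 0), thr), "mutant_selective")
  expect_equal(classifyCall(mk(0.31, -0.75, -0.9), thr),
               "reference_selective")
  expect_equal(classifyCall(mk(0.6, -1.4, 0), thr), "indeterminate")
  expect_error(classifyCall(mk(0.5)), "explicit")
})

test_that("stage-II scoring reproduces the ground-truth classes through fits", {
  classes <- c(rep("mutant_selective", 3), "reference_selective",
               rep("nonselective", 4))
  ids <- sprintf("t%02d", seq_along(classes))
  eff <- setNames(mapply(defaultEffectModel, classes, ids, SIMPLIFY = FALSE),
                  ids)
  s2 <- stageTwoDifferential(eff, 50, simConfig(seed = 3, noise_sd = 0.01),
                             seed = 17,
                             delta_threshold = c(delta_S = 0.3,
                                                 delta_R = 0.7,
                                                 delta_L = 0.3))
  expect_identical(s2$scores$call, classes)
})

test_that("marker concordance flags only genuinely divergent drug responses", {
  ctrl <- makeFit(S = 1.05, R = 0.12, L = 4)
  drug <- makeFit(S = 0.9, R = 0.11, L = 4.5)
  ref <- list(a = list(ctrl = ctrl, drug = drug))
  # identical fits are concordant
  mc <- markerConcordance(ref, ref, tolerance = 0.2)
  expect_true(mc$concordant)
  # a marker strain uniquely sensitized three-fold is flagged
  marker <- list(a = list(ctrl = ctrl,
                          drug = makeFit(S = 0.3, R = 0.11, L = 4.5)))
  mc2 <- markerConcordance(ref, marker, tolerance = 0.2)
  expect_false(mc2$concordant)
  expect_false(mc2$report$concordant[1])
  # an empty comparison set is an error, not a vacuous pass
  expect_error(markerConcordance(list(), list()), "empty")
  expect_error(markerConcordance(ref, list(b = ref$a)), "unmatched")
})
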