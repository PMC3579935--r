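test_that("percent inhibition has the control/blank fixed points", {
  expect_equal(percentInhibition(1.0, 1.0, 0.1), 0)
  expect_equal(percentInhibition(0.1, 1.0, 0.1), 100)
  expect_equal(percentInhibition(0.55, 1.00, 0.10), 50)
  # pass-through outside [0, 100], no clipping
  expect_lt(percentInhibition(1.2, 1.0, 0.1), 0)
  expect_gt(percentInhibition(0.05, 1.0, 0.1), 100)
  expect_error(percentInhibition(0.5, 0.1, 0.1), "control")
})

test_that("percent inhibition is invariant under affine rescaling of absorbances", {
  set.seed(42)
  for (i in 1:20) {
    test <- runif(1, 0, 1.5); ctrl <- runif(1, 0.5, 2); blk <- runif(1, 0, 0.4)
    if (ctrl <= blk) next
    a <- runif(1, 0.1, 5); b <- runif(1, -0.2, 0.2)
    expect_equal(percentInhibition(a * test + b, a * ctrl + b, a * blk + b),
                 percentInhibition(test, ctrl, blk))
  }
})

test_that("z-factor matches direct computation and its limits", {
  # zero spread, distinct means: perfect separation
  expect_equal(zFactor(c(100, 100), c(0, 0)), 1)
  # worked example under the sample-sd convention
  expect_equal(zFactor(c(90, 100, 110), c(-10, 0, 10)), 0.4)
  # overlapping controls go negative
  expect_lt(zFactor(c(60, 10, 40), c(0, 45, 20)), 0)
  expect_error(zFactor(c(50, 50), c(50, 50)), "QC failure")
  expect_error(zFactor(100, c(0, 1)))
})

test_that("z-factor is label-exchange invariant and never exceeds 1", {
  set.seed(9)
  for (i in 1:25) {
    pos <- rnorm(8, 100, runif(1, 0.1, 30))
    neg <- rnorm(8, 0, runif(1, 0.1, 30))
    z <- zFactor(pos, neg)
    expect_lte(z, 1)
    expect_equal(z, zFactor(neg, pos))
  }
})

test_that("plate summaries normalize against per-plate controls", {
  tp <- tinyPlate(n_compound = 4, control = 1.0, blank = 0.1,
                  compound = 1.0)
  pi_tab <- summarizePlate(tp$reads, tp$map)
  expect_equal(nrow(pi_tab), 4)
  expect_true(all(pi_tab$percent_inhibition == 0))

  tp2 <- tinyPlate(compound = 0.55)
  expect_equal(summarizePlate(tp2$reads, tp2$map)$percent_inhibition,
               rep(50, 4))
  # duplicate well entries are rejected
  expect_error(summarizePlate(rbind(tp$reads, tp$reads[1, ]), tp$map),
               "duplicate")
  # missing blanks are rejected
  bad_map <- tp$map; bad_map$role[bad_map$role == "blank"] <- "neg_control"
  expect_error(summarizePlate(tp$reads, bad_map), "blanks")
})

test_that("a null screen scores near zero inhibition and a clean screen near truth", {
  cfg <- simConfig(seed = 5, noise_sd = 0.01)
  null_sp <- genScreenPlate(320, 0, cfg = cfg)
  pi_tab <- summarizePlate(null_sp$reads, null_sp$map)
  pi48 <- pi_tab$percent_inhibition[pi_tab$read_time_h == 48]
  expect_lt(abs(mean(pi48)), 1.5)
  expect_lt(sd(pi48), 6)           # set by read noise over control window
  # at any positive threshold essentially nothing is called
  expect_lte(nrow(callHits(pi_tab, threshold = 20, read_time_h = 48)), 2)
  # threshold 0 on a null screen catches about half the wells
  frac0 <- nrow(callHits(pi_tab, threshold = 0, read_time_h = 48)) / 320
  expect_gt(frac0, 0.35); expect_lt(frac0, 0.65)

  sp <- genScreenPlate(320, 0.05, cfg = simConfig(seed = 8, noise_sd = 0.01))
  pt <- summarizePlate(sp$reads, sp$map)
  hits <- callHits(pt, threshold = 50, read_time_h = 48)
  truth_strong <- sp$truth$compound_id[sp$truth$class %in%
                                         c("mutant_selective", "nonselective")]
  expect_setequal(hits$compound_id, truth_strong)
  # deterministic ordering: PI descending then compound id
  expect_true(all(diff(hits$percent_inhibition) <= 0))
  expect_error(callHits(pt, threshold = 50, read_time_h = 24), "read time")
  expect_error(callHits(pt, read_time_h = 48), "threshold")
})

test_that("synthetic control plates support HTS-grade z-factors", {
  cp <- genControlPlate(cfg = simConfig(seed = 6, noise_sd = 0.01))
  qc <- plateQC(cp$reads, cp$map)
  expect_equal(nrow(qc), 2)
  expect_true(all(qc$z_factor > 0.5))
  expect_true(all(qc$z_factor <= 1))
})

test_that("dispensing arithmetic conserves compound mass across stages", {
  p <- dispenseProtocol()
  stages <- c("after_dispense", "after_topup", "final_assay")
  res <- lapply(stages, function(s) dispenseConcentration(p, s))
  amounts <- vapply(res, function(r) r$conc_um * r$volume_ul, numeric(1))
  expect_equal(amounts, rep(amounts[1], 3))
  # nominal protocol-sheet values
  expect_equal(res[[1]]$conc_um_nominal, 50)
  expect_equal(res[[2]]$conc_um_nominal, 12.5)
  expect_equal(res[[2]]$solvent_pct_nominal, 0.125)
  expect_equal(res[[3]]$conc_um_nominal, 10)
  expect_equal(res[[3]]$solvent_pct_nominal, 0.1)
  # full accounting differs only by the droplet volume itself
  expect_equal(res[[3]]$volume_ul, 50.05)
  # zero droplets give zero concentration at every stage
  p0 <- dispenseProtocol(n_droplets = 0)
  for (s in stages) expect_equal(dispenseConcentration(p0, s)$conc_um, 0)
})
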