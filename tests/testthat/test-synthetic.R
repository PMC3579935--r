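test_that("respiration-deficient strain on non-fermentable media stays at baseline", {
  cfg <- simConfig(seed = 2, noise_sd = 0, media_mix = 0)
  gc <- genGrowthCurve(strainArchetype("sdh2"), cfg = cfg)
  tr <- groundTruth(gc)
  expect_equal(tr$asymptote, tr$baseline)
  expect_true(all(odValues(gc) == tr$baseline))
})

test_that("noise-free two-phase curve plateaus at baseline + phase-1 saturation", {
  cfg <- simConfig(seed = 1, noise_sd = 0, media_mix = 0.5)
  gc <- genGrowthCurve(strainArchetype("wt"), cfg = cfg)
  tr <- groundTruth(gc)$phases
  # at the derivative minimum between the phases, phase 1 is complete and
  # phase 2 has barely started: the visible diauxic plateau
  d <- diff(odValues(gc)) / diff(timePoints(gc))
  between <- timePoints(gc)[-1] > tr$m[1] & timePoints(gc)[-1] < tr$m[2]
  t_plateau <- timePoints(gc)[-1][between][which.min(d[between])]
  plateau <- odValues(gc)[which.min(abs(timePoints(gc) - t_plateau))]
  expect_equal(plateau, 0.05 + tr$saturation[1], tolerance = 0.02)
  # noise-free curves are non-decreasing for competent strains
  expect_true(all(diff(odValues(gc)) >= -1e-12))
})

test_that("zero-dose drug application is an identity on curve and truth", {
  cfg <- simConfig(seed = 11, noise_sd = 0.01)
  drug <- defaultEffectModel("mutant_selective", "cmpdX")
  a <- genGrowthCurve(strainArchetype("sdh2"), cfg = cfg)
  b <- genGrowthCurve(strainArchetype("sdh2"), drug = drug, conc_um = 0,
                      cfg = cfg)
  expect_identical(odValues(a), odValues(b))
  expect_equal(groundTruth(a)$phases[, -2], groundTruth(b)$phases[, -2])
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simConfig(seed = 7, noise_sd = 0.01)
  expect_identical(odValues(genGrowthCurve(strainArchetype("wt"), cfg = cfg)),
                   odValues(genGrowthCurve(strainArchetype("wt"), cfg = cfg)))
  s1 <- genScreenPlate(32, 0.25, cfg = cfg)
  s2 <- genScreenPlate(32, 0.25, cfg = cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  e1 <- genEnzymeAssay(3.8, cfg = cfg)
  e2 <- genEnzymeAssay(3.8, cfg = cfg)
  expect_identical(e1$a340, e2$a340)
  # a different seed gives different noise
  cfg2 <- simConfig(seed = 8, noise_sd = 0.01)
  expect_false(identical(odValues(genGrowthCurve(strainArchetype("wt"),
                                                 cfg = cfg)),
                         odValues(genGrowthCurve(strainArchetype("wt"),
                                                 cfg = cfg2))))
})

test_that("drug effects transform ground truth through the Hill model", {
  drug <- drugEffect("d", list(sdh2 = list(sat_mult = 0.2, ec50_um = 1,
                                           hill = 1)))
  cfg <- simConfig(seed = 1, noise_sd = 0, media_mix = 1)
  # at c = ec50 the occupancy is 1/2: multiplier 1 - 0.8/2 = 0.6
  gc <- genGrowthCurve(strainArchetype("sdh2"), drug, conc_um = 1, cfg = cfg)
  expect_equal(groundTruth(gc)$phases$saturation, 0.55 * 0.6)
  # unaffected strain sees no effect
  gw <- genGrowthCurve(strainArchetype("wt"), drug, conc_um = 1, cfg = cfg)
  expect_equal(groundTruth(gw)$phases$saturation[1], 0.55)
})

test_that("screening plates follow the edge-control layout and truth design", {
  cfg <- simConfig(seed = 11)
  sp <- genScreenPlate(320, 0.05, cfg = cfg)
  expect_equal(nrow(sp$map), 384)
  expect_equal(nrow(sp$reads), 384 * 2)
  cols <- as.integer(substring(sp$map$well, 2))
  expect_true(all(sp$map$role[cols %in% c(1, 2, 23)] == "neg_control"))
  expect_true(all(sp$map$role[cols == 24] == "blank"))
  expect_true(all(sp$map$role[cols %in% 3:22] == "compound"))
  # binomial design with fixed assignment: 5% of 320 = 16 true inhibitors
  expect_equal(sum(sp$truth$is_inhibitor), 16)
  expect_error(genScreenPlate(400, 0.1, cfg = cfg), "multi_plate")
  expect_equal(length(unique(genScreenPlate(400, 0.1, cfg = cfg,
                                            multi_plate = TRUE)$map$plate_id)),
               2)
})

test_that("control plates alternate culture / killer / media rows", {
  cp <- genControlPlate(cfg = simConfig(seed = 4))
  rows <- match(substr(cp$map$well, 1, 1), LETTERS)
  expected <- rep(c("neg_control", "pos_control", "blank"),
                  length.out = 16)[rows]
  expect_identical(cp$map$role, expected)
  expect_setequal(unique(cp$reads$time_min), c(16, 48) * 60)
})

test_that("enzyme progress curves encode the Hill-scaled initial slope exactly", {
  cfg0 <- simConfig(seed = 1, noise_sd = 0)
  rec <- genEnzymeAssay(10, hill = 1, dilution = serialDilution(62.5, 5, 8),
                        replicates = 1, cfg = cfg0)
  tr <- attr(rec, "truth")
  kOf <- function(d) {
    # exact decay constant from consecutive noise-free points
    a <- d$a340 - tr$background
    -log(a[2] / a[1]) / diff(d$time_min[1:2])
  }
  d0 <- rec[rec$conc_um == 0, ]
  expect_equal(tr$a0 * kOf(d0), tr$v0_uninhibited, tolerance = 1e-12)
  # at c = IC50 the initial slope is exactly half the uninhibited rate
  rec2 <- genEnzymeAssay(0.5, hill = 1, dilution = serialDilution(0.5, 2, 4),
                         replicates = 1, cfg = cfg0)
  tr2 <- attr(rec2, "truth")
  dhalf <- rec2[rec2$conc_um == 0.5, ]
  a <- dhalf$a340 - tr2$background
  k <- -log(a[2] / a[1]) / 2
  expect_equal(tr2$a0 * k, tr2$v0_uninhibited / 2, tolerance = 1e-12)
})

test_that("the enzyme assay emits the full replicated dilution design", {
  rec <- genEnzymeAssay(3.8, dilution = serialDilution(62.5, 5, 8),
                        replicates = 4, cfg = simConfig(seed = 3))
  # 8 dilution points + zero-inhibitor wells, 4 replicates, 11 time points
  expect_equal(nrow(rec), 9 * 4 * 11)
  expect_equal(length(unique(rec$conc_um[rec$conc_um > 0])), 8)
  expect_error(genEnzymeAssay(-1, cfg = simConfig(seed = 1)))
  expect_error(genEnzymeAssay(10, replicates = 0, cfg = simConfig(seed = 1)))
})

test_that("invalid generator inputs are rejected", {
  expect_error(genGrowthCurve(strainArchetype("wt"), conc_um = -5,
                              cfg = simConfig(seed = 1)))
  expect_error(simConfig(duration = 0))
  expect_error(simConfig(sampling_interval = 0))
  expect_error(validObject(
    new("StrainArchetype", name = "sdh2", phase1_competent = TRUE,
        phase2_competent = TRUE,
        phase1_params = c(lag_h = 1, max_rate = 1, saturation = 1),
        phase2_params = c(lag_h = 1, max_rate = 1, saturation = 1),
        baseline_od = 0.05)))
})
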