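# Shared fixture builders (all data generated in code).

# A minimal single-plate read/map pair with explicit well values.
# values: named list role -> OD vector recycled over that role's wells.
tinyPlate <- function(n_compound = 4, control = 1.0, blank = 0.1,
                      compound = 0.55, read_time_h = 48) {
  wells <- c(paste0("A", seq_len(n_compound)), "B1", "B2", "C1", "C2")
  role <- c(rep("compound", n_compound), "neg_control", "neg_control",
            "blank", "blank")
  map <- data.frame(plate_id = "P1", well = wells, role = role,
                    compound_id = c(sprintf("cmpd%02d", seq_len(n_compound)),
                                    rep(NA, 4)),
                    conc_um = c(rep(10, n_compound), rep(0, 4)),
                    strain = "sdh2", stringsAsFactors = FALSE)
  value <- c(rep_len(compound, n_compound), control, control, blank, blank)
  reads <- data.frame(plate_id = "P1", well = wells,
                      time_min = read_time_h * 60, channel = "od600",
                      value = value, stringsAsFactors = FALSE)
  list(reads = reads, map = map)
}

# A one-phase GrowthFit with prescribed reported parameters, for tests of
# the differential algebra that do not need an actual curve fit.
makeFit <- function(S, R, L, baseline = 0.05) {
  r <- 4 * R / S
  m <- L + 2 / r
  new("GrowthFit", n_phases = 1L, baseline = baseline,
      phases = data.frame(phase = 1L, lag_h = L, max_rate = R,
                          saturation = S, K = S, r = r, m = m),
      rss = 0, aicc = NA_real_, converged = TRUE, diag = list())
}

# Noise-free single-logistic curve from raw logistic parameters.
logisticCurve <- function(b, K, r, m, t = seq(0, 24, 0.1)) {
  growthCurve(t, b + K / (1 + exp(-r * (t - m))), strain = "custom")
}
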