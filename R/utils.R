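# Internal helpers shared across modules.

# Logistic growth component K / (1 + exp(-r (t - m))).
logisticComponent <- function(t, K, r, m) K / (1 + exp(-r * (t - m)))

# Convert the reported phase parameters (lag L, maximal slope R, saturation S)
# to logistic (K, r, m): K = S, r = 4 R / S, m = L + 2 / r.
phaseToLogistic <- function(lag_h, max_rate, saturation) {
  r <- 4 * max_rate / saturation
  c(K = saturation, r = r, m = lag_h + 2 / r)
}

# Inverse transform: reported parameters from logistic ones.
logisticToPhase <- function(K, r, m) {
  c(lag_h = max(0, m - 2 / r), max_rate = r * K / 4, saturation = K)
}

# Hill occupancy: 0 at c = 0, 1/2 at c = ec50, -> 1 as c -> Inf.
hillOccupancy <- function(conc, ec50, hill) {
  if (conc <= 0) return(0)
  ch <- (conc / ec50)^hill
  ch / (1 + ch)
}

# Centred moving average with odd window, edges padded by shrinking window.
movingMean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# Small-sample-corrected AIC from a Gaussian RSS with k mean parameters.
# An RSS floor keeps the criterion finite on noise-free data.
aiccFromRSS <- function(rss, n, k, rss_floor = n * 1e-12) {
  rss <- max(rss, rss_floor)
  kk <- k + 1  # + variance parameter
  n * log(rss / n) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1)
}

# Deterministic child seed (keeps derived seeds within 32-bit integer range).
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 69069 + offset * 2654435) %% .Machine$integer.max)
}

# Well coordinate helpers for 384-well plates (rows A-P, columns 1-24).
wellName <- function(row, col) paste0(LETTERS[row], col)

wellRow <- function(well) match(substr(well, 1, 1), LETTERS)

wellCol <- function(well) as.integer(substring(well, 2))

`%||%` <- function(a, b) if (is.null(a)) b else a
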