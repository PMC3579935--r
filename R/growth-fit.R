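#' Propose the number of growth phases and initial parameter guesses
#'
#' Smooths the OD trace (moving median then moving mean, 5-point windows),
#' takes the numeric time derivative, and looks for derivative maxima. Two
#' phases are proposed when two separated maxima exist with an intervening
#' minimum below \code{valley_frac} of the smaller maximum; otherwise one.
#' When the read noise is appreciable the derivative itself is additionally
#' smoothed over roughly 1.5 h before peak finding. Initial guesses place
#' the inflection times at the derivative maxima, take maximal rates from
#' the peak slopes, and read saturations off the plateau levels.
#'
#' A curve whose smoothed dynamic range is below \code{floor_od} is declared
#' "no growth" and no fit is attempted downstream.
#'
#' @param curve a \code{\link{GrowthCurve}}
#' @param valley_frac valley-depth fraction for the two-phase call
#' @param window smoothing window in points (odd)
#' @param floor_od minimum OD dynamic range for growth
#' @return list: n_phases (0, 1 or 2), baseline, guesses (per phase list of
#'   K, r, m), plus the smoothed trace and derivative for inspection
#' @export
segmentPhases <- function(curve, valley_frac = 0.3, window = 5,
                          floor_od = 0.05) {
  stopifnot(is(curve, "GrowthCurve"))
  t <- curve@times; od <- curve@od
  n <- length(od)
  if (n < 30) stop("need at least 30 points to segment a growth curve")

  k <- max(3L, window - (window + 1L) %% 2L)  # odd
  sm <- movingMean(stats::runmed(od, k), k)
  rng <- diff(range(sm))
  base <- mean(sm[seq_len(min(5L, n))])
  if (rng < floor_od)
    return(list(n_phases = 0L, baseline = base, guesses = list(),
                smoothed = sm, deriv = rep(0, n - 1L), no_growth = TRUE))

  dt <- diff(t)
  d <- diff(sm) / dt
  noise <- stats::mad(diff(od)) / sqrt(2)
  if (noise > 0.002) {
    kw <- max(5L, round(1.5 / stats::median(dt)))
    kw <- kw + (kw + 1L) %% 2L
    d <- movingMean(d, kw)
  }
  tm <- (t[-1] + t[-n]) / 2

  # local maxima of the derivative within a +/- 0.75 h window
  hw <- max(3L, round(0.75 / stats::median(dt)))
  is_peak <- vapply(seq_along(d), function(i) {
    lo <- max(1L, i - hw); hi <- min(length(d), i + hw)
    d[i] == max(d[lo:hi]) && d[i] > 0.05 * max(d)
  }, logical(1))
  peaks <- which(is_peak)
  # collapse runs of equal values
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > hw)]
  peaks <- peaks[order(-d[peaks])]

  two <- FALSE
  p1 <- peaks[1]
  if (length(peaks) >= 2) {
    p2 <- peaks[2]
    lo <- min(p1, p2); hi <- max(p1, p2)
    valley <- min(d[lo:hi])
    if (valley < valley_frac * min(d[p1], d[p2])) {
      two <- TRUE
      if (p2 < p1) { tmp <- p1; p1 <- p2; p2 <- tmp }
    }
  }

  top <- max(sm)
  if (two) {
    lo <- min(p1, p2); hi <- max(p1, p2)
    v_idx <- lo + which.min(d[lo:hi]) - 1L
    plateau <- sm[v_idx]
    K1 <- max(plateau - base, 1e-3)
    K2 <- max(top - plateau, 1e-3)
    g <- list(
      list(K = K1, r = 4 * d[p1] / K1, m = tm[p1]),
      list(K = K2, r = 4 * d[p2] / K2, m = tm[p2]))
  } else {
    K <- max(top - base, 1e-3)
    g <- list(list(K = K, r = 4 * d[p1] / K, m = tm[p1]))
  }
  list(n_phases = if (two) 2L else 1L, baseline = base, guesses = g,
       smoothed = sm, deriv = d, no_growth = FALSE)
}

# One bounded nlsLM fit of a sum of n logistic components plus baseline.
# start: list(b, K = numeric(n), r = numeric(n), m = numeric(n))
fitLogisticSum <- function(t, od, start, t_lo, t_hi) {
  n_ph <- length(start$K)
  par0 <- c(b = start$b, K = start$K, r = start$r, m = start$m)
  names(par0) <- c("b", paste0("K", seq_len(n_ph)), paste0("r", seq_len(n_ph)),
                   paste0("m", seq_len(n_ph)))
  pred <- function(par) {
    y <- rep(par[["b"]], length(t))
    for (i in seq_len(n_ph))
      y <- y + logisticComponent(t, par[[paste0("K", i)]],
                                 par[[paste0("r", i)]], par[[paste0("m", i)]])
    y
  }
  # cap the shape rate at the sampling resolution: a transition narrower
  # than ~2 sampling intervals is not resolvable and only fits noise spikes
  r_max <- 2.2 / stats::median(diff(t))
  lower <- c(0, rep(1e-4, n_ph), rep(1e-3, n_ph), rep(t_lo - 24, n_ph))
  upper <- c(max(od), rep(2 * diff(range(od)) + 1, n_ph), rep(r_max, n_ph),
             rep(t_hi + 48, n_ph))
  par0 <- pmin(pmax(par0, lower), upper)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0,
                       fn = function(p) od - pred(as.list(p)),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  par <- as.list(stats::coef(fit))
  list(par = par, rss = sum(fit$fvec^2), info = fit$info,
       converged = fit$info %in% 1:4)
}

# Fit with a fixed phase count using multi-start (base guess + jitters).
fitNPhases <- function(t, od, seg, n_phases, n_starts, seed) {
  g <- seg$guesses
  if (length(g) < n_phases) {
    # promote a 1-phase guess to 2 phases by splitting the component
    g1 <- g[[1]]
    g <- list(list(K = g1$K * 0.6, r = g1$r, m = g1$m),
              list(K = g1$K * 0.4, r = g1$r, m = g1$m +
                     max(2, 0.25 * diff(range(t)))))
  } else if (length(g) > n_phases) {
    g <- g[order(-vapply(g, `[[`, numeric(1), "K"))][seq_len(n_phases)]
    g <- g[order(vapply(g, `[[`, numeric(1), "m"))]
  }
  base_start <- list(b = max(seg$baseline, 1e-4),
                     K = vapply(g, `[[`, numeric(1), "K"),
                     r = vapply(g, `[[`, numeric(1), "r"),
                     m = vapply(g, `[[`, numeric(1), "m"))
  starts <- list(base_start)
  if (n_starts > 1) {
    jit <- withr::with_seed(seed, lapply(seq_len(n_starts - 1), function(i)
      list(b = base_start$b,
           K = base_start$K * stats::runif(n_phases, 0.6, 1.4),
           r = base_start$r * stats::runif(n_phases, 0.5, 2),
           m = base_start$m + stats::runif(n_phases, -1.5, 1.5))))
    starts <- c(starts, jit)
  }
  fits <- lapply(starts, function(s)
    fitLogisticSum(t, od, s, min(t), max(t)))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(NULL)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  best$n_starts <- length(starts)
  best
}

growthFitFromPar <- function(par, n_phases, rss, aicc, converged, diag) {
  ord <- order(vapply(seq_len(n_phases),
                      function(i) par[[paste0("m", i)]], numeric(1)))
  rows <- lapply(seq_along(ord), function(j) {
    i <- ord[j]
    K <- par[[paste0("K", i)]]; r <- par[[paste0("r", i)]]
    m <- par[[paste0("m", i)]]
    ph <- logisticToPhase(K, r, m)
    data.frame(phase = j, lag_h = ph[["lag_h"]], max_rate = ph[["max_rate"]],
               saturation = ph[["saturation"]], K = K, r = r, m = m)
  })
  new("GrowthFit", n_phases = as.integer(n_phases), baseline = par[["b"]],
      phases = do.call(rbind, rows), rss = rss, aicc = aicc,
      converged = converged, diag = diag)
}

#' Fit a mono- or biphasic logistic growth model
#'
#' Bounded nonlinear least squares of
#' OD(t) = b + sum_i K_i / (1 + exp(-r_i (t - m_i))) with
#' \code{\link[minpack.lm]{nls.lm}}, multi-start (the segmentation guess plus
#' jittered restarts, deterministic given \code{seed}), reporting per phase
#' the saturation S_i = K_i, the maximal slope R_i = r_i K_i / 4 (OD/h), and
#' the tangent-intercept lag L_i = max(0, m_i - 2 / r_i). In \code{"auto"}
#' mode both phase-count hypotheses are fitted and the winner is chosen by
#' small-sample-corrected AIC with a 2-point preference margin for the
#' simpler model; in addition, a 2-phase candidate is only admitted when
#' both components are bona fide growth phases (amplitude at least 0.005 OD
#' and 5 percent of total growth, transition width resolvable at the
#' sampling rate, and components separated enough that a diauxic plateau
#' exists between them) — otherwise the simpler model wins. Flat curves
#' return a "no growth" fit with \code{nPhases() == 0}.
#'
#' @param curve a \code{\link{GrowthCurve}}
#' @param n_phases "auto", 1 or 2
#' @param seed integer seed for the jittered restarts
#' @param n_starts number of starts per hypothesis (default 5)
#' @param floor_od no-growth dynamic-range floor (OD)
#' @param valley_frac passed to \code{\link{segmentPhases}}
#' @return a \code{\link{GrowthFit}}; non-convergence after all starts is
#'   reported via \code{isConverged()} and the diagnostics list, never
#'   silently
#' @examples
#' gc <- genGrowthCurve(strainArchetype("sdh2"),
#'                      cfg = simConfig(seed = 5, media_mix = 1))
#' fitGrowth(gc, n_phases = 1)
#' @export
fitGrowth <- function(curve, n_phases = "auto", seed = 1L, n_starts = 5,
                      floor_od = 0.05, valley_frac = 0.3) {
  stopifnot(is(curve, "GrowthCurve"))
  t <- curve@times; od <- curve@od
  if (length(t) < 30) stop("need at least 30 points to fit a growth curve")
  n_phases <- as.character(n_phases)
  n_phases <- match.arg(n_phases, c("auto", "1", "2"))

  seg <- segmentPhases(curve, valley_frac = valley_frac, floor_od = floor_od)
  if (seg$no_growth) {
    return(new("GrowthFit", n_phases = 0L, baseline = seg$baseline,
               phases = data.frame(), rss = sum((od - seg$baseline)^2),
               aicc = NA_real_, converged = TRUE,
               diag = list(no_growth = TRUE)))
  }

  n <- length(od)
  tryHyp <- function(np) {
    f <- fitNPhases(t, od, seg, np, n_starts, childSeed(seed, np))
    if (is.null(f)) return(NULL)
    f$aicc <- aiccFromRSS(f$rss, n, k = 1 + 3 * np)
    f$np <- np
    f
  }

  # A competing 2-phase fit is only admissible when both components are
  # real growth phases: amplitude above the read-noise scale and at least
  # 5 percent of total growth, a transition width resolvable at the
  # sampling rate, and enough separation between the components that a
  # plateau (the diauxic shift) actually exists between them. Components
  # violating these are noise artifacts and defer to the simpler model.
  dt_med <- stats::median(diff(t))
  noise_est <- stats::mad(diff(od)) / sqrt(2)
  degenerate <- function(f) {
    K <- vapply(seq_len(f$np), function(i) f$par[[paste0("K", i)]], numeric(1))
    r <- vapply(seq_len(f$np), function(i) f$par[[paste0("r", i)]], numeric(1))
    m <- vapply(seq_len(f$np), function(i) f$par[[paste0("m", i)]], numeric(1))
    if (any(K < max(0.005, 0.05 * sum(K)))) return(TRUE)
    # a noise-amplitude component pinned at the resolvability cap is a
    # spike fitting a single read excursion, not a growth phase
    if (any(r > 0.95 * 2.2 / dt_med & K < 5 * noise_est)) return(TRUE)
    # a phase whose inflection lies outside the recorded window was never
    # observed: an extrapolated tail, not evidence of a second phase
    if (any(m < min(t) | m > max(t))) return(TRUE)
    if (f$np == 2L) {
      o <- order(m)
      if (diff(m[o]) < 2.2 / r[o[1]] + 2.2 / r[o[2]]) return(TRUE)
    }
    FALSE
  }

  if (n_phases == "auto") {
    f1 <- tryHyp(1L); f2 <- tryHyp(2L)
    cand <- Filter(Negate(is.null), list(f1, f2))
    if (!length(cand))
      return(new("GrowthFit", n_phases = seg$n_phases, baseline = seg$baseline,
                 phases = data.frame(), rss = NA_real_, aicc = NA_real_,
                 converged = FALSE,
                 diag = list(message = "all starts failed for both hypotheses")))
    pick <- if (!is.null(f1) && !is.null(f2)) {
      if (!f2$converged || degenerate(f2) || f2$aicc + 2 >= f1$aicc) f1 else f2
    } else cand[[1]]
    diag <- list(selection = "aicc",
                 aicc_1 = if (!is.null(f1)) f1$aicc else NA_real_,
                 aicc_2 = if (!is.null(f2)) f2$aicc else NA_real_,
                 rss_1 = if (!is.null(f1)) f1$rss else NA_real_,
                 rss_2 = if (!is.null(f2)) f2$rss else NA_real_,
                 n_starts = pick$n_starts, segment_hypothesis = seg$n_phases)
    growthFitFromPar(pick$par, pick$np, pick$rss, pick$aicc,
                     pick$converged, diag)
  } else {
    np <- as.integer(n_phases)
    f <- tryHyp(np)
    if (is.null(f))
      return(new("GrowthFit", n_phases = np, baseline = seg$baseline,
                 phases = data.frame(), rss = NA_real_, aicc = NA_real_,
                 converged = FALSE,
                 diag = list(message = "all starts failed")))
    growthFitFromPar(f$par, np, f$rss, f$aicc, f$converged,
                     list(n_starts = f$n_starts,
                          segment_hypothesis = seg$n_phases))
  }
}

#' Fitted OD values of a growth fit
#'
#' @param fit a \code{\link{GrowthFit}}
#' @param times time grid (h)
#' @return predicted OD600
#' @export
predictGrowth <- function(fit, times) {
  y <- rep(fit@baseline, length(times))
  if (fit@n_phases == 0L) return(y)
  for (i in seq_len(nrow(fit@phases)))
    y <- y + logisticComponent(times, fit@phases$K[i], fit@phases$r[i],
                               fit@phases$m[i])
  y
}

#' Plot a growth curve with its fit overlaid
#'
#' @param x a \code{\link{GrowthCurve}}
#' @param y optionally a \code{\link{GrowthFit}} to overlay
#' @param ... passed to \code{\link[graphics]{plot}}
#' @export
setMethod("plot", signature("GrowthCurve", "ANY"), function(x, y, ...) {
  graphics::plot(x@times, x@od, pch = 16, cex = 0.3, col = "grey40",
                 xlab = "time (h)", ylab = "OD600",
                 main = sprintf("%s %s", x@strain,
                                if (nzchar(x@compound_id))
                                  sprintf("+ %s (%g uM)", x@compound_id,
                                          x@conc_um) else ""), ...)
  if (!missing(y) && is(y, "GrowthFit"))
    graphics::lines(x@times, predictGrowth(y, x@times), col = "red3", lwd = 2)
  invisible(NULL)
})
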