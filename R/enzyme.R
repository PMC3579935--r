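#' Initial rate of an NADH-depletion progress curve
#'
#' Fits ordinary least-squares lines over expanding windows anchored at the
#' start of the A340 trace (from \code{min_points} points up to the full
#' curve) and returns the slope magnitude of the longest window whose linear
#' fit has R^2 at or above \code{r2_floor}. If no window qualifies the
#' \code{min_points} window is used and a "curvature" flag is raised. A
#' constant trace returns a zero rate with a "flat" flag; a trace that
#' rises beyond noise is flagged "increasing" (wrong assay direction).
#' Optionally converts the rate to uM NADH/min via the 6.22 mM^-1 cm^-1
#' extinction coefficient and a stated path length.
#'
#' @param time_min time points (minutes, >= min_points values)
#' @param a340 absorbance values at 340 nm
#' @param min_points minimum window length (>= 3, default 4)
#' @param r2_floor linearity requirement (default 0.98)
#' @param path_cm optical path length in cm; if given, \code{v0_um_min} is
#'   reported as well
#' @return list: v0 (delta A340/min, magnitude of the initial slope),
#'   window_used, r2, flags (character), slope (signed), and optionally
#'   v0_um_min
#' @examples
#' t <- seq(0, 20, 2)
#' initialRate(t, 1 - 0.01 * t)$v0  # 0.01, all points
#' @export
initialRate <- function(time_min, a340, min_points = 4, r2_floor = 0.98,
                        path_cm = NULL) {
  stopifnot(length(time_min) == length(a340))
  if (min_points < 3) stop("min_points must be >= 3")
  n <- length(a340)
  if (n < min_points) stop("fewer points than min_points")
  if (any(!is.finite(a340))) stop("a340 must be finite")

  flags <- character()
  if (diff(range(a340)) < 1e-9) {
    out <- list(v0 = 0, window_used = n, r2 = NA_real_,
                flags = "flat", slope = 0)
    if (!is.null(path_cm)) out$v0_um_min <- 0
    return(out)
  }

  slopes <- r2s <- rep(NA_real_, n)
  for (m in min_points:n) {
    tt <- time_min[1:m]; yy <- a340[1:m]
    fit <- stats::lm.fit(cbind(1, tt), yy)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((yy - mean(yy))^2)
    slopes[m] <- fit$coefficients[2]
    r2s[m] <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  }
  ok <- which(r2s >= r2_floor)
  if (length(ok)) {
    m <- max(ok)
  } else {
    m <- min_points
    flags <- c(flags, "curvature")
  }
  slope <- slopes[m]
  if (slope > 0) {
    # rising absorbance: flag if the rise exceeds the residual noise scale
    noise <- stats::mad(diff(a340)) / sqrt(2)
    if (slope * diff(range(time_min)) > 3 * max(noise, 1e-12))
      flags <- c(flags, "increasing")
  }
  out <- list(v0 = max(0, -slope), window_used = m, r2 = r2s[m],
              flags = flags, slope = slope)
  if (!is.null(path_cm))
    out$v0_um_min <- out$v0 / (6.22 * path_cm) * 1000  # A/min -> uM/min
  out
}

#' Initial rates for a set of progress curves
#'
#' Applies \code{\link{initialRate}} to every (compound, concentration,
#' replicate) progress curve in a long-format table.
#'
#' @param progress data.frame with columns compound_id, conc_um, replicate,
#'   time_min, a340 (an optional \code{run} column is carried through)
#' @param ... passed to \code{\link{initialRate}}
#' @return data.frame: compound_id, (run,) conc_um, replicate, v0,
#'   window_used, r2, flags
#' @export
enzymeRates <- function(progress, ...) {
  need <- c("compound_id", "conc_um", "replicate", "time_min", "a340")
  if (!all(need %in% names(progress)))
    stop("progress table must have columns: ", paste(need, collapse = ", "))
  has_run <- "run" %in% names(progress)
  keys <- c("compound_id", if (has_run) "run", "conc_um", "replicate")
  sp <- split(progress, progress[keys], drop = TRUE)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$time_min), ]
    r <- initialRate(d$time_min, d$a340, ...)
    cbind(d[1, keys, drop = FALSE],
          data.frame(v0 = r$v0, window_used = r$window_used, r2 = r$r2,
                     flags = paste(r$flags, collapse = ";")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[keys]), ]
}

#' Enzyme-inhibition IC50 from progress curves
#'
#' Computes initial rates for every record, averages replicates per
#' concentration, normalizes to the zero-inhibitor mean rate, and delegates
#' to \code{\link{fitIC50}}. When the table carries a \code{run} column
#' (independent assay repetitions) each run is fitted separately and the
#' per-run IC50s and their mean are reported.
#'
#' @param progress long progress-curve table (see \code{\link{enzymeRates}});
#'   must contain zero-inhibitor wells
#' @param hill,bootstrap,seed passed to \code{\link{fitIC50}}
#' @param asymptotes passed to \code{\link{fitIC50}}. Rates are normalized
#'   to the zero-inhibitor mean, which itself carries estimation error, so
#'   the default "bottom0" fixes the lower plateau at zero activity while
#'   letting the top float rather than forcing the curve through 1
#' @param ... passed to \code{\link{initialRate}}
#' @return list: fit (pooled \code{DoseResponseFit}), rates (per-well rate
#'   table), per_run (data.frame of per-run IC50s, if runs present),
#'   ic50_mean
#' @export
enzymeInhibitionIC50 <- function(progress, hill = "free",
                                 asymptotes = "bottom0", bootstrap = 0,
                                 seed = 1L, ...) {
  rates <- enzymeRates(progress, ...)
  if (!any(rates$conc_um == 0))
    stop("missing zero-inhibitor wells: cannot normalize rates")

  fitSub <- function(r) {
    v0_ref <- mean(r$v0[r$conc_um == 0])
    if (v0_ref <= 0) stop("zero-inhibitor rate is zero; cannot normalize")
    agg <- stats::aggregate(v0 ~ conc_um, data = r, FUN = mean)
    agg$sd <- stats::aggregate(v0 ~ conc_um, data = r,
                               FUN = stats::sd)$v0
    agg$response <- agg$v0 / v0_ref
    if (max(agg$response[agg$conc_um > 0]) < 0.1) {
      # every tested concentration abolishes activity: the dilution range
      # carries no dose information, only the zero anchor differs
      fit <- new("DoseResponseFit", ic50 = NA_real_, hill = NA_real_,
                 top = 1, bottom = 0, rss = NA_real_,
                 ci_ic50 = c(NA_real_, NA_real_), converged = FALSE,
                 diag = list(flags = list("flat_at_zero"), flat = TRUE))
    } else {
      fit <- fitIC50(agg$conc_um, agg$response, hill = hill,
                     asymptotes = asymptotes, bootstrap = bootstrap,
                     seed = seed)
    }
    list(fit = fit, table = agg)
  }

  has_run <- "run" %in% names(rates)
  if (has_run) {
    runs <- split(rates, rates$run)
    subs <- lapply(runs, fitSub)
    ic50s <- vapply(subs, function(s)
      if (s$fit@converged) s$fit@ic50 else NA_real_, numeric(1))
    pooled <- fitSub(rates)
    list(fit = pooled$fit, rates = rates,
         per_run = data.frame(run = names(runs), ic50 = ic50s,
                              row.names = NULL),
         ic50_mean = mean(ic50s, na.rm = TRUE),
         response_table = pooled$table)
  } else {
    pooled <- fitSub(rates)
    list(fit = pooled$fit, rates = rates, per_run = NULL,
         ic50_mean = if (pooled$fit@converged) pooled$fit@ic50 else NA_real_,
         response_table = pooled$table)
  }
}
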