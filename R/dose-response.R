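#' Design an exact serial dilution series
#'
#' Geometric series c_k = top / fold^(k - 1), k = 1..n. The ratio of
#' consecutive concentrations is exactly \code{fold}.
#'
#' @param top_conc top concentration (uM, > 0)
#' @param fold dilution factor (> 1)
#' @param n_points number of points (>= 2)
#' @return a \code{\link{DilutionSeries-class}} object
#' @examples
#' serialDilution(62.5, 5, 8)  # bottom = 0.0008 uM = 0.8 nM
#' @export
serialDilution <- function(top_conc, fold, n_points) {
  if (top_conc <= 0) stop("top_conc must be > 0")
  if (fold <= 1) stop("fold must be > 1")
  if (n_points < 2) stop("n_points must be >= 2")
  new("DilutionSeries", top_conc = as.numeric(top_conc),
      fold = as.numeric(fold), n_points = as.integer(n_points),
      concentrations = top_conc / fold^(seq_len(n_points) - 1))
}

# 4PL prediction; conc may contain zeros (response = top there).
fourPL <- function(conc, top, bottom, lic50, hill) {
  ratio <- ifelse(conc > 0, (conc / exp(lic50))^hill, 0)
  bottom + (top - bottom) / (1 + ratio)
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Fits response(c) = bottom + (top - bottom) / (1 + (c / IC50)^hill) by
#' bounded least squares on log concentration, multi-starting the IC50 over
#' a grid spanning the tested dilution range. The Hill slope is free by
#' default and can be fixed at 1. Asymptotes are free by default; for
#' responses already normalized to fractional activity, the "normalized"
#' mode fixes top = 1 and bottom = 0, which keeps the IC50 identified when
#' the tested range does not reach the lower plateau, and the "bottom0"
#' mode fixes only bottom = 0 while letting the top float — the usual
#' choice when responses are normalized to a control mean that itself
#' carries estimation error, so the curve is not forced through 1. Zero-concentration
#' anchor points are allowed (they pin the top asymptote). Responses that
#' are flat across the dilution range give a non-converged result with a
#' "flat" diagnostic. A percentile bootstrap confidence interval for the
#' IC50 (residual resampling) is available.
#'
#' @param conc concentrations (>= 0; at least 4 distinct values)
#' @param response responses (normalized rates or maximal growth)
#' @param hill "free" or "fixed1"
#' @param asymptotes "free" (top and bottom fitted), "normalized"
#'   (top = 1, bottom = 0), or "bottom0" (bottom = 0, top fitted)
#' @param bootstrap number of bootstrap resamples for the IC50 CI (0 = off)
#' @param seed integer seed (bootstrap resampling)
#' @return a \code{\link{DoseResponseFit-class}} object; the diagnostics
#'   list carries \code{flat}, \code{extrapolated} and the tested span
#' @examples
#' cs <- concentrations(serialDilution(100, 4, 8))
#' fitIC50(cs, 1 / (1 + cs / 10))  # IC50 = 10
#' @export
fitIC50 <- function(conc, response, hill = c("free", "fixed1"),
                    asymptotes = c("free", "normalized", "bottom0"),
                    bootstrap = 0, seed = 1L) {
  hill <- match.arg(hill)
  asymptotes <- match.arg(asymptotes)
  stopifnot(length(conc) == length(response))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (any(!is.finite(response))) stop("responses must be finite")
  pos <- sort(unique(conc[conc > 0]))
  if (length(pos) < 4) stop("need at least 4 distinct positive concentrations")

  rng <- diff(range(response))
  if (rng < 0.02 * max(abs(response), 1e-12)) {
    return(new("DoseResponseFit", ic50 = NA_real_, hill = NA_real_,
               top = mean(response), bottom = mean(response),
               rss = 0, ci_ic50 = c(NA_real_, NA_real_), converged = FALSE,
               diag = list(flags = list("flat"), flat = TRUE)))
  }

  # monotonicity check (warn only): mean response should not rise with dose
  mresp <- vapply(pos, function(p) mean(response[conc == p]), numeric(1))
  mono_viol <- mean(diff(mresp) > 0.1 * rng) > 0.5
  if (mono_viol)
    warning("responses increase with concentration beyond noise; fitting anyway")

  fitOne <- function(lic50_0) {
    free <- hill == "free"
    fit_top <- asymptotes != "normalized"
    fit_bottom <- asymptotes == "free"
    par0 <- c(if (fit_top) c(top = max(response)),
              if (fit_bottom) c(bottom = min(response)),
              lic50 = lic50_0, if (free) c(hill = 1))
    lower <- c(rep(min(response) - rng, fit_top + fit_bottom),
               log(min(pos)) - log(1e3), if (free) 0.2)
    upper <- c(rep(max(response) + rng, fit_top + fit_bottom),
               log(max(pos)) + log(1e3), if (free) 10)
    fn <- function(p) {
      p <- as.list(p)
      response - fourPL(conc, p$top %||% 1, p$bottom %||% 0, p$lic50,
                        if (free) p$hill else 1)
    }
    f <- tryCatch(minpack.lm::nls.lm(par = par0, fn = fn, lower = lower,
                                     upper = upper,
                                     control = minpack.lm::nls.lm.control(maxiter = 200)),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    list(par = as.list(stats::coef(f)), rss = sum(f$fvec^2),
         converged = f$info %in% 1:4)
  }

  grid <- log(unique(c(pos, sqrt(pos[-1] * pos[-length(pos)]),
                       exp(mean(log(pos))))))
  fits <- Filter(Negate(is.null), lapply(grid, fitOne))
  if (!length(fits))
    return(new("DoseResponseFit", ic50 = NA_real_, hill = NA_real_,
               top = NA_real_, bottom = NA_real_, rss = NA_real_,
               ci_ic50 = c(NA_real_, NA_real_), converged = FALSE,
               diag = list(flags = list("no_fit"))))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  p <- best$par
  est_ic50 <- exp(p$lic50)
  est_hill <- if (hill == "free") p$hill else 1
  est_top <- p$top %||% 1; est_bottom <- p$bottom %||% 0
  # enforce bottom <= top in the report (swap never occurs for inhibition data)
  top <- max(est_top, est_bottom); bottom <- min(est_top, est_bottom)
  extrap <- est_ic50 < min(pos) || est_ic50 > max(pos)

  ci <- c(NA_real_, NA_real_)
  if (bootstrap > 0 && best$converged) {
    fitted <- fourPL(conc, est_top, est_bottom, p$lic50, est_hill)
    res <- response - fitted
    boots <- withr::with_seed(seed, vapply(seq_len(bootstrap), function(b) {
      yb <- fitted + sample(res, replace = TRUE)
      fb <- tryCatch({
        fn <- function(q) {
          q <- as.list(q)
          yb - fourPL(conc, q$top %||% 1, q$bottom %||% 0, q$lic50,
                      if (hill == "free") q$hill else 1)
        }
        f <- minpack.lm::nls.lm(par = unlist(p), fn = fn,
                                control = minpack.lm::nls.lm.control(maxiter = 100))
        exp(stats::coef(f)[["lic50"]])
      }, error = function(e) NA_real_)
      fb
    }, numeric(1)))
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }

  new("DoseResponseFit", ic50 = est_ic50, hill = est_hill, top = top,
      bottom = bottom, rss = best$rss, ci_ic50 = ci,
      converged = best$converged,
      diag = list(flags = list(), flat = FALSE, extrapolated = extrap,
                  tested_range = range(pos), n_boot = bootstrap,
                  monotonicity_warning = mono_viol))
}

#' IC50 fold differential between two strains
#'
#' Returns IC50(reference) / IC50(mutant); values above 1 indicate the
#' mutant strain is more sensitive to the compound.
#'
#' @param fit_ref \code{DoseResponseFit} (or numeric IC50) of the reference
#'   strain
#' @param fit_mut \code{DoseResponseFit} (or numeric IC50) of the mutant
#' @return fold differential
#' @examples
#' ic50Ratio(70, 5)  # 14-fold
#' @export
ic50Ratio <- function(fit_ref, fit_mut) {
  val <- function(x, lab) {
    if (is(x, "DoseResponseFit")) {
      if (!x@converged) stop(lab, " fit has not converged")
      x@ic50
    } else as.numeric(x)
  }
  val(fit_ref, "reference") / val(fit_mut, "mutant")
}
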