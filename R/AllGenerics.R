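#' @include AllClasses.R
NULL

#' Accessors for growth curves and fits
#'
#' \code{timePoints} and \code{odValues} return the time grid (h) and OD600
#' trace of a \code{GrowthCurve}; \code{groundTruth} returns the generator's
#' ground-truth list (empty for curves built from real data);
#' \code{strainName} the strain identifier.
#'
#' @param object a \code{GrowthCurve}, \code{GrowthFit} or
#'   \code{DoseResponseFit}
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("odValues", function(object) standardGeneric("odValues"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("strainName", function(object) standardGeneric("strainName"))

#' @rdname accessors
#' @export
setMethod("timePoints", "GrowthCurve", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("odValues", "GrowthCurve", function(object) object@od)
#' @rdname accessors
#' @export
setMethod("groundTruth", "GrowthCurve", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("strainName", "GrowthCurve", function(object) object@strain)
#' @rdname accessors
#' @export
setMethod("strainName", "StrainArchetype", function(object) object@name)

#' @rdname accessors
#' @export
setGeneric("nPhases", function(object) standardGeneric("nPhases"))
#' @rdname accessors
#' @export
setMethod("nPhases", "GrowthFit", function(object) object@n_phases)

#' @rdname accessors
#' @export
setGeneric("baselineOD", function(object) standardGeneric("baselineOD"))
#' @rdname accessors
#' @export
setMethod("baselineOD", "GrowthFit", function(object) object@baseline)

#' Per-phase fitted parameters
#'
#' Returns the phase table of a \code{GrowthFit}: one row per phase with
#' columns \code{phase}, \code{lag_h}, \code{max_rate} (OD/h),
#' \code{saturation} (OD), and the underlying logistic parameters
#' \code{K}, \code{r}, \code{m}.
#'
#' @param object a \code{GrowthFit}
#' @export
setGeneric("phaseParameters", function(object) standardGeneric("phaseParameters"))
#' @rdname phaseParameters
#' @export
setMethod("phaseParameters", "GrowthFit", function(object) object@phases)

#' Total saturation of a fitted curve
#'
#' Total growth above baseline: the sum of per-phase saturation increments,
#' equal to the fitted asymptote minus the baseline. This is the "maximum
#' saturation reached by either phase" quantity used in differential scoring.
#'
#' @param object a \code{GrowthFit}
#' @export
setGeneric("totalSaturation", function(object) standardGeneric("totalSaturation"))
#' @rdname totalSaturation
#' @export
setMethod("totalSaturation", "GrowthFit", function(object) {
  if (object@n_phases == 0L) 0 else sum(object@phases$saturation)
})

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "GrowthFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("isConverged", "DoseResponseFit", function(object) object@converged)

#' Dose-response accessors
#'
#' @param object a \code{DoseResponseFit}
#' @name dr-accessors
NULL

#' @rdname dr-accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @rdname dr-accessors
#' @export
setMethod("ic50", "DoseResponseFit", function(object) object@ic50)
#' @rdname dr-accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))
#' @rdname dr-accessors
#' @export
setMethod("hillSlope", "DoseResponseFit", function(object) object@hill)
#' @rdname dr-accessors
#' @export
setGeneric("ic50CI", function(object) standardGeneric("ic50CI"))
#' @rdname dr-accessors
#' @export
setMethod("ic50CI", "DoseResponseFit", function(object) object@ci_ic50)

#' Concentrations of a dilution series
#'
#' @param object a \code{DilutionSeries}
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @rdname concentrations
#' @export
setMethod("concentrations", "DilutionSeries", function(object) object@concentrations)

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: read every %g min for %g h, noise sd %g OD, media mix %g, seed %d\n",
              object@sampling_interval, object@duration, object@noise_sd,
              object@media_mix, object@seed))
})

setMethod("show", "StrainArchetype", function(object) {
  cat(sprintf("StrainArchetype '%s' (baseline %.3g OD)\n", object@name, object@baseline_od))
  fmt <- function(p) sprintf("lag %.3g h, max rate %.3g OD/h, saturation %.3g OD",
                             p[["lag_h"]], p[["max_rate"]], p[["saturation"]])
  cat("  phase 1 (glycolytic): ",
      if (object@phase1_competent) fmt(object@phase1_params) else "absent", "\n", sep = "")
  cat("  phase 2 (respiratory): ",
      if (object@phase2_competent) fmt(object@phase2_params) else "absent", "\n", sep = "")
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve: strain %s, %s, %d points over %.3g h (OD %.3g-%.3g)\n",
              object@strain,
              if (nzchar(object@compound_id))
                sprintf("%s at %g uM", object@compound_id, object@conc_um)
              else "no compound",
              length(object@times), max(object@times),
              min(object@od), max(object@od)))
  if (length(object@truth)) cat("  (synthetic; ground truth attached)\n")
})

setMethod("show", "GrowthFit", function(object) {
  if (object@n_phases == 0L) {
    cat("GrowthFit: no growth (flat curve)\n")
    return(invisible(NULL))
  }
  cat(sprintf("GrowthFit: %d phase(s), baseline %.4g OD, RSS %.4g, %s\n",
              object@n_phases, object@baseline, object@rss,
              if (object@converged) "converged" else "NOT converged"))
  print(object@phases[, c("phase", "lag_h", "max_rate", "saturation")],
        row.names = FALSE, digits = 4)
})

setMethod("show", "DoseResponseFit", function(object) {
  if (!object@converged) {
    cat("DoseResponseFit: not converged (",
        paste(unlist(object@diag$flags), collapse = ", "), ")\n", sep = "")
    return(invisible(NULL))
  }
  cat(sprintf("DoseResponseFit: IC50 %.4g, hill %.3g, top %.3g, bottom %.3g, RSS %.4g\n",
              object@ic50, object@hill, object@top, object@bottom, object@rss))
  if (all(is.finite(object@ci_ic50)))
    cat(sprintf("  95%% CI (bootstrap): [%.4g, %.4g]\n",
                object@ci_ic50[1], object@ci_ic50[2]))
  if (isTRUE(object@diag$extrapolated))
    cat("  warning: IC50 outside tested concentration span (extrapolated)\n")
})

setMethod("show", "DilutionSeries", function(object) {
  cat(sprintf("DilutionSeries: %d points, %g-fold from %g uM down to %g uM\n",
              object@n_points, object@fold, object@top_conc,
              min(object@concentrations)))
})

setMethod("show", "DispenseProtocol", function(object) {
  cat(sprintf("DispenseProtocol: %g x %g nL droplets of %g mM stock in %s\n",
              object@n_droplets, object@droplet_vol_nl, object@stock_conc_mm,
              object@solvent))
  cat(sprintf("  volumes (uL): %g predispensed + %g top-up + %g inoculum\n",
              object@predispensed_vol_ul, object@topup_vol_ul,
              object@inoculum_vol_ul))
})
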