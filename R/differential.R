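#' Differential growth-inhibition scores
#'
#' Quantifies how differently a compound inhibits the mutant and reference
#' strains from the four growth fits of the matched quadruple
#' (mutant/reference, with/without drug at the same concentration and
#' media). With S the total saturation reached across the phases of growth
#' and R, L the maximal rate and lag of the glycolytic (first) phase:
#' \deqn{\Delta S = S_{ref,drug}/S_{ref,ctrl} - S_{mut,drug}/S_{mut,ctrl}}
#' \deqn{\Delta R = R_{ref,drug}/R_{ref,ctrl} - R_{mut,drug}/R_{mut,ctrl}}
#' \deqn{\Delta L = L_{mut,drug}/L_{mut,ctrl} - L_{ref,drug}/L_{ref,ctrl}}
#' The lag difference is oriented so that, like the saturation and rate
#' differences, positive values always indicate greater inhibition of the
#' mutant (drug-induced lag grows under inhibition while saturation and rate
#' shrink). A control lag below \code{lag_floor} hours is replaced by the
#' floor before forming the ratio. A drugged curve scored "no growth"
#' contributes zero saturation (complete inhibition).
#' When a drugged culture reaches less than \code{kinetic_floor} of
#' its control saturation, its rate and lag ratios are suppressed (NA):
#' the kinetics of a culture that barely grew are not reliably
#' quantifiable, and the saturation delta already carries the inhibition
#' signal.
#'
#' @param fit_mut_ctrl,fit_mut_drug,fit_ref_ctrl,fit_ref_drug
#'   \code{\link{GrowthFit}} objects for the four conditions
#' @param compound_id compound identifier
#' @param conc_um tested concentration (uM)
#' @param lag_floor minimum control lag (h) used in the lag ratio
#' @param kinetic_floor minimum drugged/control saturation ratio below
#'   which a strain's rate and lag ratios are not quantified
#' @return one-row data.frame: compound_id, conc_um, delta_S, delta_R,
#'   delta_L, indeterminate
#' @export
deltaScores <- function(fit_mut_ctrl, fit_mut_drug, fit_ref_ctrl,
                        fit_ref_drug, compound_id = "", conc_um = NA_real_,
                        lag_floor = 0.25, kinetic_floor = 0.15) {
  fits <- list(fit_mut_ctrl, fit_mut_drug, fit_ref_ctrl, fit_ref_drug)
  stopifnot(all(vapply(fits, is, logical(1), "GrowthFit")))
  bad <- !vapply(fits, isConverged, logical(1))
  indeterminate <- any(bad)

  phase1 <- function(f, what) {
    if (f@n_phases == 0L) return(if (what == "lag_h") NA_real_ else 0)
    f@phases[[what]][1]
  }
  S <- vapply(fits, totalSaturation, numeric(1))
  R <- vapply(fits, phase1, numeric(1), what = "max_rate")
  L <- vapply(fits, phase1, numeric(1), what = "lag_h")
  names(S) <- names(R) <- names(L) <-
    c("mut_ctrl", "mut_drug", "ref_ctrl", "ref_drug")

  eps <- 1e-6
  if (!indeterminate && (S[["mut_ctrl"]] < eps || S[["ref_ctrl"]] < eps ||
                         R[["mut_ctrl"]] < eps || R[["ref_ctrl"]] < eps))
    indeterminate <- TRUE  # a control culture that did not grow cannot anchor ratios

  if (indeterminate) {
    return(data.frame(compound_id = compound_id, conc_um = conc_um,
                      delta_S = NA_real_, delta_R = NA_real_,
                      delta_L = NA_real_, indeterminate = TRUE,
                      stringsAsFactors = FALSE))
  }

  sr_mut <- S[["mut_drug"]] / S[["mut_ctrl"]]
  sr_ref <- S[["ref_drug"]] / S[["ref_ctrl"]]
  delta_S <- sr_ref - sr_mut
  # kinetics of a barely-growing culture are not quantifiable
  kin_mut <- sr_mut >= kinetic_floor
  kin_ref <- sr_ref >= kinetic_floor
  delta_R <- if (kin_mut && kin_ref)
    R[["ref_drug"]] / R[["ref_ctrl"]] - R[["mut_drug"]] / R[["mut_ctrl"]]
  else NA_real_
  lagRatio <- function(drug, ctrl) {
    if (is.na(drug)) return(NA_real_)
    drug / max(ctrl, lag_floor)
  }
  lr_mut <- if (kin_mut) lagRatio(L[["mut_drug"]], L[["mut_ctrl"]]) else NA_real_
  lr_ref <- if (kin_ref) lagRatio(L[["ref_drug"]], L[["ref_ctrl"]]) else NA_real_
  delta_L <- if (is.na(lr_mut) || is.na(lr_ref)) NA_real_ else lr_mut - lr_ref

  data.frame(compound_id = compound_id, conc_um = conc_um,
             delta_S = delta_S, delta_R = delta_R, delta_L = delta_L,
             indeterminate = FALSE, stringsAsFactors = FALSE)
}

#' Classify a differential score
#'
#' A compound is called \code{mutant_selective} when any differential
#' exceeds its positive threshold (strictly), \code{reference_selective}
#' when any falls strictly below the negative threshold, and
#' \code{nonselective} otherwise; a delta exactly at the threshold stays
#' nonselective. When metrics exceed their thresholds in opposite
#' directions the call follows the metric with the largest
#' threshold-normalized magnitude (an exact tie, or an indeterminate score
#' from a failed fit in the quadruple, gives \code{indeterminate}).
#'
#' @param score one-row data.frame from \code{\link{deltaScores}}
#' @param thresholds named numeric (delta_S, delta_R, delta_L) or one number
#'   recycled to all three metrics; must be given explicitly
#' @return character call
#' @examples
#' s <- data.frame(delta_S = 0.7, delta_R = 0, delta_L = 0,
#'                 indeterminate = FALSE)
#' classifyCall(s, 0.3)  # "mutant_selective"
#' @export
classifyCall <- function(score, thresholds) {
  if (missing(thresholds)) stop("classification thresholds must be explicit")
  if (length(thresholds) == 1L)
    thresholds <- c(delta_S = thresholds, delta_R = thresholds,
                    delta_L = thresholds)
  if (isTRUE(score$indeterminate)) return("indeterminate")
  deltas <- c(delta_S = score$delta_S, delta_R = score$delta_R,
              delta_L = score$delta_L)
  use <- !is.na(deltas)
  thr <- thresholds[names(deltas)]
  up <- any(deltas[use] > thr[use])
  down <- any(deltas[use] < -thr[use])
  if (up && down) {
    norm <- deltas[use] / thr[use]
    hi <- max(norm); lo <- min(norm)
    if (isTRUE(all.equal(hi, -lo))) "indeterminate"
    else if (hi > -lo) "mutant_selective"
    else "reference_selective"
  } else if (up) "mutant_selective"
  else if (down) "reference_selective"
  else "nonselective"
}

#' Marker-strain concordance check
#'
#' Confirms that drug effects on the reference strain and on the
#' marker-bearing control strain are indistinguishable, compound by
#' compound: for each growth parameter the drug/control ratio is formed in
#' both strains and the relative difference must not exceed
#' \code{tolerance}. A discordant compound is flagged as a possible marker
#' (resistance-cassette acetyltransferase) artifact rather than a
#' consequence of the mutation under study.
#'
#' @param fits_ref named list, one entry per compound, each a list with
#'   \code{ctrl} and \code{drug} \code{\link{GrowthFit}}s for the reference
#'   strain
#' @param fits_marker same structure for the marker-control strain; compound
#'   names must match
#' @param tolerance maximum relative difference of parameter ratios
#' @param lag_floor minimum control lag (h), as in \code{\link{deltaScores}}
#' @return list: \code{concordant} (logical, all compounds concordant) and
#'   \code{report} data.frame (compound_id, rel_diff_S, rel_diff_R,
#'   rel_diff_L, concordant)
#' @export
markerConcordance <- function(fits_ref, fits_marker, tolerance = 0.2,
                              lag_floor = 0.25) {
  if (!length(fits_ref) || !length(fits_marker))
    stop("empty comparison set: concordance cannot be assessed")
  ids <- names(fits_ref)
  if (!setequal(ids, names(fits_marker)))
    stop("unmatched compounds between reference and marker strain fit sets")

  ratios <- function(pair) {
    ctrl <- pair$ctrl; drug <- pair$drug
    p1 <- function(f, what) {
      if (f@n_phases == 0L) return(if (what == "lag_h") NA_real_ else 0)
      f@phases[[what]][1]
    }
    c(S = totalSaturation(drug) / totalSaturation(ctrl),
      R = p1(drug, "max_rate") / p1(ctrl, "max_rate"),
      L = {
        ld <- p1(drug, "lag_h"); lc <- p1(ctrl, "lag_h")
        if (is.na(ld) || is.na(lc)) NA_real_ else ld / max(lc, lag_floor)
      })
  }
  rows <- lapply(ids, function(id) {
    rr <- ratios(fits_ref[[id]])
    rm <- ratios(fits_marker[[id]])
    rel <- abs(rr - rm) / pmax(abs(rr), 1e-6)
    ok <- all(rel <= tolerance, na.rm = TRUE)
    data.frame(compound_id = id, rel_diff_S = rel[["S"]],
               rel_diff_R = rel[["R"]], rel_diff_L = rel[["L"]],
               concordant = ok, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(concordant = all(report$concordant), report = report)
}
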