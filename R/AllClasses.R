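#' @import methods
NULL

#' Simulation configuration
#'
#' Sampling and noise settings shared by every synthetic-data generator.
#' Defaults emulate the plate-reader protocol used throughout the package:
#' one OD600 reading every 6 minutes over 48 h, additive Gaussian read noise,
#' and a fermentable/non-fermentable media mix (1 = all fermentable).
#'
#' @slot sampling_interval numeric, minutes between reads (> 0)
#' @slot duration numeric, total duration in hours (> 0)
#' @slot noise_sd numeric, sd of additive Gaussian noise in absorbance units
#' @slot seed integer seed; identical seeds give bit-identical output
#' @slot media_mix numeric in [0, 1], fraction of fermentable carbon
#' @export
setClass("SimConfig", representation(
  sampling_interval = "numeric",
  duration          = "numeric",
  noise_sd          = "numeric",
  seed              = "integer",
  media_mix         = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@sampling_interval) != 1L || object@sampling_interval <= 0)
    msg <- c(msg, "sampling_interval must be a single positive number (minutes)")
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number (hours)")
  if (length(object@noise_sd) != 1L || object@noise_sd < 0)
    msg <- c(msg, "noise_sd must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@media_mix) != 1L || object@media_mix < 0 || object@media_mix > 1)
    msg <- c(msg, "media_mix must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param sampling_interval minutes between reads
#' @param duration total duration (h)
#' @param noise_sd additive Gaussian noise sd (absorbance units)
#' @param seed integer seed
#' @param media_mix fraction fermentable carbon in [0, 1]
#' @return a \code{SimConfig}
#' @rdname SimConfig-class
#' @examples
#' simConfig(seed = 1, media_mix = 0.5)
#' @export
simConfig <- function(sampling_interval = 6, duration = 48, noise_sd = 0.01,
                      seed = 1L, media_mix = 0.5) {
  new("SimConfig",
      sampling_interval = as.numeric(sampling_interval),
      duration = as.numeric(duration),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed),
      media_mix = as.numeric(media_mix))
}

#' Strain growth archetype
#'
#' Ground-truth growth phenotype of a yeast strain on mixed
#' fermentable/non-fermentable media. Phase 1 is the glycolytic
#' (fermentative) phase; phase 2 is the respiratory phase entered after the
#' diauxic shift. A respiration-deficient (SDH-null) strain is modelled by
#' \code{phase2_competent = FALSE}. Each phase is parameterised by the three
#' quantities reported by the curve fitter: lag time (h), maximal growth rate
#' (OD/h, the steepest slope), and maximal saturation (OD increment above
#' baseline).
#'
#' @slot name strain identifier ("wt", "sdh2", "nhp6a", or custom)
#' @slot phase1_competent,phase2_competent logical phase competence
#' @slot phase1_params,phase2_params named numeric (lag_h, max_rate, saturation)
#' @slot baseline_od non-growing optical density (media + inoculum)
#' @export
setClass("StrainArchetype", representation(
  name             = "character",
  phase1_competent = "logical",
  phase2_competent = "logical",
  phase1_params    = "numeric",
  phase2_params    = "numeric",
  baseline_od      = "numeric"
))

setValidity("StrainArchetype", function(object) {
  msg <- character()
  chk <- function(p, lab) {
    if (!all(c("lag_h", "max_rate", "saturation") %in% names(p)))
      return(sprintf("%s must have lag_h, max_rate, saturation", lab))
    if (p[["lag_h"]] < 0) return(sprintf("%s lag_h must be >= 0", lab))
    if (p[["max_rate"]] <= 0 || p[["saturation"]] <= 0)
      return(sprintf("%s rate and saturation must be > 0", lab))
    NULL
  }
  if (object@phase1_competent) msg <- c(msg, chk(object@phase1_params, "phase1_params"))
  if (object@phase2_competent) msg <- c(msg, chk(object@phase2_params, "phase2_params"))
  if (object@baseline_od < 0) msg <- c(msg, "baseline_od must be >= 0")
  if (identical(object@name, "sdh2") && object@phase2_competent)
    msg <- c(msg, "the sdh2 archetype is respiration-deficient: phase2_competent must be FALSE")
  if (length(msg)) msg else TRUE
})

#' Built-in strain archetypes
#'
#' \code{strainArchetype("wt")} is the reference strain with both glycolytic
#' and respiratory phases; \code{"sdh2"} lacks the respiratory phase (cannot
#' engage the TCA cycle); \code{"nhp6a"} is the marker-control strain,
#' phenotypically identical to wild type. Pass \code{phase1}, \code{phase2},
#' \code{baseline_od} to override the defaults, or \code{name = "custom"} to
#' build an arbitrary strain.
#'
#' @param name one of "wt", "sdh2", "nhp6a", "custom"
#' @param phase1,phase2 named numeric vectors (lag_h, max_rate, saturation),
#'   or NULL to drop the phase (custom strains)
#' @param baseline_od baseline optical density
#' @return a \code{StrainArchetype}
#' @examples
#' wt <- strainArchetype("wt")
#' mut <- strainArchetype("sdh2")
#' @export
strainArchetype <- function(name = c("wt", "sdh2", "nhp6a", "custom"),
                            phase1 = c(lag_h = 4, max_rate = 0.12, saturation = 0.55),
                            phase2 = c(lag_h = 18, max_rate = 0.05, saturation = 0.50),
                            baseline_od = 0.05) {
  name <- match.arg(name)
  p1_ok <- !is.null(phase1)
  p2_ok <- !is.null(phase2) && name != "sdh2"
  new("StrainArchetype",
      name = name,
      phase1_competent = p1_ok,
      phase2_competent = p2_ok,
      phase1_params = if (p1_ok) phase1 else c(lag_h = 0, max_rate = 1, saturation = 1),
      phase2_params = if (p2_ok) phase2 else c(lag_h = 0, max_rate = 1, saturation = 1),
      baseline_od = as.numeric(baseline_od))
}

#' Drug effect model
#'
#' Ground-truth concentration-dependent action of a compound on growth
#' parameters, per strain. Each affected parameter carries a saturable Hill
#' response: at concentration c the occupancy is
#' f(c) = c^h / (c^h + ec50^h), and
#' \itemize{
#'   \item saturation is multiplied by 1 - (1 - sat_mult) f(c),
#'   \item maximal rate is multiplied by 1 - (1 - rate_mult) f(c),
#'   \item lag is increased by add_lag_h * f(c).
#' }
#' \code{sat_mult} and \code{rate_mult} are the asymptotic (full-occupancy)
#' multipliers in (0, 1]; \code{add_lag_h >= 0} is the asymptotic added lag.
#' The per-strain table is keyed by strain name with an optional "*"
#' fallback; strains with no entry are unaffected.
#'
#' @slot compound_id compound identifier
#' @slot effects named list (strain -> list(sat_mult, rate_mult, add_lag_h,
#'   ec50_um, hill))
#' @export
setClass("DrugEffect", representation(
  compound_id = "character",
  effects     = "list"
))

setValidity("DrugEffect", function(object) {
  msg <- character()
  for (s in names(object@effects)) {
    e <- object@effects[[s]]
    if (e$sat_mult <= 0 || e$sat_mult > 1 || e$rate_mult <= 0 || e$rate_mult > 1)
      msg <- c(msg, sprintf("effects[%s]: multipliers must lie in (0, 1]", s))
    if (e$add_lag_h < 0) msg <- c(msg, sprintf("effects[%s]: add_lag_h must be >= 0", s))
    if (e$ec50_um <= 0) msg <- c(msg, sprintf("effects[%s]: ec50_um must be > 0", s))
    if (e$hill <= 0) msg <- c(msg, sprintf("effects[%s]: hill must be > 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' @param compound_id compound identifier
#' @param effects per-strain effect list; each entry a list with elements
#'   sat_mult, rate_mult, add_lag_h, ec50_um, hill (missing elements default
#'   to no effect)
#' @return a \code{DrugEffect}
#' @rdname DrugEffect-class
#' @examples
#' d <- drugEffect("cmpd1", list(sdh2 = list(sat_mult = 0.2, ec50_um = 1)))
#' @export
drugEffect <- function(compound_id, effects = list()) {
  fill <- function(e) {
    base <- list(sat_mult = 1, rate_mult = 1, add_lag_h = 0, ec50_um = 1, hill = 1)
    base[names(e)] <- e
    base
  }
  new("DrugEffect", compound_id = as.character(compound_id),
      effects = lapply(effects, fill))
}

#' High-resolution growth curve
#'
#' An OD600 time series for one strain under one condition, optionally
#' carrying the generator's ground-truth parameters (for synthetic curves).
#'
#' @slot strain strain identifier
#' @slot compound_id compound identifier ("" for no compound)
#' @slot conc_um compound concentration (uM)
#' @slot media_mix fraction fermentable carbon
#' @slot times numeric hours, strictly increasing
#' @slot od numeric absorbance at 600 nm, finite and >= 0
#' @slot truth list of ground-truth parameters (empty for real data)
#' @export
setClass("GrowthCurve", representation(
  strain      = "character",
  compound_id = "character",
  conc_um     = "numeric",
  media_mix   = "numeric",
  times       = "numeric",
  od          = "numeric",
  truth       = "list"
))

setValidity("GrowthCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@od))
    msg <- c(msg, "times and od must have equal length")
  if (any(diff(object@times) <= 0)) msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@od)) || any(object@od < 0))
    msg <- c(msg, "od must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a growth curve from raw vectors
#'
#' @param times hours, strictly increasing
#' @param od absorbance values (600 nm)
#' @param strain strain identifier
#' @param compound_id compound identifier ("" if none)
#' @param conc_um concentration in uM
#' @param media_mix fraction fermentable carbon
#' @param truth optional ground-truth list (synthetic curves)
#' @return a \code{GrowthCurve}
#' @export
growthCurve <- function(times, od, strain = "unknown", compound_id = "",
                        conc_um = 0, media_mix = 0.5, truth = list()) {
  new("GrowthCurve", strain = as.character(strain),
      compound_id = as.character(compound_id), conc_um = as.numeric(conc_um),
      media_mix = as.numeric(media_mix), times = as.numeric(times),
      od = as.numeric(od), truth = truth)
}

#' Fitted growth model
#'
#' Result of fitting a sum-of-logistics growth model
#' OD(t) = b + sum_i K_i / (1 + exp(-r_i (t - m_i))). Each phase reports the
#' three field-standard parameters: saturation S_i = K_i (asymptotic OD
#' increment), maximal rate R_i = r_i K_i / 4 (steepest slope, OD/h), and lag
#' L_i = max(0, m_i - 2 / r_i) (tangent-at-inflection intercept). A flat
#' curve yields \code{n_phases = 0} ("no growth") without a fit attempt.
#'
#' @slot n_phases integer 0, 1 or 2
#' @slot baseline fitted baseline OD (b)
#' @slot phases data.frame with one row per phase: phase, lag_h, max_rate,
#'   saturation, K, r, m
#' @slot rss residual sum of squares
#' @slot aicc small-sample-corrected AIC of the selected model
#' @slot converged logical
#' @slot diag diagnostics list (candidate RSS/AICc, start count, messages)
#' @export
setClass("GrowthFit", representation(
  n_phases  = "integer",
  baseline  = "numeric",
  phases    = "data.frame",
  rss       = "numeric",
  aicc      = "numeric",
  converged = "logical",
  diag      = "list"
))

setValidity("GrowthFit", function(object) {
  msg <- character()
  if (!object@n_phases %in% 0:2) msg <- c(msg, "n_phases must be 0, 1 or 2")
  if (object@n_phases > 0 && object@converged) {
    ph <- object@phases
    if (nrow(ph) != object@n_phases) msg <- c(msg, "phases must have n_phases rows")
    else {
      if (any(ph$lag_h < 0)) msg <- c(msg, "lag must be >= 0")
      if (any(ph$max_rate <= 0) || any(ph$saturation <= 0))
        msg <- c(msg, "rates and saturations must be > 0")
      if (object@n_phases == 2 && ph$m[2] <= ph$m[1])
        msg <- c(msg, "phase 2 inflection must follow phase 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Dose-response fit
#'
#' Four-parameter log-logistic fit
#' response(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill).
#'
#' @slot ic50 half-maximal inhibitory concentration (input units)
#' @slot hill Hill slope
#' @slot top,bottom asymptotic responses
#' @slot rss residual sum of squares
#' @slot ci_ic50 numeric(2) bootstrap 95 percent interval (NA if not requested)
#' @slot converged logical
#' @slot diag diagnostics (flat/extrapolated flags, tested range, messages)
#' @export
setClass("DoseResponseFit", representation(
  ic50      = "numeric",
  hill      = "numeric",
  top       = "numeric",
  bottom    = "numeric",
  rss       = "numeric",
  ci_ic50   = "numeric",
  converged = "logical",
  diag      = "list"
))

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (object@converged) {
    if (!is.finite(object@ic50) || object@ic50 <= 0)
      msg <- c(msg, "ic50 must be positive for a converged fit")
    if (object@bottom > object@top) msg <- c(msg, "bottom must be <= top")
  }
  if (length(msg)) msg else TRUE
})

#' Serial dilution series
#'
#' Exact geometric dilution: c_k = top / fold^(k - 1), k = 1..n.
#'
#' @slot top_conc top concentration (uM)
#' @slot fold dilution factor (> 1)
#' @slot n_points number of points (>= 2)
#' @slot concentrations derived, strictly decreasing
#' @export
setClass("DilutionSeries", representation(
  top_conc       = "numeric",
  fold           = "numeric",
  n_points       = "integer",
  concentrations = "numeric"
))

setValidity("DilutionSeries", function(object) {
  msg <- character()
  if (object@top_conc <= 0) msg <- c(msg, "top_conc must be > 0")
  if (object@fold <= 1) msg <- c(msg, "fold must be > 1")
  if (object@n_points < 2) msg <- c(msg, "n_points must be >= 2")
  if (length(object@concentrations) != object@n_points)
    msg <- c(msg, "concentrations must have n_points values")
  if (any(diff(object@concentrations) >= 0))
    msg <- c(msg, "concentrations must be strictly decreasing")
  if (any(object@concentrations <= 0)) msg <- c(msg, "concentrations must be positive")
  if (length(msg)) msg else TRUE
})

#' Acoustic dispensing protocol
#'
#' Volumes and stock concentration of the droplet-based compound dispensing
#' workflow: nanolitre DMSO droplets into pre-dispensed medium, a media
#' top-up, then culture inoculation.
#'
#' @slot stock_conc_mm compound stock concentration (mM, in DMSO)
#' @slot droplet_vol_nl droplet volume (nL)
#' @slot n_droplets droplets dispensed per well
#' @slot predispensed_vol_ul medium present before dispensing (uL)
#' @slot topup_vol_ul medium added after dispensing (uL)
#' @slot inoculum_vol_ul culture volume added last (uL)
#' @slot solvent solvent name
#' @export
setClass("DispenseProtocol", representation(
  stock_conc_mm       = "numeric",
  droplet_vol_nl      = "numeric",
  n_droplets          = "numeric",
  predispensed_vol_ul = "numeric",
  topup_vol_ul        = "numeric",
  inoculum_vol_ul     = "numeric",
  solvent             = "character"
))

setValidity("DispenseProtocol", function(object) {
  vols <- c(object@droplet_vol_nl, object@predispensed_vol_ul,
            object@topup_vol_ul, object@inoculum_vol_ul)
  msg <- character()
  if (any(vols <= 0)) msg <- c(msg, "all volumes must be > 0")
  if (object@stock_conc_mm <= 0) msg <- c(msg, "stock_conc_mm must be > 0")
  if (object@n_droplets < 0) msg <- c(msg, "n_droplets must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param stock_conc_mm stock concentration (mM)
#' @param droplet_vol_nl droplet volume (nL)
#' @param n_droplets number of droplets
#' @param predispensed_vol_ul pre-dispensed medium (uL)
#' @param topup_vol_ul top-up medium (uL)
#' @param inoculum_vol_ul inoculum volume (uL)
#' @param solvent solvent name
#' @return a \code{DispenseProtocol}; the default reproduces the screening
#'   protocol (20 x 2.5 nL droplets of 10 mM stock into 10 uL, +30 uL medium,
#'   +10 uL culture).
#' @rdname DispenseProtocol-class
#' @export
dispenseProtocol <- function(stock_conc_mm = 10, droplet_vol_nl = 2.5,
                             n_droplets = 20, predispensed_vol_ul = 10,
                             topup_vol_ul = 30, inoculum_vol_ul = 10,
                             solvent = "DMSO") {
  new("DispenseProtocol", stock_conc_mm = stock_conc_mm,
      droplet_vol_nl = droplet_vol_nl, n_droplets = n_droplets,
      predispensed_vol_ul = predispensed_vol_ul, topup_vol_ul = topup_vol_ul,
      inoculum_vol_ul = inoculum_vol_ul, solvent = solvent)
}
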