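#' Synthesize a high-resolution growth curve
#'
#' Builds an OD600 time series as baseline plus one logistic component per
#' competent, expressed growth phase, with additive Gaussian read noise.
#' Phase 1 (glycolytic) is expressed when the media contain any fermentable
#' carbon (\code{media_mix > 0}); phase 2 (respiratory) when any
#' non-fermentable carbon is present (\code{media_mix < 1}) and the strain is
#' respiration-competent. Drug action transforms the ground-truth phase
#' parameters through the Hill model of \code{\link{drugEffect}} before the
#' curve is synthesized. The diauxic pause is enforced by constraining the
#' phase-2 inflection to at least \code{diauxic_gap} hours after the phase-1
#' inflection.
#'
#' @param archetype a \code{\link{strainArchetype}}
#' @param drug a \code{\link{drugEffect}} or NULL
#' @param conc_um compound concentration (uM, >= 0)
#' @param cfg a \code{\link{simConfig}} (sampling, duration, noise, seed,
#'   media mix)
#' @param diauxic_gap minimum hours between phase inflections (default 1)
#' @return a \code{\link{GrowthCurve}}; \code{groundTruth()} carries the
#'   post-drug true parameters, the baseline, and the asymptotic OD.
#' @examples
#' wt <- strainArchetype("wt")
#' gc <- genGrowthCurve(wt, cfg = simConfig(seed = 7, noise_sd = 0))
#' @export
genGrowthCurve <- function(archetype, drug = NULL, conc_um = 0,
                           cfg = simConfig(), diauxic_gap = 1) {
  stopifnot(is(archetype, "StrainArchetype"), is(cfg, "SimConfig"))
  if (conc_um < 0) stop("concentration must be >= 0")
  if (!is.null(drug)) stopifnot(is(drug, "DrugEffect"))

  times <- seq(0, cfg@duration, by = cfg@sampling_interval / 60)
  expressed <- c(phase1 = archetype@phase1_competent && cfg@media_mix > 0,
                 phase2 = archetype@phase2_competent && cfg@media_mix < 1)

  eff <- drugEffectFor(drug, archetype@name)
  pars <- list()
  if (expressed[["phase1"]])
    pars$phase1 <- applyDrugToPhase(archetype@phase1_params, eff, conc_um)
  if (expressed[["phase2"]])
    pars$phase2 <- applyDrugToPhase(archetype@phase2_params, eff, conc_um)

  logis <- lapply(pars, function(p)
    phaseToLogistic(p[["lag_h"]], p[["max_rate"]], p[["saturation"]]))
  if (length(logis) == 2L) {
    m_min <- logis$phase1[["m"]] + diauxic_gap
    if (logis$phase2[["m"]] < m_min) {
      shift <- m_min - logis$phase2[["m"]]
      logis$phase2[["m"]] <- m_min
      pars$phase2[["lag_h"]] <- pars$phase2[["lag_h"]] + shift
    }
  }

  clean <- rep(archetype@baseline_od, length(times))
  for (lp in logis)
    clean <- clean + logisticComponent(times, lp[["K"]], lp[["r"]], lp[["m"]])

  od <- if (cfg@noise_sd > 0) {
    withr::with_seed(cfg@seed,
      pmax(0, clean + stats::rnorm(length(times), sd = cfg@noise_sd)))
  } else clean

  phases <- if (length(pars)) {
    data.frame(
      phase      = seq_along(pars),
      name       = names(pars),
      lag_h      = vapply(pars, `[[`, numeric(1), "lag_h"),
      max_rate   = vapply(pars, `[[`, numeric(1), "max_rate"),
      saturation = vapply(pars, `[[`, numeric(1), "saturation"),
      K = vapply(logis, `[[`, numeric(1), "K"),
      r = vapply(logis, `[[`, numeric(1), "r"),
      m = vapply(logis, `[[`, numeric(1), "m"),
      row.names = NULL)
  } else {
    data.frame(phase = integer(), name = character(), lag_h = numeric(),
               max_rate = numeric(), saturation = numeric(),
               K = numeric(), r = numeric(), m = numeric())
  }

  growthCurve(times, od,
              strain = archetype@name,
              compound_id = if (is.null(drug)) "" else drug@compound_id,
              conc_um = conc_um, media_mix = cfg@media_mix,
              truth = list(baseline = archetype@baseline_od,
                           phases = phases,
                           asymptote = archetype@baseline_od +
                             sum(phases$saturation),
                           clean = clean))
}

# Strain-specific effect entry with "*" fallback; NULL means no effect.
drugEffectFor <- function(drug, strain) {
  if (is.null(drug)) return(NULL)
  drug@effects[[strain]] %||% drug@effects[["*"]]
}

# Hill-transform one phase's (lag, rate, saturation) triple.
applyDrugToPhase <- function(params, eff, conc_um) {
  if (is.null(eff) || conc_um <= 0) return(params)
  f <- hillOccupancy(conc_um, eff$ec50_um, eff$hill)
  c(lag_h      = params[["lag_h"]] + eff$add_lag_h * f,
    max_rate   = params[["max_rate"]] * (1 - (1 - eff$rate_mult) * f),
    saturation = params[["saturation"]] * (1 - (1 - eff$sat_mult) * f))
}

#' Built-in compound effect classes for synthetic screens
#'
#' Returns the \code{\link{drugEffect}} used by \code{\link{genScreenPlate}}
#' for a given truth class. The classes encode well-separated effect sizes:
#' \describe{
#'   \item{mutant_selective}{strong saturation loss in the SDH-null strain
#'     (asymptotic multiplier 0.15), mild in reference strains (0.9)}
#'   \item{reference_selective}{strong loss in reference strains (0.1),
#'     partial in the mutant (0.5) so the compound still registers in a
#'     mutant-only primary screen}
#'   \item{nonselective}{equal strong loss in all strains (0.2)}
#'   \item{inert}{no effect}
#' }
#' All effects use EC50 = 1 uM and Hill slope 2, so 10 uM (primary screen)
#' and 50 uM (retest) doses sit on the upper plateau.
#'
#' @param class one of "inert", "nonselective", "mutant_selective",
#'   "reference_selective"
#' @param compound_id compound identifier
#' @export
defaultEffectModel <- function(class = c("inert", "nonselective",
                                         "mutant_selective",
                                         "reference_selective"),
                               compound_id) {
  class <- match.arg(class)
  hill <- list(ec50_um = 1, hill = 2)
  eff <- switch(class,
    inert = list(),
    nonselective = list("*" = c(list(sat_mult = 0.2), hill)),
    mutant_selective = list(sdh2 = c(list(sat_mult = 0.15), hill),
                            "*"  = c(list(sat_mult = 0.9), hill)),
    reference_selective = list(sdh2 = c(list(sat_mult = 0.5), hill),
                               "*"  = c(list(sat_mult = 0.1), hill)))
  drugEffect(compound_id, eff)
}

#' Generate a synthetic 384-well screening plate set
#'
#' Emits 384-well plates (16 rows A-P x 24 columns) in the screening layout:
#' columns 1, 2 and 23 hold no-compound (negative) controls, column 24 holds
#' media blanks, and columns 3-22 hold one compound per well at
#' \code{conc_um}. Endpoint OD600 reads are taken from the growth-curve model
#' at the two read times, with additive read noise. A truth table records
#' each compound's effect class; the per-compound \code{DrugEffect} objects
#' are returned so downstream stages can re-simulate high-resolution curves
#' for the same compounds.
#'
#' @param n_compounds number of compounds (320 fit on one plate)
#' @param hit_fraction fraction of compounds that are true growth inhibitors
#' @param effect_mix named proportions of inhibitor classes among hits
#'   (mutant_selective / reference_selective / nonselective)
#' @param cfg \code{\link{simConfig}}; seed, noise and media mix are honoured
#' @param archetype screening strain archetype (default the SDH-null mutant)
#' @param conc_um screening concentration (uM)
#' @param read_times_h endpoint read times in hours
#' @param multi_plate allow splitting across several plates
#' @param plate_prefix plate identifier prefix
#' @return list with \code{reads} (long CSV-shaped data.frame: plate_id,
#'   well, time_min, channel, value), \code{map} (plate_id, well, role,
#'   compound_id, conc_um, strain), \code{truth} (compound_id, plate_id,
#'   well, class, is_inhibitor) and \code{effects} (named list of
#'   \code{DrugEffect})
#' @examples
#' sp <- genScreenPlate(320, 0.05, cfg = simConfig(seed = 11))
#' table(sp$truth$class)
#' @export
genScreenPlate <- function(n_compounds, hit_fraction,
                           effect_mix = c(mutant_selective = 0.6,
                                          reference_selective = 0.1,
                                          nonselective = 0.3),
                           cfg = simConfig(),
                           archetype = strainArchetype("sdh2"),
                           conc_um = 10,
                           read_times_h = c(16, 48),
                           multi_plate = FALSE,
                           plate_prefix = "PLATE") {
  stopifnot(hit_fraction >= 0, hit_fraction <= 1, n_compounds >= 1)
  compound_cols <- 3:22
  per_plate <- 16L * length(compound_cols)
  if (n_compounds > per_plate && !multi_plate)
    stop(sprintf("%d compounds exceed the %d compound wells of one plate; set multi_plate = TRUE",
                 n_compounds, per_plate))
  n_plates <- ceiling(n_compounds / per_plate)

  n_hits <- round(hit_fraction * n_compounds)
  mix <- effect_mix / sum(effect_mix)
  n_mut <- round(n_hits * mix[["mutant_selective"]])
  n_ref <- round(n_hits * mix[["reference_selective"]])
  n_non <- n_hits - n_mut - n_ref

  compound_ids <- sprintf("cmpd%04d", seq_len(n_compounds))
  classes <- rep("inert", n_compounds)
  hit_idx <- withr::with_seed(childSeed(cfg@seed, 1L),
                              sample(n_compounds, n_hits))
  classes[hit_idx] <- rep(c("mutant_selective", "reference_selective",
                            "nonselective"), c(n_mut, n_ref, n_non))
  effects <- stats::setNames(
    mapply(defaultEffectModel, classes, compound_ids, SIMPLIFY = FALSE),
    compound_ids)

  # layout: compounds fill compound columns row-major per plate
  map <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    plate_id <- paste0(plate_prefix, p)
    rows <- expand.grid(col = 1:24, row = 1:16)[, c("row", "col")]
    role <- ifelse(rows$col %in% c(1, 2, 23), "neg_control",
                   ifelse(rows$col == 24, "blank", "compound"))
    data.frame(plate_id = plate_id, well = wellName(rows$row, rows$col),
               role = role, compound_id = NA_character_,
               conc_um = 0, strain = archetype@name,
               stringsAsFactors = FALSE)
  }))
  map$strain[map$role == "blank"] <- ""
  cw <- which(map$role == "compound")
  map$compound_id[cw[seq_len(n_compounds)]] <- compound_ids
  map$conc_um[cw[seq_len(n_compounds)]] <- conc_um
  # surplus compound wells (short final plate) become extra negative controls
  unused <- cw[is.na(map$compound_id[cw]) & map$role[cw] == "compound"]
  map$role[unused] <- "neg_control"

  # endpoint clean OD per well
  cleanOD <- function(drug, conc, t_h) {
    cfg0 <- cfg; cfg0@noise_sd <- 0
    gc <- genGrowthCurve(archetype, drug, conc, cfg0)
    stats::approx(gc@times, groundTruth(gc)$clean, xout = t_h)$y
  }
  base_clean <- cleanOD(NULL, 0, read_times_h)

  reads <- do.call(rbind, lapply(seq_along(read_times_h), function(i) {
    t_h <- read_times_h[i]
    value <- vapply(seq_len(nrow(map)), function(j) {
      role <- map$role[j]
      if (role == "blank") return(archetype@baseline_od)
      if (role == "neg_control" || is.na(map$compound_id[j])) return(base_clean[i])
      cleanOD(effects[[map$compound_id[j]]], map$conc_um[j], t_h)
    }, numeric(1))
    data.frame(plate_id = map$plate_id, well = map$well,
               time_min = t_h * 60, channel = "od600", value = value,
               stringsAsFactors = FALSE)
  }))
  if (cfg@noise_sd > 0)
    reads$value <- withr::with_seed(childSeed(cfg@seed, 2L),
      pmax(0, reads$value + stats::rnorm(nrow(reads), sd = cfg@noise_sd)))

  truth <- data.frame(compound_id = compound_ids,
                      plate_id = map$plate_id[cw[seq_len(n_compounds)]],
                      well = map$well[cw[seq_len(n_compounds)]],
                      class = classes,
                      is_inhibitor = classes != "inert",
                      stringsAsFactors = FALSE)

  list(reads = reads, map = map, truth = truth, effects = effects,
       read_times_h = read_times_h, conc_um = conc_um)
}

#' Generate a z-factor control plate
#'
#' Control plates alternate full rows of culture alone (negative control),
#' culture plus a strongly inhibitory positive-control compound, and media
#' alone (blank), cycling down the 16 rows. Endpoint reads are produced at
#' the same read times as screening plates.
#'
#' @param cfg \code{\link{simConfig}}
#' @param archetype screening strain archetype
#' @param killer positive-control \code{\link{drugEffect}} (defaults to a
#'   near-complete growth inhibitor)
#' @param conc_um positive-control concentration (uM)
#' @param read_times_h endpoint read times (h)
#' @param plate_id plate identifier
#' @return list with \code{reads} and \code{map} data.frames (same schemas
#'   as \code{\link{genScreenPlate}})
#' @export
genControlPlate <- function(cfg = simConfig(),
                            archetype = strainArchetype("sdh2"),
                            killer = drugEffect("killer",
                              list("*" = list(sat_mult = 0.02,
                                              ec50_um = 0.1, hill = 2))),
                            conc_um = 10,
                            read_times_h = c(16, 48),
                            plate_id = "CTRL1") {
  roles <- rep(c("neg_control", "pos_control", "blank"), length.out = 16)
  grid <- expand.grid(col = 1:24, row = 1:16)[, c("row", "col")]
  map <- data.frame(plate_id = plate_id,
                    well = wellName(grid$row, grid$col),
                    role = roles[grid$row],
                    compound_id = NA_character_, conc_um = 0,
                    strain = archetype@name, stringsAsFactors = FALSE)
  map$compound_id[map$role == "pos_control"] <- killer@compound_id
  map$conc_um[map$role == "pos_control"] <- conc_um
  map$strain[map$role == "blank"] <- ""

  cfg0 <- cfg; cfg0@noise_sd <- 0
  neg_curve <- genGrowthCurve(archetype, NULL, 0, cfg0)
  pos_curve <- genGrowthCurve(archetype, killer, conc_um, cfg0)
  odAt <- function(curve, t_h)
    stats::approx(curve@times, groundTruth(curve)$clean, xout = t_h)$y

  reads <- do.call(rbind, lapply(read_times_h, function(t_h) {
    value <- ifelse(map$role == "blank", archetype@baseline_od,
                    ifelse(map$role == "pos_control",
                           odAt(pos_curve, t_h), odAt(neg_curve, t_h)))
    data.frame(plate_id = plate_id, well = map$well, time_min = t_h * 60,
               channel = "od600", value = value, stringsAsFactors = FALSE)
  }))
  if (cfg@noise_sd > 0)
    reads$value <- withr::with_seed(childSeed(cfg@seed, 3L),
      pmax(0, reads$value + stats::rnorm(nrow(reads), sd = cfg@noise_sd)))

  list(reads = reads, map = map, read_times_h = read_times_h)
}

#' Generate NADH-depletion enzyme assay progress curves
#'
#' For every inhibitor concentration in the dilution series (plus
#' zero-inhibitor wells used for normalization), emits decreasing A340
#' progress curves sampled at 2-min intervals over 20 min (11 points by
#' default). The noise-free curve is first-order NADH depletion
#' A(t) = background + A0 exp(-k t) with k chosen so that the initial slope
#' A0 k equals the uninhibited rate scaled by 1 / (1 + (c / IC50)^hill).
#' The default signal A0 = 1.24 is the 340 nm absorbance of 200 uM NADH at
#' a 1 cm path (extinction coefficient 6.22 mM^-1 cm^-1); the default
#' uninhibited rate consumes about 15 percent of the NADH over the 20-min
#' window, keeping every well inside the initial-rate regime the assay is
#' designed for.
#'
#' @param true_ic50 ground-truth IC50 (uM, > 0)
#' @param hill ground-truth Hill slope
#' @param dilution a \code{\link{serialDilution}} series
#' @param replicates replicate wells per concentration (>= 1)
#' @param cfg \code{\link{simConfig}} (noise sd applies to A340; seed). The
#'   default read noise of 0.003 absorbance units reflects photometric
#'   kinetic reads, which are quieter than OD600 culture measurements.
#' @param v0_uninhibited uninhibited initial rate (delta A340/min)
#' @param a0 initial NADH absorbance signal above background
#' @param background non-depleting background absorbance
#' @param include_zero add zero-inhibitor wells
#' @param t_max_min,dt_min time span and spacing in minutes
#' @param compound_id compound identifier
#' @return long data.frame (compound_id, conc_um, replicate, time_min, a340)
#'   with the ground truth attached as \code{attr(, "truth")}
#' @examples
#' rec <- genEnzymeAssay(3.8, 1, serialDilution(62.5, 5, 8), replicates = 4,
#'                       cfg = simConfig(seed = 3, noise_sd = 0.005))
#' @export
genEnzymeAssay <- function(true_ic50, hill = 1,
                           dilution = serialDilution(62.5, 5, 8),
                           replicates = 4, cfg = simConfig(noise_sd = 0.003),
                           v0_uninhibited = 0.01, a0 = 1.24,
                           background = 0.05, include_zero = TRUE,
                           t_max_min = 20, dt_min = 2,
                           compound_id = "cmpd") {
  stopifnot(true_ic50 > 0, replicates >= 1)
  concs <- concentrations(dilution)
  if (any(concs <= 0)) stop("dilution concentrations must be positive")
  if (include_zero) concs <- c(0, concs)
  times <- seq(0, t_max_min, by = dt_min)

  grid <- expand.grid(replicate = seq_len(replicates), conc_um = concs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    conc <- grid$conc_um[i]
    v0 <- v0_uninhibited / (1 + (conc / true_ic50)^hill)
    k <- v0 / a0
    data.frame(compound_id = compound_id, conc_um = conc,
               replicate = grid$replicate[i], time_min = times,
               a340 = background + a0 * exp(-k * times),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (cfg@noise_sd > 0)
    out$a340 <- withr::with_seed(childSeed(cfg@seed, 4L),
      out$a340 + stats::rnorm(nrow(out), sd = cfg@noise_sd))
  attr(out, "truth") <- list(true_ic50 = true_ic50, hill = hill,
                             v0_uninhibited = v0_uninhibited, a0 = a0,
                             background = background)
  out
}
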