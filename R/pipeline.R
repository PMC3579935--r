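#' Default configuration for a synthetic end-to-end screen
#'
#' Returns the fully explicit configuration list consumed by
#' \code{\link{runScreen}}. Every decision threshold of the analysis (hit
#' percent-inhibition cutoff, differential delta cutoff, marker-concordance
#' tolerance) appears here explicitly so a run record is auditable; none is
#' hidden inside the pipeline.
#'
#' @param seed master seed governing every random draw of the run
#' @return nested named list (simulate / stage1 / stage2 / stage3 blocks)
#' @export
defaultScreenConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_compounds = 320,
      hit_fraction = 0.0625,
      effect_mix = list(mutant_selective = 0.6, reference_selective = 0.1,
                        nonselective = 0.3),
      noise_sd = 0.01,
      media_mix = 0.5,
      read_times_h = c(16, 48),
      screen_conc_um = 10
    ),
    stage1 = list(threshold = 40, read_time_h = 48),
    # per-metric thresholds are scaled to each delta's replicate noise under
    # the retest design: saturation and lag ratios are precise (sd ~ 0.03),
    # while the maximal rate of a strongly inhibited (steep, low-amplitude)
    # curve is intrinsically ill-determined (delta_R sd ~ 0.2), so its
    # threshold sits at ~3x that noise floor
    stage2 = list(conc_um = 50,
                  delta_threshold = list(delta_S = 0.3, delta_R = 0.7,
                                         delta_L = 0.3),
                  lag_floor = 0.25, duration_h = 48, sampling_min = 6,
                  n_starts = 5),
    stage3 = list(tolerance = 0.2)
  )
}

checkScreenConfig <- function(config) {
  need <- list(c("seed"), c("simulate", "n_compounds"),
               c("simulate", "hit_fraction"), c("stage1", "threshold"),
               c("stage1", "read_time_h"), c("stage2", "conc_um"),
               c("stage2", "delta_threshold"), c("stage3", "tolerance"))
  for (path in need) {
    v <- config
    for (k in path) v <- v[[k]]
    if (is.null(v))
      stop("config is missing required entry: ", paste(path, collapse = "$"))
  }
  invisible(TRUE)
}

# Generate the strain quadruple for one compound and fit all four curves.
fitQuad <- function(effect, conc_um, cfg_base, seed, mutant = "sdh2",
                    reference = "wt", n_starts = 5) {
  arch <- list(mut = strainArchetype(mutant), ref = strainArchetype(reference))
  out <- list()
  i <- 0L
  for (s in names(arch)) {
    for (drugged in c(FALSE, TRUE)) {
      i <- i + 1L
      cfg <- cfg_base
      cfg@seed <- childSeed(seed, i)
      curve <- genGrowthCurve(arch[[s]],
                              drug = if (drugged) effect else NULL,
                              conc_um = if (drugged) conc_um else 0,
                              cfg = cfg)
      out[[paste0(s, if (drugged) "_drug" else "_ctrl")]] <-
        fitGrowth(curve, n_phases = "auto", seed = childSeed(seed, 100L + i),
                  n_starts = n_starts)
    }
  }
  out
}

#' Stage-II differential retest on a compound set
#'
#' For every compound, simulates the matched quadruple of high-resolution
#' growth curves (mutant and reference strain, each with and without the
#' compound), fits each curve, computes \code{\link{deltaScores}} and
#' classifies the compound with \code{\link{classifyCall}}.
#'
#' @param effects named list of \code{\link{drugEffect}} objects
#' @param conc_um retest concentration (uM)
#' @param cfg a \code{\link{simConfig}} template (noise, duration, media)
#' @param seed integer seed
#' @param delta_threshold classification threshold for the deltas
#' @param mutant,reference strain archetype names
#' @param lag_floor control-lag floor (h)
#' @param n_starts multi-start count per fit
#' @return list: \code{scores} data.frame (one row per compound with deltas
#'   and call) and \code{fits} (per-compound list of the four
#'   \code{GrowthFit}s, names mut_ctrl/mut_drug/ref_ctrl/ref_drug)
#' @export
stageTwoDifferential <- function(effects, conc_um, cfg, seed,
                                 delta_threshold, mutant = "sdh2",
                                 reference = "wt", lag_floor = 0.25,
                                 n_starts = 5) {
  delta_threshold <- unlist(delta_threshold)
  ids <- names(effects)
  fits <- list()
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    quad <- fitQuad(effects[[id]], conc_um, cfg, childSeed(seed, 1000L + j),
                    mutant = mutant, reference = reference,
                    n_starts = n_starts)
    fits[[id]] <- quad
    sc <- deltaScores(quad$mut_ctrl, quad$mut_drug, quad$ref_ctrl,
                      quad$ref_drug, compound_id = id, conc_um = conc_um,
                      lag_floor = lag_floor)
    sc$call <- classifyCall(sc, delta_threshold)
    rows[[j]] <- sc
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  list(scores = scores, fits = fits)
}

#' Stage-III marker-strain confirmation
#'
#' Re-simulates the differential compounds on the marker-control strain,
#' fits the with/without-drug pair, and checks concordance of the
#' drug-effect ratios against the reference strain with
#' \code{\link{markerConcordance}}.
#'
#' @param effects named list of \code{\link{drugEffect}}s for the
#'   differential compounds
#' @param ref_fits per-compound list with \code{ref_ctrl}/\code{ref_drug}
#'   fits from \code{\link{stageTwoDifferential}}
#' @param conc_um tested concentration (uM)
#' @param cfg \code{\link{simConfig}} template
#' @param seed integer seed
#' @param tolerance concordance tolerance (relative)
#' @param marker marker-control strain archetype name
#' @param n_starts multi-start count per fit
#' @return the \code{\link{markerConcordance}} result
#' @export
stageThreeConcordance <- function(effects, ref_fits, conc_um, cfg, seed,
                                  tolerance = 0.2, marker = "nhp6a",
                                  n_starts = 5) {
  ids <- names(effects)
  if (!length(ids)) stop("empty comparison set: no differential compounds")
  arch <- strainArchetype(marker)
  marker_fits <- list()
  for (j in seq_along(ids)) {
    id <- ids[j]
    s2 <- childSeed(seed, 2000L + j)
    cfg_c <- cfg; cfg_c@seed <- childSeed(s2, 1L)
    cfg_d <- cfg; cfg_d@seed <- childSeed(s2, 2L)
    ctrl <- fitGrowth(genGrowthCurve(arch, NULL, 0, cfg_c),
                      seed = childSeed(s2, 3L), n_starts = n_starts)
    drug <- fitGrowth(genGrowthCurve(arch, effects[[id]], conc_um, cfg_d),
                      seed = childSeed(s2, 4L), n_starts = n_starts)
    marker_fits[[id]] <- list(ctrl = ctrl, drug = drug)
  }
  ref_pairs <- lapply(ref_fits[ids], function(q)
    list(ctrl = q$ref_ctrl, drug = q$ref_drug))
  markerConcordance(ref_pairs, marker_fits, tolerance = tolerance)
}

#' Run the three-stage differential growth-inhibition screen end to end
#'
#' Simulates the primary screening plates and a z-factor control plate,
#' scores percent inhibition and calls Stage-I hits, retests every hit in
#' the high-resolution differential growth assay (Stage II), confirms
#' differential compounds against the marker-control strain (Stage III),
#' and emits a screening-funnel summary plus a reproducibility manifest.
#' Two runs with the same configuration are identical.
#'
#' @param config configuration list as from \code{\link{defaultScreenConfig}},
#'   or the path of a YAML/JSON file holding one
#' @param outdir optional directory; when given, all tables are written as
#'   CSV and the manifest as JSON
#' @return list: funnel, hits, pi_table, qc, scores, concordance, truth,
#'   manifest
#' @examples
#' \donttest{
#' run <- runScreen(defaultScreenConfig(seed = 42))
#' run$funnel
#' }
#' @export
runScreen <- function(config = defaultScreenConfig(), outdir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  checkScreenConfig(config)
  # named parameter blocks may arrive as lists (e.g. from YAML)
  config$simulate$effect_mix <- unlist(config$simulate$effect_mix)
  config$stage2$delta_threshold <- unlist(config$stage2$delta_threshold)
  seed <- as.integer(config$seed)
  sim <- config$simulate
  t0 <- proc.time()[["elapsed"]]

  # --- Stage I: primary screen + QC -------------------------------------
  cfg_plate <- simConfig(noise_sd = sim$noise_sd, seed = childSeed(seed, 10L),
                         media_mix = sim$media_mix)
  screen <- genScreenPlate(sim$n_compounds, sim$hit_fraction,
                           effect_mix = sim$effect_mix, cfg = cfg_plate,
                           conc_um = sim$screen_conc_um %||% 10,
                           read_times_h = sim$read_times_h %||% c(16, 48),
                           multi_plate = TRUE)
  ctrl <- genControlPlate(cfg = simConfig(noise_sd = sim$noise_sd,
                                          seed = childSeed(seed, 11L),
                                          media_mix = sim$media_mix),
                          read_times_h = sim$read_times_h %||% c(16, 48))
  pi_table <- summarizePlate(screen$reads, screen$map)
  qc <- plateQC(ctrl$reads, ctrl$map)
  hits <- callHits(pi_table, threshold = config$stage1$threshold,
                   read_time_h = config$stage1$read_time_h)
  t1 <- proc.time()[["elapsed"]]

  # --- Stage II: differential retest of hits ----------------------------
  hit_ids <- hits$compound_id
  cfg_curve <- simConfig(sampling_interval = config$stage2$sampling_min %||% 6,
                         duration = config$stage2$duration_h %||% 48,
                         noise_sd = sim$noise_sd, seed = childSeed(seed, 12L),
                         media_mix = sim$media_mix)
  if (length(hit_ids)) {
    s2 <- stageTwoDifferential(screen$effects[hit_ids],
                               conc_um = config$stage2$conc_um,
                               cfg = cfg_curve, seed = childSeed(seed, 13L),
                               delta_threshold = config$stage2$delta_threshold,
                               lag_floor = config$stage2$lag_floor %||% 0.25,
                               n_starts = config$stage2$n_starts %||% 5)
    scores <- s2$scores
  } else {
    s2 <- list(scores = NULL, fits = list())
    scores <- data.frame(compound_id = character(), conc_um = numeric(),
                         delta_S = numeric(), delta_R = numeric(),
                         delta_L = numeric(), indeterminate = logical(),
                         call = character())
  }
  diff_ids <- scores$compound_id[scores$call %in%
                                   c("mutant_selective", "reference_selective")]
  t2 <- proc.time()[["elapsed"]]

  # --- Stage III: marker-strain confirmation ----------------------------
  concordance <- if (length(diff_ids)) {
    stageThreeConcordance(screen$effects[diff_ids], s2$fits,
                          conc_um = config$stage2$conc_um, cfg = cfg_curve,
                          seed = childSeed(seed, 14L),
                          tolerance = config$stage3$tolerance,
                          n_starts = config$stage2$n_starts %||% 5)
  } else list(concordant = NA, report = NULL)
  n_confirmed <- if (is.null(concordance$report)) 0L
                 else sum(concordance$report$concordant)
  t3 <- proc.time()[["elapsed"]]

  funnel <- data.frame(
    count = c(sim$n_compounds, nrow(hits), length(diff_ids),
              sum(scores$call == "mutant_selective"),
              sum(scores$call == "reference_selective"), n_confirmed),
    characteristic = c("total compounds initially screened",
                       sprintf("inhibit mutant at %g uM (PI >= %g at %g h)",
                               screen$conc_um, config$stage1$threshold,
                               config$stage1$read_time_h),
                       "differential effect on mutant vs. reference",
                       "mutant inhibited more than reference",
                       "reference inhibited more than mutant",
                       "confirmed against marker-control strain"),
    stringsAsFactors = FALSE)

  manifest <- list(
    package = "DiffGrowthScreen",
    version = as.character(utils::packageVersion("DiffGrowthScreen")),
    config = config,
    seed = seed,
    timings_s = list(stage1 = t1 - t0, stage2 = t2 - t1, stage3 = t3 - t2),
    counts = as.list(stats::setNames(funnel$count,
                                     c("screened", "hits", "differential",
                                       "mutant_selective",
                                       "reference_selective", "confirmed"))))

  out <- list(funnel = funnel, hits = hits, pi_table = pi_table, qc = qc,
              scores = scores, concordance = concordance,
              truth = screen$truth, effects = screen$effects,
              fits = s2$fits, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writePlateCSV(screen$reads, file.path(outdir, "reads.csv"))
    writePlateCSV(screen$map, file.path(outdir, "plate_map.csv"))
    writePlateCSV(screen$truth, file.path(outdir, "truth.csv"))
    writePlateCSV(pi_table, file.path(outdir, "percent_inhibition.csv"))
    writePlateCSV(qc, file.path(outdir, "qc_zfactors.csv"))
    writePlateCSV(hits, file.path(outdir, "hits.csv"))
    writePlateCSV(scores, file.path(outdir, "differential_scores.csv"))
    if (!is.null(concordance$report))
      writePlateCSV(concordance$report, file.path(outdir, "concordance.csv"))
    writePlateCSV(funnel, file.path(outdir, "funnel.csv"))
    digest <- vapply(list.files(outdir, pattern = "\\.csv$",
                                full.names = TRUE), function(f)
      sprintf("%d bytes", file.size(f)), character(1))
    manifest$outputs <- as.list(digest)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}

#' Human-readable run summary
#'
#' Prints the screening funnel, plate QC z-factors, per-compound calls and
#' (when present) the marker-concordance table of a \code{\link{runScreen}}
#' result.
#'
#' @param run result of \code{\link{runScreen}}
#' @return the summary lines, invisibly
#' @export
screenReport <- function(run) {
  need <- c("funnel", "qc", "scores")
  if (!all(need %in% names(run)))
    stop("malformed run artifact: missing ",
         paste(setdiff(need, names(run)), collapse = ", "))
  lines <- c("=== Differential growth-inhibition screen ===", "",
             "Screening funnel:",
             utils::capture.output(print(run$funnel, row.names = FALSE)), "",
             "Plate QC (z-factors):",
             utils::capture.output(print(run$qc, row.names = FALSE)), "")
  if (nrow(run$scores)) {
    lines <- c(lines, "Differential calls:",
               utils::capture.output(print(
                 run$scores[, c("compound_id", "delta_S", "delta_R",
                                "delta_L", "call")], row.names = FALSE,
                 digits = 3)))
  } else {
    lines <- c(lines, "No Stage-II compounds (zero Stage-I hits).")
  }
  if (!is.null(run$concordance$report)) {
    lines <- c(lines, "", "Marker-strain concordance:",
               utils::capture.output(print(run$concordance$report,
                                           row.names = FALSE, digits = 3)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
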