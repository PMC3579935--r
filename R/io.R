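# CSV interchange: long-format plate reads, plate maps, growth curves, fits.

#' Read and write long-format plate data
#'
#' The canonical interchange schemas are plate-reader style long CSVs:
#' reads (plate_id, well, time_min, channel, value) and plate maps
#' (plate_id, well, role, compound_id, conc_um, strain).
#'
#' @param path file path
#' @return data.frame in the corresponding schema
#' @name plate-io
NULL

#' @rdname plate-io
#' @export
readPlateReads <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "time_min", "channel", "value")
  if (!all(need %in% names(d)))
    stop("reads CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname plate-io
#' @export
readPlateMap <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "role", "compound_id", "conc_um", "strain")
  if (!all(need %in% names(d)))
    stop("plate map CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname plate-io
#' @param x data.frame to write
#' @export
writePlateCSV <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read growth curves from CSV
#'
#' Expects columns strain, compound_id, conc_um, media_mix, time_h, od600;
#' one curve per (strain, compound_id, conc_um) combination.
#'
#' @param path file path
#' @return named list of \code{\link{GrowthCurve}} objects
#' @export
readGrowthCurves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "compound_id", "conc_um", "media_mix", "time_h", "od600")
  if (!all(need %in% names(d)))
    stop("curves CSV must have columns: ", paste(need, collapse = ", "))
  d$compound_id[is.na(d$compound_id)] <- ""
  sp <- split(d, interaction(d$strain, d$compound_id, d$conc_um, drop = TRUE))
  out <- lapply(sp, function(g) {
    g <- g[order(g$time_h), ]
    growthCurve(g$time_h, g$od600, strain = g$strain[1],
                compound_id = g$compound_id[1], conc_um = g$conc_um[1],
                media_mix = g$media_mix[1])
  })
  names(out) <- vapply(out, function(gc)
    paste(gc@strain, if (nzchar(gc@compound_id)) gc@compound_id else "none",
          gc@conc_um, sep = "_"), character(1))
  out
}

#' Write growth curves to CSV
#'
#' @param curves list of \code{\link{GrowthCurve}} objects
#' @param path file path
#' @export
writeGrowthCurves <- function(curves, path) {
  rows <- lapply(curves, function(gc)
    data.frame(strain = gc@strain, compound_id = gc@compound_id,
               conc_um = gc@conc_um, media_mix = gc@media_mix,
               time_h = gc@times, od600 = gc@od, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Tabulate growth fits
#'
#' One row per curve and phase, suitable for the fits CSV.
#'
#' @param fits named list of \code{\link{GrowthFit}} objects
#' @return data.frame: curve_id, n_phases, phase, lag_h, max_rate,
#'   saturation, baseline, rss, converged
#' @export
fitsToTable <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    if (f@n_phases == 0L)
      return(data.frame(curve_id = id, n_phases = 0L, phase = NA_integer_,
                        lag_h = NA_real_, max_rate = NA_real_,
                        saturation = NA_real_, baseline = f@baseline,
                        rss = f@rss, converged = f@converged,
                        stringsAsFactors = FALSE))
    data.frame(curve_id = id, n_phases = f@n_phases,
               phase = f@phases$phase, lag_h = f@phases$lag_h,
               max_rate = f@phases$max_rate,
               saturation = f@phases$saturation, baseline = f@baseline,
               rss = f@rss, converged = f@converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
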