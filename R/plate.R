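#' Percent inhibition of growth
#'
#' Normalized endpoint score placing no-compound controls at 0 percent and
#' media blanks at 100 percent:
#' \deqn{PI = 100 (1 - (test - blank) / (control - blank)).}
#' Values above 100 (test below blank) and below 0 (growth stimulation) are
#' passed through unclipped.
#'
#' @param test OD600 of the compound well(s); vectorised
#' @param control_mean mean OD600 of no-compound control wells
#' @param blank_mean mean OD600 of media-only wells
#' @return percent inhibition
#' @examples
#' percentInhibition(0.55, 1.00, 0.10)  # 50
#' @export
percentInhibition <- function(test, control_mean, blank_mean) {
  if (control_mean <= blank_mean)
    stop("invalid plate: control mean must exceed blank mean (no-growth control failure)")
  100 * (1 - (test - blank_mean) / (control_mean - blank_mean))
}

#' Screening z-factor
#'
#' Assay-quality statistic
#' \deqn{z = 1 - 3 (\sigma_p + \sigma_n) / |\mu_p - \mu_n|}
#' computed on percent-inhibition values of positive and negative controls,
#' with sample (n - 1) standard deviations. z is at most 1; values above 0.5
#' conventionally indicate an assay suitable for high-throughput screening,
#' and negative values indicate overlapping control distributions.
#'
#' @param pos percent-inhibition values of positive (growth-killed) controls
#' @param neg percent-inhibition values of negative (untreated) controls
#' @return the z-factor (<= 1)
#' @examples
#' zFactor(c(90, 100, 110), c(-10, 0, 10))  # 0.4
#' @export
zFactor <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 values per control group")
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (isTRUE(all.equal(mu_p, mu_n)))
    stop("QC failure: control means are equal; z-factor undefined")
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Per-well percent inhibition for a plate set
#'
#' Computes, per plate and read time, the negative-control and blank means
#' from that plate only, and attaches percent inhibition to every compound
#' well. Positive-control wells (if present) are scored too so control
#' plates can feed \code{\link{zFactor}}.
#'
#' @param reads long-format reads data.frame (plate_id, well, time_min,
#'   channel, value)
#' @param map plate map data.frame (plate_id, well, role, compound_id,
#'   conc_um, strain)
#' @return data.frame with one row per scored well per read time:
#'   plate_id, well, role, compound_id, conc_um, read_time_h, od600,
#'   control_mean, blank_mean, percent_inhibition
#' @export
summarizePlate <- function(reads, map) {
  need <- c("plate_id", "well", "time_min", "channel", "value")
  if (!all(need %in% names(reads))) stop("reads must have columns: ",
                                         paste(need, collapse = ", "))
  reads <- reads[reads$channel == "od600", ]
  if (anyDuplicated(reads[, c("plate_id", "well", "time_min")]))
    stop("duplicate (plate, well, read time) entries in reads")
  key_m <- paste(map$plate_id, map$well)
  key_r <- paste(reads$plate_id, reads$well)
  if (!all(key_r %in% key_m)) stop("plate map does not cover all read wells")
  idx <- match(key_r, key_m)
  dat <- cbind(reads, map[idx, c("role", "compound_id", "conc_um"), drop = FALSE])
  dat$read_time_h <- dat$time_min / 60

  out <- lapply(split(dat, list(dat$plate_id, dat$read_time_h), drop = TRUE),
    function(d) {
      nc <- d$value[d$role == "neg_control"]
      bl <- d$value[d$role == "blank"]
      if (length(nc) < 1 || length(bl) < 1)
        stop(sprintf("plate %s at %g h: missing negative controls or blanks",
                     d$plate_id[1], d$read_time_h[1]))
      scored <- d[d$role %in% c("compound", "pos_control"), ]
      if (!nrow(scored)) return(NULL)
      data.frame(plate_id = scored$plate_id, well = scored$well,
                 role = scored$role, compound_id = scored$compound_id,
                 conc_um = scored$conc_um, read_time_h = scored$read_time_h,
                 od600 = scored$value,
                 control_mean = mean(nc), blank_mean = mean(bl),
                 percent_inhibition = percentInhibition(scored$value,
                                                        mean(nc), mean(bl)),
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$plate_id, out$read_time_h, out$well), ]
}

#' Plate quality-control report
#'
#' z-factor per plate and read time, computed from the percent inhibition of
#' positive-control wells against negative-control wells (the latter scored
#' against the same plate's control/blank means, hence centred at 0).
#'
#' @param reads,map as in \code{\link{summarizePlate}}; the map must contain
#'   pos_control wells
#' @return data.frame (plate_id, read_time_h, z_factor, n_pos, n_neg,
#'   suitable) where \code{suitable} flags z > 0.5
#' @export
plateQC <- function(reads, map) {
  reads <- reads[reads$channel == "od600", ]
  key_m <- paste(map$plate_id, map$well)
  idx <- match(paste(reads$plate_id, reads$well), key_m)
  dat <- cbind(reads, map[idx, c("role"), drop = FALSE])
  dat$read_time_h <- dat$time_min / 60
  out <- lapply(split(dat, list(dat$plate_id, dat$read_time_h), drop = TRUE),
    function(d) {
      nc <- d$value[d$role == "neg_control"]
      bl <- d$value[d$role == "blank"]
      pc <- d$value[d$role == "pos_control"]
      if (length(pc) < 2) return(NULL)
      pi_pos <- percentInhibition(pc, mean(nc), mean(bl))
      pi_neg <- percentInhibition(nc, mean(nc), mean(bl))
      z <- zFactor(pi_pos, pi_neg)
      data.frame(plate_id = d$plate_id[1], read_time_h = d$read_time_h[1],
                 z_factor = z, n_pos = length(pc), n_neg = length(nc),
                 suitable = z > 0.5, stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$plate_id, out$read_time_h), ]
}

#' Call primary-screen hits
#'
#' Compounds whose percent inhibition meets the threshold at the chosen read
#' time. Ordering is deterministic: by percent inhibition descending, then by
#' compound identifier.
#'
#' @param pi_table output of \code{\link{summarizePlate}}
#' @param threshold percent-inhibition threshold (must be given explicitly)
#' @param read_time_h read time in hours at which to call hits
#' @return data.frame of hit compounds (compound_id, plate_id, well,
#'   percent_inhibition)
#' @export
callHits <- function(pi_table, threshold, read_time_h) {
  if (missing(threshold)) stop("a hit threshold must be given explicitly")
  d <- pi_table[pi_table$role == "compound" &
                  pi_table$read_time_h == read_time_h, ]
  if (!nrow(pi_table[pi_table$read_time_h == read_time_h, ]))
    stop(sprintf("read time %g h absent from the table", read_time_h))
  hits <- d[d$percent_inhibition >= threshold, ]
  hits <- hits[order(-hits$percent_inhibition, hits$compound_id), ]
  rownames(hits) <- NULL
  hits[, c("compound_id", "plate_id", "well", "conc_um",
           "percent_inhibition")]
}

#' Compound concentration and solvent fraction at each dispensing stage
#'
#' Exact mass-balance arithmetic for the droplet dispensing protocol.
#' Compound amount is n_droplets x droplet volume x stock concentration;
#' concentration is amount over the cumulative well volume at the stage
#' (after droplet dispensing into the pre-dispensed medium, after the media
#' top-up, or after inoculation). Both the full volume accounting (droplet
#' volume included in the total) and the nominal convention that ignores the
#' nanolitre droplet volume are reported; the nominal values are the round
#' numbers a protocol sheet quotes (50 uM 5x stage, 10 uM / 0.1 percent DMSO
#' final).
#'
#' @param p a \code{\link{dispenseProtocol}}
#' @param stage "after_dispense", "after_topup" or "final_assay"
#' @return list with conc_um, conc_um_nominal, solvent_pct,
#'   solvent_pct_nominal, volume_ul
#' @examples
#' dispenseConcentration(dispenseProtocol(), "final_assay")
#' @export
dispenseConcentration <- function(p = dispenseProtocol(),
                                  stage = c("after_dispense", "after_topup",
                                            "final_assay")) {
  stage <- match.arg(stage)
  drop_ul <- p@n_droplets * p@droplet_vol_nl / 1000   # uL of DMSO stock
  amount_nmol <- drop_ul * p@stock_conc_mm            # uL * mM = nmol
  vol_nominal <- switch(stage,
    after_dispense = p@predispensed_vol_ul,
    after_topup    = p@predispensed_vol_ul + p@topup_vol_ul,
    final_assay    = p@predispensed_vol_ul + p@topup_vol_ul + p@inoculum_vol_ul)
  vol_exact <- vol_nominal + drop_ul
  list(conc_um = amount_nmol / vol_exact * 1000,
       conc_um_nominal = amount_nmol / vol_nominal * 1000,
       solvent_pct = 100 * drop_ul / vol_exact,
       solvent_pct_nominal = 100 * drop_ul / vol_nominal,
       volume_ul = vol_exact)
}
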