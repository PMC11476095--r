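#' Aggregate replicate wells
#'
#' Mean and sample SD of absorbance over replicate wells for one channel and
#' stage, keyed by isolate x condition x timepoint (and optionally
#' biological replicate). All `n_bio x n_tech` wells enter the arithmetic
#' mean; no outlier removal is applied.
#'
#' @param readings,layout As from [read_plate_long()] / [read_layout()].
#' @param channel `"OD570"` or `"OD600"`.
#' @param stage One of `growth_endpoint`, `rz_baseline`, `rz_final`.
#' @param per_bio_rep Keep biological replicates separate (adds a `bio_rep`
#'   column); used e.g. for the 24 h vs 48 h production ratios.
#' @return A `data.frame` with columns `isolate_id`, `factor`, `level`,
#'   (`bio_rep`,) `timepoint_h`, `channel`, `stage`, `n_wells`, `mean_od`,
#'   `sd_od`. `sd_od` is 0 when `n_wells` is 1.
#' @export
aggregate_wells <- function(readings, layout, channel = "OD570",
                            stage = "growth_endpoint", per_bio_rep = FALSE) {
  stopifnot(channel %in% CHANNELS, stage %in% STAGES)
  smp <- layout[layout$role == "sample", ]
  rd <- readings[readings$channel == channel & readings$stage == stage, ]
  mg <- merge(rd, smp, by = c("plate_id", "well"))
  if (nrow(mg) == 0) {
    stopf("no %s/%s readings found for sample wells", channel, stage)
  }
  keys <- c("isolate_id", "factor", "level",
            if (per_bio_rep) "bio_rep", "timepoint_h")
  mg$level[is.na(mg$level)] <- -Inf      # keep NA-level (baseline) groups
  out <- do.call(rbind, lapply(
    split(mg, mg[keys], drop = TRUE),
    function(g) {
      data.frame(g[1, keys, drop = FALSE],
                 channel = channel, stage = stage,
                 n_wells = nrow(g),
                 mean_od = mean(g$absorbance),
                 sd_od = sd0(g$absorbance),
                 stringsAsFactors = FALSE)
    }))
  out$level[is.infinite(out$level)] <- NA_real_
  out <- out[order(out$isolate_id, out$factor, out$level, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

#' Ro correction factor of the oxidized resazurin substrate
#'
#' Per plate, the ratio of mean OD570 to mean OD600 over sterility-control
#' wells at the pre-incubation (`rz_baseline`) read, when the substrate is
#' fully oxidized. Ro corrects the spectral overlap of resazurin in the
#' AR570 formula.
#'
#' @param readings,layout As from the readers.
#' @param plate_id Restrict to one plate (default: all plates with the
#'   required readings).
#' @return `data.frame` with columns `plate_id`, `ro`.
#' @export
compute_Ro <- function(readings, layout, plate_id = NULL) {
  ctrl <- layout[layout$role == "sterility_control", ]
  rd <- readings[readings$stage == "rz_baseline", ]
  mg <- merge(rd, ctrl[, c("plate_id", "well")], by = c("plate_id", "well"))
  if (!is.null(plate_id)) mg <- mg[mg$plate_id %in% plate_id, ]
  if (nrow(mg) == 0) stopf("no rz_baseline readings on sterility wells")
  out <- do.call(rbind, lapply(split(mg, mg$plate_id), function(g) {
    m570 <- mean(g$absorbance[g$channel == "OD570"])
    m600 <- mean(g$absorbance[g$channel == "OD600"])
    if (!is.finite(m570) || !is.finite(m600)) {
      stopf("plate %s lacks OD570 or OD600 at rz_baseline on sterility wells",
            g$plate_id[1])
    }
    if (m600 <= 0) stopf("Ro undefined for plate %s: mean OD600 <= 0",
                         g$plate_id[1])
    data.frame(plate_id = g$plate_id[1], ro = m570 / m600,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Corrected reduced-resazurin signal AR570
#'
#' `AR570 = (OD570 - OD600 * Ro) * 100`: the 570 nm absorbance in excess of
#' what the oxidized substrate alone would give, on a percent-like scale.
#' A non-positive value means no reduction was detectable; it is clamped to
#' 0 and flagged, mirroring the asterisk notation used for such cells in
#' reports.
#'
#' @param od570,od600 Absorbances (vectorized).
#' @param ro Ro factor (scalar or vector).
#' @return `data.frame` with columns `ar570` (clamped at 0) and `detectable`
#'   (`TRUE` iff the raw value is > 0).
#' @examples
#' compute_AR570(0.9, 0.4, 1.25)  # ar570 = 40, detectable
#' compute_AR570(0.5, 0.4, 1.25)  # exactly oxidized: 0, non-detectable
#' @export
compute_AR570 <- function(od570, od600, ro) {
  if (any(!is.finite(ro)) || any(ro <= 0)) stopf("invalid Ro factor")
  raw <- (od570 - od600 * ro) * 100
  data.frame(ar570 = pmax(0, raw), detectable = raw > 0)
}

#' Viability table from final resazurin reads
#'
#' For every isolate x condition x timepoint: on each plate (= biological
#' replicate), AR570 is computed from the technical-well mean OD570/OD600 at
#' `rz_final` using that plate's own Ro; plate-level values are then
#' averaged over biological replicates. `detectable` is `FALSE` (and the
#' stored value 0) when the averaged raw AR570 is non-positive.
#'
#' @param readings,layout As from the readers.
#' @return `data.frame` with columns `isolate_id`, `factor`, `level`,
#'   `timepoint_h`, `n_plates`, `ar570`, `detectable`.
#' @export
viability_table <- function(readings, layout) {
  ro <- compute_Ro(readings, layout)
  f570 <- aggregate_wells_plate(readings, layout, "OD570", "rz_final")
  f600 <- aggregate_wells_plate(readings, layout, "OD600", "rz_final")
  keyc <- c("plate_id", "isolate_id", "factor", "level", "timepoint_h")
  mg <- merge(f570, f600, by = keyc, suffixes = c("_570", "_600"))
  if (nrow(mg) < nrow(f570)) {
    miss <- f570[!(do.call(paste, f570[keyc]) %in% do.call(paste, mg[keyc])), ]
    stopf("missing OD600 rz_final readings for isolate %s (%s, t=%sh)",
          miss$isolate_id[1],
          condition_label(miss$factor[1], miss$level[1]),
          miss$timepoint_h[1])
  }
  mg <- merge(mg, ro, by = "plate_id")
  mg$raw <- (mg$mean_od_570 - mg$mean_od_600 * mg$ro) * 100
  keys <- c("isolate_id", "factor", "level", "timepoint_h")
  mg$level[is.na(mg$level)] <- -Inf
  out <- do.call(rbind, lapply(split(mg, mg[keys], drop = TRUE), function(g) {
    raw <- mean(g$raw)
    data.frame(g[1, keys, drop = FALSE], n_plates = nrow(g),
               ar570 = max(0, raw), detectable = raw > 0,
               stringsAsFactors = FALSE)
  }))
  out$level[is.infinite(out$level)] <- NA_real_
  out <- out[order(out$isolate_id, out$factor, out$level, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

# per-plate tech-well means (internal)
aggregate_wells_plate <- function(readings, layout, channel, stage) {
  smp <- layout[layout$role == "sample", ]
  rd <- readings[readings$channel == channel & readings$stage == stage, ]
  mg <- merge(rd, smp, by = c("plate_id", "well"))
  if (nrow(mg) == 0) stopf("no %s/%s readings for sample wells", channel, stage)
  keys <- c("plate_id", "isolate_id", "factor", "level", "timepoint_h")
  mg$level[is.na(mg$level)] <- -Inf
  out <- do.call(rbind, lapply(split(mg, mg[keys], drop = TRUE), function(g) {
    data.frame(g[1, keys, drop = FALSE], n_wells = nrow(g),
               mean_od = mean(g$absorbance), stringsAsFactors = FALSE)
  }))
  out$level[is.infinite(out$level)] <- NA_real_
  rownames(out) <- NULL
  out
}
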