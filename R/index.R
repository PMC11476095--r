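#' Biofilm absorbance per viable cell
#'
#' Divides the crystal-violet mean OD by the AR570 viability signal. Cells
#' whose viability is non-detectable get an undefined index (NA) with
#' reason `nondetectable_viability` — the asterisked cells of the assay's
#' per-cell figures.
#'
#' @param cv_mean Crystal-violet mean OD (vectorized).
#' @param ar570 Clamped AR570 values.
#' @param detectable Logical, viability detectable.
#' @return `data.frame` with columns `index`, `defined`, `undefined_reason`.
#' @examples
#' biofilm_per_viable(0.4, 40, TRUE)   # index 0.01
#' biofilm_per_viable(0.4, 0, FALSE)   # undefined, flagged
#' @export
biofilm_per_viable <- function(cv_mean, ar570, detectable) {
  index <- ifelse(detectable, cv_mean / ar570, NA_real_)
  data.frame(index = index, defined = detectable,
             undefined_reason = ifelse(detectable, "none",
                                       "nondetectable_viability"),
             stringsAsFactors = FALSE)
}

#' Per-cell index table for a whole dataset
#'
#' @param cv_summary From [aggregate_wells()].
#' @param viability From [viability_table()].
#' @return `data.frame` keyed by isolate x condition x timepoint with the
#'   columns of [biofilm_per_viable()].
#' @export
biofilm_index <- function(cv_summary, viability) {
  keys <- c("isolate_id", "factor", "level", "timepoint_h")
  mg <- merge(cv_summary[, c(keys, "mean_od")],
              viability[, c(keys, "ar570", "detectable")], by = keys)
  if (nrow(mg) < nrow(cv_summary)) {
    warnf("%d isolate x condition cells lack a viability record and were dropped",
          nrow(cv_summary) - nrow(mg))
  }
  out <- cbind(mg[, c(keys, "mean_od", "ar570")],
               biofilm_per_viable(mg$mean_od, mg$ar570, mg$detectable))
  out <- out[order(out$isolate_id, out$factor, out$level, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

#' Average index per condition x timepoint
#'
#' Arithmetic mean over isolates with a defined index; undefined cells are
#' excluded from both numerator and denominator. A key with no defined
#' index gets an NA average with a warning.
#'
#' @param indices From [biofilm_index()].
#' @return `data.frame` with columns `factor`, `level`, `timepoint_h`,
#'   `n_defined`, `average`.
#' @export
condition_average <- function(indices) {
  keys <- c("factor", "level", "timepoint_h")
  indices$level[is.na(indices$level)] <- -Inf
  out <- do.call(rbind, lapply(split(indices, indices[keys], drop = TRUE),
                               function(g) {
    def <- g$index[g$defined]
    if (length(def) == 0) {
      warnf("no defined index for %s t=%sh; average undefined",
            condition_label(g$factor[1],
                            ifelse(is.infinite(g$level[1]), NA, g$level[1])),
            g$timepoint_h[1])
    }
    data.frame(g[1, keys, drop = FALSE], n_defined = length(def),
               average = if (length(def)) mean(def) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$level[is.infinite(out$level)] <- NA_real_
  out <- out[order(out$factor, out$level, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

#' Flag the conditions with highest average per-cell production
#'
#' Within each factor family (temperature / NaCl / pH / baseline), flags
#' the condition x timepoint cell(s) whose average index is maximal — the
#' "green bubble" cells of the assay's per-cell figures. Ties are all
#' flagged. With `per_factor = FALSE` a single global argmax is taken.
#'
#' @param averages From [condition_average()].
#' @param per_factor Flag within each factor family (default) or globally.
#' @return Subset of `averages` rows that are flagged.
#' @export
flag_max_conditions <- function(averages, per_factor = TRUE) {
  av <- averages[!is.na(averages$average), , drop = FALSE]
  if (nrow(av) == 0) stopf("no defined averages to flag")
  groups <- if (per_factor) split(av, av$factor) else list(av)
  out <- do.call(rbind, lapply(groups, function(g) {
    g[g$average == max(g$average), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}
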