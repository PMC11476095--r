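#' Classification cutoff from sterility-control readings
#'
#' `ODc = mean(controls) + 3 * SD(controls)` with the sample SD (n - 1
#' denominator; defined as 0 for a single control well). Negative control
#' means are allowed (blanked instruments); ODc may then be small and
#' classification proceeds unchanged.
#'
#' @param controls Numeric vector of control-well ODs (>= 1 value).
#' @return `list(control_mean, control_sd, odc)`.
#' @examples
#' compute_cutoff(c(0.08, 0.10, 0.12))  # odc = 0.16
#' @export
compute_cutoff <- function(controls) {
  if (length(controls) < 1 || any(!is.finite(controls))) {
    stopf("compute_cutoff needs at least one finite control OD")
  }
  m <- mean(controls)
  s <- sd0(controls)
  list(control_mean = m, control_sd = s, odc = m + 3 * s)
}

#' Cutoffs for every condition x timepoint in a dataset
#'
#' Control wells are the sterility wells' `growth_endpoint` OD570 readings.
#' By default each condition x timepoint uses its own sterility wells
#' (pooled over that condition's plates, i.e. biological-replicate days);
#' `pool = TRUE` instead pools all sterility wells in the dataset per
#' timepoint, yielding one cutoff per timepoint.
#'
#' @param readings,layout As from the readers.
#' @param pool Pool control wells across conditions.
#' @return `data.frame` with columns `factor`, `level`, `timepoint_h`,
#'   `n_controls`, `control_mean`, `control_sd`, `odc`. When `pool = TRUE`
#'   the factor/level columns are `"pooled"`/`NA`.
#' @export
compute_cutoffs <- function(readings, layout, pool = FALSE) {
  ctrl <- layout[layout$role == "sterility_control", ]
  rd <- readings[readings$stage == "growth_endpoint" &
                   readings$channel == "OD570", ]
  mg <- merge(rd, ctrl, by = c("plate_id", "well"))
  if (nrow(mg) == 0) stopf("no growth_endpoint OD570 readings on sterility wells")
  if (pool) {
    mg$factor <- "pooled"
    mg$level <- NA_real_
  }
  keys <- c("factor", "level", "timepoint_h")
  mg$level[is.na(mg$level)] <- -Inf
  out <- do.call(rbind, lapply(split(mg, mg[keys], drop = TRUE), function(g) {
    co <- compute_cutoff(g$absorbance)
    data.frame(g[1, keys, drop = FALSE], n_controls = nrow(g),
               control_mean = co$control_mean, control_sd = co$control_sd,
               odc = co$odc, stringsAsFactors = FALSE)
  }))
  out$level[is.infinite(out$level)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Four-class producer classification of one OD against a cutoff
#'
#' Bands: non-producer `od <= odc`; weak `(odc, 2 odc]`; moderate
#' `(2 odc, 4 odc]`; strong `> 4 odc`. The published inequalities are
#' strict on both sides and leave the exact boundaries unassigned; the
#' half-open convention here makes the boundary (a measure-zero event)
#' deterministic.
#'
#' @param od Numeric vector of mean ODs.
#' @param odc Positive cutoff(s), recycled against `od`.
#' @return Ordered factor with levels `NP < WP < MP < SP`.
#' @examples
#' classify_od(c(0.05, 0.15, 0.45), odc = 0.10)  # NP WP SP
#' @export
classify_od <- function(od, odc) {
  if (any(!is.finite(odc)) || any(odc <= 0)) stopf("odc must be positive")
  r <- od / odc
  cls <- ifelse(r <= 1, "NP", ifelse(r <= 2, "WP", ifelse(r <= 4, "MP", "SP")))
  producer_factor(cls)
}

#' Classify every isolate x condition x timepoint
#'
#' Joins crystal-violet replicate summaries with matching cutoffs and
#' applies [classify_od()] to the replicate mean (all wells pooled; no
#' per-replicate majority vote). Provenance (mean OD and the ODc used) is
#' carried in the output.
#'
#' @param cv_summary From [aggregate_wells()] (channel OD570,
#'   growth_endpoint).
#' @param cutoffs From [compute_cutoffs()].
#' @return `data.frame` with columns `isolate_id`, `factor`, `level`,
#'   `timepoint_h`, `mean_od`, `odc`, `class`.
#' @export
classify_all <- function(cv_summary, cutoffs) {
  pooled <- identical(unique(cutoffs$factor), "pooled")
  by <- if (pooled) "timepoint_h" else c("factor", "level", "timepoint_h")
  mg <- merge(cv_summary, cutoffs[, c(by, "odc")], by = by)
  if (nrow(mg) < nrow(cv_summary)) {
    miss <- cv_summary[!(do.call(paste, cv_summary[by]) %in%
                           do.call(paste, mg[by])), ]
    stopf("no cutoff for key %s t=%sh",
          condition_label(miss$factor[1], miss$level[1]), miss$timepoint_h[1])
  }
  out <- data.frame(mg[, c("isolate_id", "factor", "level", "timepoint_h",
                           "mean_od", "odc")],
                    class = classify_od(mg$mean_od, mg$odc),
                    stringsAsFactors = FALSE)
  out <- out[order(out$isolate_id, out$factor, out$level, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

#' Tally producer classes at one condition x timepoint
#'
#' @param classes A classification table ([classify_all()] or
#'   [load_printed_classes()]).
#' @param timepoint_h Timepoint to tally.
#' @param factor,level Condition (defaults: the baseline assay).
#' @return Named integer vector over `NP`, `WP`, `MP`, `SP`; sums to the
#'   number of isolates at that key.
#' @export
tally_classes <- function(classes, timepoint_h, factor = "baseline",
                          level = NA) {
  sel <- classes$timepoint_h == timepoint_h & classes$factor == factor &
    (if (is.na(level)) is.na(classes$level) else
      !is.na(classes$level) & classes$level == level)
  tab <- table(producer_factor(classes$class[sel]))
  out <- as.integer(tab[PRODUCER_LEVELS])
  names(out) <- PRODUCER_LEVELS
  out
}

#' Cross-tabulate classes at two timepoints
#'
#' A 4 x 4 matrix of isolate-id sets: rows are the class at `timepoint_a`,
#' columns at `timepoint_b`. Every isolate classified at both timepoints
#' appears in exactly one cell.
#'
#' @param classes Classification table.
#' @param timepoint_a,timepoint_b The two timepoints (e.g. 24 and 48).
#' @param factor,level Condition (defaults: baseline).
#' @return 4 x 4 list matrix; each cell a character vector of isolate ids.
#' @export
cross_tab <- function(classes, timepoint_a = 24, timepoint_b = 48,
                      factor = "baseline", level = NA) {
  pick <- function(tp) {
    sel <- classes$timepoint_h == tp & classes$factor == factor &
      (if (is.na(level)) is.na(classes$level) else
        !is.na(classes$level) & classes$level == level)
    stats::setNames(as.character(classes$class[sel]), classes$isolate_id[sel])
  }
  a <- pick(timepoint_a)
  b <- pick(timepoint_b)
  ids <- intersect(names(a), names(b))
  if (length(ids) == 0) stopf("no isolates classified at both timepoints")
  out <- matrix(vector("list", 16), 4, 4,
                dimnames = list(PRODUCER_LEVELS, PRODUCER_LEVELS))
  for (i in PRODUCER_LEVELS) for (j in PRODUCER_LEVELS) {
    out[[i, j]] <- sort(ids[a[ids] == i & b[ids] == j])
  }
  out
}

#' Isolates classified as producers at least once
#'
#' @param classes Classification table.
#' @return Sorted character vector of isolates with any non-NP class.
#' @export
ever_producer <- function(classes) {
  sort(unique(classes$isolate_id[as.character(classes$class) != "NP"]))
}
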