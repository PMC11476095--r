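#' Read long-format well readings
#'
#' Reads a long ("tidy") CSV of plate-reader absorbance values, one row per
#' well x channel x timepoint x stage. This is the canonical input format:
#' multi-plate, multi-channel, multi-timepoint data does not fit a single
#' 8 x 12 grid export (see [grid_to_long()] for converting one grid).
#'
#' Expected columns: `plate_id`, `well`, `channel` (`OD570`/`OD600`),
#' `timepoint_h` (positive hours), `stage` (`growth_endpoint`, `rz_baseline`
#' or `rz_final`) and `absorbance` (optical density; may legitimately be
#' negative after instrument blanking — values are never clamped on input).
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal point).
#' @return A `data.frame` of well readings with the columns above.
#'   Row count equals the number of data rows in the file.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plate_id,well,channel,timepoint_h,stage,absorbance",
#'              "p1,A1,OD570,24,growth_endpoint,0.42"), f)
#' read_plate_long(f)
#' @export
read_plate_long <- function(path) {
  if (!file.exists(path)) stopf("readings file not found: %s", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(dat), READING_COLS)) {
    stopf("readings header must be exactly: %s",
          paste(READING_COLS, collapse = ","))
  }
  if (nrow(dat) == 0) {
    return(data.frame(plate_id = character(), well = character(),
                      channel = character(), timepoint_h = numeric(),
                      stage = character(), absorbance = numeric(),
                      stringsAsFactors = FALSE))
  }
  dat$timepoint_h <- suppressWarnings(as.numeric(dat$timepoint_h))
  dat$absorbance <- suppressWarnings(as.numeric(dat$absorbance))
  bad <- which(!is_valid_well(dat$well) |
                 !(dat$channel %in% CHANNELS) |
                 !(dat$stage %in% STAGES) |
                 is.na(dat$timepoint_h) | dat$timepoint_h <= 0 |
                 !is.finite(dat$absorbance))
  if (length(bad) > 0) {
    # +1 for the header row so the message points at the file line
    stopf("malformed reading at line %d of %s", bad[1] + 1L, path)
  }
  key <- paste(dat$plate_id, dat$well, dat$channel, dat$timepoint_h,
               dat$stage, sep = "\r")
  if (anyDuplicated(key)) {
    d <- dat[which(duplicated(key))[1], ]
    stopf("duplicate reading key: plate %s well %s channel %s t=%sh stage %s",
          d$plate_id, d$well, d$channel, d$timepoint_h, d$stage)
  }
  dat
}

#' Read a plate layout map
#'
#' Reads the CSV mapping wells to their role (`sample`, `sterility_control`,
#' `reference_control`), isolate, assay condition (`factor` + `level`) and
#' replicate indices. Every plate must carry at least one sterility-control
#' well, since the classification cutoff ODc is derived from those wells.
#'
#' Expected columns: `plate_id`, `well`, `role`, `isolate_id`, `factor`
#' (`baseline`, `temperature`, `nacl`, `ph`), `level` (numeric; empty for
#' baseline), `bio_rep`, `tech_rep`.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` layout satisfying the structural invariants.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stopf("layout file not found: %s", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(dat), LAYOUT_COLS)) {
    stopf("layout header must be exactly: %s",
          paste(LAYOUT_COLS, collapse = ","))
  }
  dat$level <- suppressWarnings(as.numeric(dat$level))
  dat$bio_rep <- suppressWarnings(as.integer(dat$bio_rep))
  dat$tech_rep <- suppressWarnings(as.integer(dat$tech_rep))
  validate_layout(dat)
  dat
}

validate_layout <- function(layout) {
  if (!all(is_valid_well(layout$well))) {
    stopf("invalid well coordinate in layout: %s",
          layout$well[!is_valid_well(layout$well)][1])
  }
  if (!all(layout$role %in% ROLES)) {
    stopf("unknown role in layout: %s",
          layout$role[!(layout$role %in% ROLES)][1])
  }
  if (!all(layout$factor %in% FACTOR_LEVELS)) {
    stopf("unknown condition factor in layout: %s",
          layout$factor[!(layout$factor %in% FACTOR_LEVELS)][1])
  }
  smp <- layout[layout$role == "sample", ]
  if (any(is.na(smp$isolate_id) | smp$isolate_id == "")) {
    stopf("sample well without isolate_id (plate %s well %s)",
          smp$plate_id[smp$isolate_id == ""][1],
          smp$well[smp$isolate_id == ""][1])
  }
  no_ctrl <- setdiff(unique(layout$plate_id),
                     unique(layout$plate_id[layout$role == "sterility_control"]))
  if (length(no_ctrl) > 0) {
    stopf("plate %s has no sterility_control well (sterility control required for ODc)",
          no_ctrl[1])
  }
  key <- paste(smp$isolate_id, smp$factor, smp$level, smp$bio_rep,
               smp$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    d <- smp[which(duplicated(key))[1], ]
    stopf("duplicate layout key: isolate %s %s bio_rep %d tech_rep %d",
          d$isolate_id, condition_label(d$factor, d$level), d$bio_rep,
          d$tech_rep)
  }
  invisible(TRUE)
}

#' Convert one 8 x 12 grid of absorbances to long readings
#'
#' Helper for plate readers that export a single grid per read.
#'
#' @param grid 8 x 12 numeric matrix (rows A-H, columns 1-12).
#' @param plate_id,channel,timepoint_h,stage Metadata applied to every well.
#' @param drop_na Drop `NA` cells (unused wells) instead of erroring.
#' @return A readings `data.frame` as from [read_plate_long()].
#' @export
grid_to_long <- function(grid, plate_id, channel, timepoint_h, stage,
                         drop_na = TRUE) {
  stopifnot(is.matrix(grid), nrow(grid) == 8, ncol(grid) == 12)
  out <- data.frame(
    plate_id = plate_id,
    well = paste0(rep(LETTERS[1:8], times = 12),
                  rep(1:12, each = 8)),
    channel = channel,
    timepoint_h = timepoint_h,
    stage = stage,
    absorbance = as.vector(grid),
    stringsAsFactors = FALSE
  )
  if (drop_na) out <- out[!is.na(out$absorbance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-check readings against a layout
#'
#' Structural validation that never throws: problems are returned as a
#' report. Errors: a reading whose (plate, well) is absent from the layout;
#' a sample well with no `growth_endpoint` reading. Warning: a plate with
#' `rz_final` readings (viability in use) but no `rz_baseline` read on its
#' sterility wells, which makes the Ro correction factor uncomputable.
#'
#' @param readings Readings as from [read_plate_long()].
#' @param layout Layout as from [read_layout()].
#' @return A `data.frame` with columns `severity` (`error`/`warning`),
#'   `message`, `location`; zero rows iff the dataset passes all checks.
#' @export
validate_plate_data <- function(readings, layout) {
  rep_rows <- list()
  add <- function(severity, message, location) {
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(
      severity = severity, message = message, location = location,
      stringsAsFactors = FALSE)
  }
  lay_key <- paste(layout$plate_id, layout$well)
  orphan <- !(paste(readings$plate_id, readings$well) %in% lay_key)
  for (i in which(orphan)) {
    add("error", "reading for a well absent from the layout",
        paste(readings$plate_id[i], readings$well[i]))
  }
  smp <- layout[layout$role == "sample", ]
  ge <- readings[readings$stage == "growth_endpoint", ]
  has_ge <- paste(smp$plate_id, smp$well) %in% paste(ge$plate_id, ge$well)
  for (i in which(!has_ge)) {
    add("error", "sample well missing a growth_endpoint reading",
        paste(smp$plate_id[i], smp$well[i]))
  }
  ctrl <- layout[layout$role == "sterility_control", ]
  for (p in unique(readings$plate_id[readings$stage == "rz_final"])) {
    base_p <- readings[readings$stage == "rz_baseline" &
                         readings$plate_id == p, ]
    ctrl_p <- ctrl[ctrl$plate_id == p, ]
    if (nrow(ctrl_p) > 0 &&
        !any(base_p$well %in% ctrl_p$well)) {
      add("warning",
          "plate uses viability (rz_final) but has no rz_baseline reading on sterility wells; Ro cannot be computed",
          p)
    }
  }
  if (length(rep_rows) == 0) {
    return(data.frame(severity = character(), message = character(),
                      location = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rep_rows)
}

#' Write / read a result table as TSV
#'
#' Tab-separated with a header row; numeric columns are written with 17
#' significant digits so that a write/read round trip reproduces the table
#' field-by-field.
#'
#' @param table A `data.frame`.
#' @param path Output path.
#' @return `write_tidy` invisibly returns `path`; `read_tidy` returns the
#'   `data.frame`.
#' @export
write_tidy <- function(table, path) {
  if (is.null(table)) stopf("table must be non-null")
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         sprintf("%.17g", out[[j]]))
    }
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write to %s", path)
  invisible(path)
}

#' @rdname write_tidy
#' @export
read_tidy <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
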