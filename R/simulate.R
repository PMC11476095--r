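#' Define a synthetic plate experiment
#'
#' Describes a multi-condition crystal-violet + resazurin assay with known
#' latent producer classes, from which [simulate_experiment()] draws
#' well-level readings. Class multipliers position each class's expected
#' crystal-violet signal inside its cutoff band: the implied cutoff is
#' `ODc = control_mean + 3 * control_sd`, and a cell of class `cl` has
#' expected signal `class_multipliers[cl] * ODc`.
#'
#' @param classes Latent truth: `data.frame` with columns `isolate_id`,
#'   `factor`, `level`, `timepoint_h`, `class` covering a full
#'   isolate x condition x timepoint grid.
#' @param n_bio,n_tech Biological (independent days = plates) and technical
#'   (wells within a plate) replicates per isolate x condition.
#' @param control_mean,control_sd Mean and SD (OD units) of sterility-well
#'   crystal-violet readings.
#' @param class_multipliers Named vector over `NP`,`WP`,`MP`,`SP`, in ODc
#'   units; must satisfy NP < 1 < WP < 2 < MP < 4 < SP.
#' @param noise_cv Coefficient of variation of multiplicative well noise.
#' @param bio_share Share of the noise variance attributed to the
#'   biological-day component (remainder is technical).
#' @param viability_slope Expected AR570 units per unit of expected
#'   crystal-violet OD (links the resazurin channel to biofilm signal).
#' @param ro True OD570/OD600 ratio of the oxidized resazurin substrate.
#' @param rz_od600 Baseline OD600 of the resazurin read.
#' @param seed Mandatory integer seed; there is no hidden global random
#'   state.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(classes, n_bio = 3, n_tech = 3,
                              control_mean = 0.10, control_sd = 0.02,
                              class_multipliers = c(NP = 0.5, WP = 1.5,
                                                    MP = 3, SP = 6),
                              noise_cv = 0.15, bio_share = 2 / 3,
                              viability_slope = 100, ro = 1.25,
                              rz_od600 = 0.40, seed) {
  if (missing(seed)) stopf("experiment_design requires an explicit seed")
  stopifnot(n_bio >= 1, n_tech >= 1, control_mean > 0, control_sd >= 0,
            noise_cv >= 0, bio_share >= 0, bio_share <= 1,
            viability_slope > 0, ro > 0, rz_od600 > 0)
  m <- class_multipliers
  if (!identical(sort(names(m)), sort(PRODUCER_LEVELS))) {
    stopf("class_multipliers must be named NP, WP, MP, SP")
  }
  if (!(m[["NP"]] < 1 && m[["WP"]] > 1 && m[["WP"]] < 2 &&
        m[["MP"]] > 2 && m[["MP"]] < 4 && m[["SP"]] > 4)) {
    stopf("class_multipliers must lie inside the threshold bands: NP < 1 < WP < 2 < MP < 4 < SP")
  }
  need <- c("isolate_id", "factor", "level", "timepoint_h", "class")
  stopifnot(all(need %in% names(classes)))
  classes$class <- as.character(classes$class)
  stopifnot(all(classes$class %in% PRODUCER_LEVELS))
  grid <- expand.grid(isolate_id = unique(classes$isolate_id),
                      cond = unique(condition_label(classes$factor, classes$level)),
                      timepoint_h = unique(classes$timepoint_h),
                      stringsAsFactors = FALSE)
  key <- paste(classes$isolate_id, condition_label(classes$factor, classes$level),
               classes$timepoint_h)
  if (anyDuplicated(key) || nrow(classes) != nrow(grid) ||
      !all(paste(grid$isolate_id, grid$cond, grid$timepoint_h) %in% key)) {
    stopf("classes must cover the full isolate x condition x timepoint grid exactly once")
  }
  structure(list(classes = classes, n_bio = n_bio, n_tech = n_tech,
                 control_mean = control_mean, control_sd = control_sd,
                 class_multipliers = m, noise_cv = noise_cv,
                 bio_share = bio_share, viability_slope = viability_slope,
                 ro = ro, rz_od600 = rz_od600, seed = as.integer(seed)),
            class = "experiment_design")
}

#' The default selected-panel study design
#'
#' The 10-isolate panel under the full condition grid: baseline (37 degC
#' growth medium), temperatures 4/10/20/37 degC, NaCl 1/2/4/8 % and pH
#' 5/6/7/8/9, at 24 and 48 h, with 3 biological x 3 technical replicates.
#' Latent classes are the packaged printed classifications
#' ([load_printed_classes()]).
#'
#' @param seed Integer seed passed to [experiment_design()].
#' @param ... Overrides forwarded to [experiment_design()].
#' @return An `experiment_design`.
#' @export
default_study_design <- function(seed, ...) {
  classes <- rbind(load_printed_classes("selected"),
                   load_printed_classes("temperature"),
                   load_printed_classes("nacl"),
                   load_printed_classes("ph"))
  experiment_design(classes = classes, seed = seed, ...)
}

#' Simulate well-level readings from a design
#'
#' Draws a complete dataset: one plate per condition x biological replicate,
#' each carrying all isolates' technical wells plus `n_ctrl` sterility
#' wells. Sterility crystal-violet readings are Normal(control_mean,
#' control_sd) truncated at 0. Sample crystal-violet readings are lognormal
#' around `multiplier x ODc` with total CV `noise_cv`, decomposed into a
#' per-day (biological) and per-well (technical) component. The resazurin
#' baseline read is oxidized everywhere (OD570 = ro x OD600, so AR570 = 0);
#' at the final read, sample wells gain reduced signal with expectation
#' `viability_slope x` the well's crystal-violet signal.
#'
#' @param design An [experiment_design()].
#' @param n_ctrl Sterility-control wells per plate.
#' @return `list(readings, layout, truth)`: readings and layout as the
#'   reader functions produce, truth the design's latent class table.
#'   Deterministic given `design$seed`.
#' @export
simulate_experiment <- function(design, n_ctrl = 3) {
  stopifnot(inherits(design, "experiment_design"))
  cls <- design$classes
  isolates <- unique(cls$isolate_id)
  conds <- unique(cls[, c("factor", "level")])
  tps <- sort(unique(cls$timepoint_h))
  n_iso <- length(isolates)
  n_wells <- n_iso * design$n_tech + n_ctrl
  if (n_wells > 96) stopf("design needs %d wells per plate (max 96)", n_wells)
  odc <- design$control_mean + 3 * design$control_sd
  sig_tot <- sqrt(log(1 + design$noise_cv^2))
  sig_bio <- sig_tot * sqrt(design$bio_share)
  sig_tec <- sig_tot * sqrt(1 - design$bio_share)
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))[1:n_wells]
  smp_wells <- wells[seq_len(n_iso * design$n_tech)]
  ctl_wells <- wells[(n_iso * design$n_tech + 1):n_wells]
  mult <- design$class_multipliers

  with_seed(design$seed, {
    readings <- list()
    layouts <- list()
    for (ci in seq_len(nrow(conds))) {
      fac <- conds$factor[ci]
      lev <- conds$level[ci]
      clab <- condition_label(fac, lev)
      cls_c <- cls[condition_label(cls$factor, cls$level) == clab, ]
      for (b in seq_len(design$n_bio)) {
        plate <- paste0(gsub(":", "", clab), "_b", b)
        layouts[[plate]] <- data.frame(
          plate_id = plate,
          well = c(smp_wells, ctl_wells),
          role = c(rep("sample", length(smp_wells)),
                   rep("sterility_control", n_ctrl)),
          isolate_id = c(rep(isolates, each = design$n_tech),
                         rep("", n_ctrl)),
          factor = fac, level = lev, bio_rep = b,
          tech_rep = c(rep(seq_len(design$n_tech), times = n_iso),
                       seq_len(n_ctrl)),
          stringsAsFactors = FALSE)
        for (tp in tps) {
          # latent per-isolate class at this condition x timepoint
          rows <- cls_c[cls_c$timepoint_h == tp, ]
          m_iso <- mult[rows$class[match(isolates, rows$isolate_id)]]
          mu <- m_iso * odc                       # expected CV signal per isolate
          e_bio <- stats::rnorm(n_iso, 0, sig_bio) # one day effect per isolate
          e_tec <- stats::rnorm(n_iso * design$n_tech, 0, sig_tec)
          s <- rep(mu, each = design$n_tech) *
            exp(rep(e_bio, each = design$n_tech) + e_tec -
                  (sig_bio^2 + sig_tec^2) / 2)    # E[s] = mu
          ctrl_cv <- pmax(0, stats::rnorm(n_ctrl, design$control_mean,
                                          design$control_sd))
          od600_b <- design$rz_od600 *
            exp(stats::rnorm(n_wells, 0, sig_tec) - sig_tec^2 / 2)
          od600_f <- design$rz_od600 *
            exp(stats::rnorm(n_wells, 0, sig_tec) - sig_tec^2 / 2)
          delta <- (design$viability_slope * s / 100) *
            exp(stats::rnorm(length(s), 0, sig_tec) - sig_tec^2 / 2)
          add <- function(well, channel, stage, ab) {
            data.frame(plate_id = plate, well = well, channel = channel,
                       timepoint_h = tp, stage = stage, absorbance = ab,
                       stringsAsFactors = FALSE)
          }
          readings[[length(readings) + 1]] <- rbind(
            add(wells, "OD570", "growth_endpoint", c(s, ctrl_cv)),
            add(wells, "OD600", "rz_baseline", od600_b),
            add(wells, "OD570", "rz_baseline", design$ro * od600_b),
            add(wells, "OD600", "rz_final", od600_f),
            add(wells, "OD570", "rz_final",
                design$ro * od600_f + c(delta, rep(0, n_ctrl))))
        }
      }
    }
    readings <- do.call(rbind, readings)
    layout <- do.call(rbind, layouts)
    rownames(readings) <- rownames(layout) <- NULL
    truth <- cls
    truth$class <- producer_factor(truth$class)
    list(readings = readings, layout = layout, truth = truth)
  })
}
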