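#' Full biofilm-assay analysis
#'
#' Single entry point running every stage on a validated dataset:
#' replicate aggregation, viability correction, cutoff computation and
#' producer classification, per-condition tallies, the baseline 24 h vs
#' 48 h cross-tabulation, biofilm-per-viable-cell indices with condition
#' averages and highest-production flags, the rank-product timepoint
#' comparison, PCA, and the UPGMA producer dendrogram cut into ranked
#' clusters.
#'
#' @param readings,layout As from [read_plate_long()] / [read_layout()].
#' @param pool_cutoffs Pool sterility wells across conditions
#'   ([compute_cutoffs()]).
#' @param alpha,B Rank-product significance level and Monte Carlo null
#'   size ([rank_product_test()]).
#' @param rp_timepoints Length-2 vector: denominator and numerator
#'   timepoints of the production ratio (default `c(24, 48)`).
#' @param n_components,standardize PCA settings ([assay_pca()]).
#' @param include_viability Include AR570 columns in the feature matrix.
#' @param k Number of dendrogram clusters ([cut_clusters()]).
#' @param seed Seed for the stochastic stages (rank-product null).
#' @return Object of class `biofilm_analysis` with components
#'   `cv_summary`, `viability`, `cutoffs`, `classes`, `tallies`,
#'   `cross_tab`, `index`, `averages`, `flags`, `ratios`, `rp`,
#'   `features`, `pca`, `dendrogram`, `clusters`, `newick`, `config`.
#' @examples
#' sim <- simulate_experiment(default_study_design(seed = 1))
#' fit <- biofilm_analysis(sim$readings, sim$layout, B = 200, seed = 1)
#' summary(fit)
#' @export
biofilm_analysis <- function(readings, layout, pool_cutoffs = FALSE,
                             alpha = 0.05, B = 10000,
                             rp_timepoints = c(24, 48), n_components = 3,
                             standardize = TRUE, include_viability = TRUE,
                             k = 3, seed) {
  if (missing(seed)) stopf("biofilm_analysis requires an explicit seed")
  rep <- validate_plate_data(readings, layout)
  if (any(rep$severity == "error")) {
    stopf("validation failed: %s (%s)",
          rep$message[rep$severity == "error"][1],
          rep$location[rep$severity == "error"][1])
  }
  cv_summary <- aggregate_wells(readings, layout, "OD570", "growth_endpoint")
  cv_by_rep <- aggregate_wells(readings, layout, "OD570", "growth_endpoint",
                               per_bio_rep = TRUE)
  viability <- viability_table(readings, layout)
  cutoffs <- compute_cutoffs(readings, layout, pool = pool_cutoffs)
  classes <- classify_all(cv_summary, cutoffs)
  conds <- unique(classes[, c("factor", "level", "timepoint_h")])
  tallies <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    tl <- tally_classes(classes, conds$timepoint_h[i], conds$factor[i],
                        conds$level[i])
    data.frame(conds[i, ], t(tl), stringsAsFactors = FALSE)
  }))
  rownames(tallies) <- NULL
  tps <- sort(unique(classes$timepoint_h))
  xtab <- if (length(tps) >= 2) cross_tab(classes, tps[1], tps[2]) else NULL
  idx <- biofilm_index(cv_summary, viability)
  averages <- condition_average(idx)
  flags <- flag_max_conditions(averages)
  ratios <- ratio_24_48(cv_by_rep, rp_timepoints[1], rp_timepoints[2])
  rp <- rank_product_test(ratios, B = B, seed = seed, alpha = alpha)
  features <- feature_matrix(cv_summary,
                             if (include_viability) viability else NULL)
  pca <- assay_pca(features, n_components = n_components,
                   standardize = standardize)
  dend <- upgma(features, standardize = standardize)
  production <- vapply(split(cv_summary$mean_od, cv_summary$isolate_id),
                       mean, numeric(1))
  clusters <- cut_clusters(dend, k = k, production = production)
  structure(list(cv_summary = cv_summary, viability = viability,
                 cutoffs = cutoffs, classes = classes, tallies = tallies,
                 cross_tab = xtab, index = idx, averages = averages,
                 flags = flags, ratios = ratios, rp = rp,
                 features = features, pca = pca, dendrogram = dend,
                 clusters = clusters, newick = to_newick(dend),
                 config = list(pool_cutoffs = pool_cutoffs, alpha = alpha,
                               B = B, rp_timepoints = rp_timepoints,
                               n_components = n_components,
                               standardize = standardize,
                               include_viability = include_viability,
                               k = k, seed = seed)),
            class = "biofilm_analysis")
}

#' @export
print.biofilm_analysis <- function(x, ...) {
  cat("Biofilm assay analysis\n")
  cat(sprintf("  %d isolates, %d condition x timepoint cells\n",
              length(unique(x$classes$isolate_id)),
              nrow(unique(x$classes[, c("factor", "level", "timepoint_h")]))))
  cat(sprintf("  rank-product: %d/%d isolates significant at alpha = %g\n",
              sum(x$rp$significant), nrow(x$rp), x$config$alpha))
  cat(sprintf("  PCA: %d components, %.1f%% of variance; %d clusters\n",
              x$config$n_components, 100 * sum(x$pca$variance_fraction),
              x$config$k))
  invisible(x)
}

#' @export
summary.biofilm_analysis <- function(object, ...) {
  x <- object
  print(x)
  base <- x$tallies[x$tallies$factor == "baseline", ]
  if (nrow(base) > 0) {
    n <- length(unique(x$classes$isolate_id))
    for (i in seq_len(nrow(base))) {
      cat(sprintf("  baseline %gh: %d/%d NP, %d WP, %d MP, %d SP\n",
                  base$timepoint_h[i], base$NP[i], n, base$WP[i],
                  base$MP[i], base$SP[i]))
    }
  }
  sig <- x$rp$isolate_id[x$rp$significant]
  if (length(sig)) {
    cat("  significant 24h vs 48h shifts: ", paste(sig, collapse = ", "),
        "\n", sep = "")
  }
  best <- x$clusters$leaf[x$clusters$cluster == 1]
  cat("  best-producer cluster: ", paste(best, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.biofilm_analysis <- function(x, which = c("dendrogram", "scree"), ...) {
  which <- match.arg(which)
  if (which == "dendrogram") {
    plot(stats::as.hclust(x$dendrogram),
         main = "UPGMA producer dendrogram", xlab = "", sub = "",
         ylab = "Euclidean distance", ...)
  } else {
    graphics::barplot(100 * x$pca$variance_fraction,
                      names.arg = paste0("PC", seq_along(x$pca$variance_fraction)),
                      ylab = "% variance explained", ...)
  }
  invisible(x)
}

#' Radar-chart-ready long table
#'
#' One row per isolate x condition x timepoint x detection method, with
#' values copied unchanged from the crystal-violet summaries and the
#' viability table — the layout radar-chart tools consume.
#'
#' @param cv_summary From [aggregate_wells()].
#' @param viability Optional, from [viability_table()].
#' @return `data.frame` with columns `isolate_id`, `factor`, `level`,
#'   `timepoint_h`, `method` (`crystal_violet` / `resazurin`), `value`.
#' @export
radar_long <- function(cv_summary, viability = NULL) {
  out <- data.frame(cv_summary[, c("isolate_id", "factor", "level",
                                   "timepoint_h")],
                    method = "crystal_violet", value = cv_summary$mean_od,
                    stringsAsFactors = FALSE)
  if (!is.null(viability)) {
    out <- rbind(out, data.frame(
      viability[, c("isolate_id", "factor", "level", "timepoint_h")],
      method = "resazurin", value = viability$ar570,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param readings,layout Paths to the input CSVs.
#' @param out_dir Output directory (created if absent).
#' @param ... Analysis settings forwarded to [biofilm_analysis()].
#' @param seed Mandatory seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(readings, layout, out_dir, seed, ...) {
  if (missing(seed)) stopf("pipeline_config requires an explicit seed")
  structure(list(readings = readings, layout = layout, out_dir = out_dir,
                 seed = seed, analysis = list(...)),
            class = "pipeline_config")
}

#' Run the full pipeline and write its artifacts
#'
#' Reads and validates the inputs, runs [biofilm_analysis()], and writes
#' 13 plain-text artifacts plus a JSON run manifest (configuration, seed,
#' package and R versions, artifact checksums) to `out_dir`. Deterministic:
#' the same configuration and seed reproduce byte-identical artifacts.
#'
#' @param config From [pipeline_config()].
#' @return Invisibly, the `biofilm_analysis` object, with attribute
#'   `"artifacts"` naming the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  readings <- read_plate_long(config$readings)
  layout <- read_layout(config$layout)
  rep <- validate_plate_data(readings, layout)
  if (any(rep$severity == "error")) {
    stopf("pipeline validation failed at stage plate_model: %s (%s)",
          rep$message[rep$severity == "error"][1],
          rep$location[rep$severity == "error"][1])
  }
  fit <- do.call(biofilm_analysis,
                 c(list(readings = readings, layout = layout,
                        seed = config$seed), config$analysis))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  xtab_long <- do.call(rbind, lapply(PRODUCER_LEVELS, function(i) {
    do.call(rbind, lapply(PRODUCER_LEVELS, function(j) {
      ids <- fit$cross_tab[[i, j]]
      if (length(ids) == 0) return(NULL)
      data.frame(class_a = i, class_b = j, isolate_id = ids,
                 stringsAsFactors = FALSE)
    }))
  }))
  pca_long <- rbind(
    data.frame(kind = "score",
               name = rep(rownames(fit$pca$scores), ncol(fit$pca$scores)),
               component = rep(seq_len(ncol(fit$pca$scores)),
                               each = nrow(fit$pca$scores)),
               value = as.vector(fit$pca$scores), stringsAsFactors = FALSE),
    data.frame(kind = "loading",
               name = rep(rownames(fit$pca$loadings), ncol(fit$pca$loadings)),
               component = rep(seq_len(ncol(fit$pca$loadings)),
                               each = nrow(fit$pca$loadings)),
               value = as.vector(fit$pca$loadings), stringsAsFactors = FALSE),
    data.frame(kind = "variance_fraction", name = "",
               component = seq_along(fit$pca$variance_fraction),
               value = fit$pca$variance_fraction, stringsAsFactors = FALSE))
  artifacts <- c(
    cv_summary = write_tidy(fit$cv_summary, path("cv_summary.tsv")),
    viability = write_tidy(fit$viability, path("viability.tsv")),
    classes = write_tidy(fit$classes, path("classes.tsv")),
    tallies = write_tidy(fit$tallies, path("tallies.tsv")),
    cross_tab = write_tidy(xtab_long, path("cross_tab.tsv")),
    index = write_tidy(fit$index, path("index.tsv")),
    averages = write_tidy(fit$averages, path("averages.tsv")),
    flags = write_tidy(fit$flags, path("flags.tsv")),
    rp = write_tidy(fit$rp, path("rp.tsv")),
    pca = write_tidy(pca_long, path("pca.tsv")),
    clusters = write_tidy(fit$clusters, path("clusters.tsv")),
    newick = {
      writeLines(fit$newick, path("tree.nwk"))
      path("tree.nwk")
    },
    radar_long = write_tidy(radar_long(fit$cv_summary, fit$viability),
                            path("radar_long.tsv")))
  manifest <- list(
    package = "biofilmq",
    version = as.character(utils::packageVersion("biofilmq")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = c(list(readings = config$readings, layout = config$layout),
               fit$config),
    n_readings = nrow(readings),
    artifacts = as.list(tools::md5sum(unname(artifacts))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message(sprintf("pipeline: %d readings -> %d artifacts in %s",
                  nrow(readings), length(artifacts), config$out_dir))
  attr(fit, "artifacts") <- artifacts
  invisible(fit)
}
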