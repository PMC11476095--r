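#' Isolate x variable feature matrix
#'
#' Concatenates, per isolate, the crystal-violet mean ODs and (optionally)
#' the AR570 viability values over all condition x timepoint cells — the
#' input of the PCA and dendrogram stages. Non-detectable viability enters
#' as 0, consistent with the AR570 clamp rule.
#'
#' @param cv_summary From [aggregate_wells()].
#' @param viability From [viability_table()]; `NULL` for crystal violet
#'   only.
#' @return Numeric matrix, isolates in rows (rownames set), one column per
#'   condition x timepoint x measurement.
#' @export
feature_matrix <- function(cv_summary, viability = NULL) {
  wide <- function(df, value, tag) {
    cell <- paste0(tag, ".", condition_label(df$factor, df$level), ".",
                   df$timepoint_h, "h")
    ids <- sort(unique(df$isolate_id))
    cols <- unique(cell)
    m <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
    m[cbind(match(df$isolate_id, ids), match(cell, cols))] <- df[[value]]
    m
  }
  m <- wide(cv_summary, "mean_od", "cv")
  if (!is.null(viability)) {
    v <- wide(viability, "ar570", "rz")
    if (!identical(rownames(m), rownames(v))) {
      stopf("cv_summary and viability cover different isolates")
    }
    m <- cbind(m, v)
  }
  if (anyNA(m)) stopf("feature matrix has missing cells")
  m
}

#' Principal component analysis of the assay matrix
#'
#' Column-centered (and, by default, unit-variance standardized — the
#' columns mix OD and AR570 units) PCA via the singular value
#' decomposition. Components are sorted by explained variance; each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param x Numeric matrix, observations in rows.
#' @param n_components Number of components to return.
#' @param standardize Scale columns to unit variance.
#' @return Object of class `assay_pca`: `scores` (n x m), `loadings`
#'   (p x m), `variance_fraction` (length m, non-increasing), `center`,
#'   `scale`, `rank`.
#' @export
assay_pca <- function(x, n_components = 3, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("PCA needs >= 2 rows")
  if (anyNA(x)) stopf("PCA input must not contain missing values (impute first)")
  if (standardize && any(apply(x, 2, stats::sd) == 0)) {
    stopf("cannot standardize: zero-variance column present")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  rk <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_components > rk) {
    stopf("n_components (%d) exceeds matrix rank (%d)", n_components, rk)
  }
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2,
                    flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = (pc$sdev^2 / sum(pc$sdev^2))[
                   seq_len(n_components)],
                 center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 rank = rk),
            class = "assay_pca")
}

#' @export
print.assay_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components, %.1f%% of variance\n",
              length(x$variance_fraction),
              100 * sum(x$variance_fraction)))
  print(round(x$variance_fraction, 4))
  invisible(x)
}

#' UPGMA dendrogram on Euclidean distances
#'
#' Agglomerative average-linkage (UPGMA) clustering: the two closest
#' clusters merge at a height equal to the mean pairwise distance between
#' their members; heights are therefore non-decreasing (ultrametric). Ties
#' in the minimum distance are broken deterministically towards the pair
#' whose lexicographically smallest leaf labels come first.
#'
#' @param x Numeric matrix with rownames (leaf labels), or `NULL` if `d`
#'   is given.
#' @param standardize Scale columns to unit variance before computing
#'   distances.
#' @param d Optional precomputed `dist` object (overrides `x`).
#' @return Object of class `biofilm_dendrogram`: `merge` and `height` in
#'   [stats::hclust()] convention, `labels`, `order`.
#' @export
upgma <- function(x = NULL, standardize = FALSE, d = NULL) {
  if (is.null(d)) {
    x <- as.matrix(x)
    if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
    if (standardize) x <- scale(x)
    d <- stats::dist(x)
  }
  labels <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  n <- attr(d, "Size")
  if (n < 2) stopf("UPGMA needs >= 2 leaves")
  D <- as.matrix(d)
  if (anyNA(D) || any(!is.finite(D))) stopf("NaN or infinite distance")
  diag(D) <- Inf
  # active cluster bookkeeping
  size <- rep(1L, n)
  id <- -seq_len(n)                      # hclust convention: leaves negative
  minlab <- labels                       # smallest member label per cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n))
  for (s in seq_len(n - 1)) {
    idx <- which(active)
    Dsub <- D[idx, idx, drop = FALSE]
    mn <- min(Dsub)
    cand <- which(Dsub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: sort each pair's two smallest leaf labels
    keyf <- apply(cand, 1, function(p) {
      paste(sort(c(minlab[idx[p[1]]], minlab[idx[p[2]]])), collapse = "\r")
    })
    pick <- cand[order(keyf)[1], ]
    i <- idx[pick[1]]
    j <- idx[pick[2]]
    a <- id[i]; b <- id[j]
    merge[s, ] <- sort(c(a, b))
    height[s] <- mn
    # Lance-Williams update keeps D[k, new] = mean pairwise distance
    new_d <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- new_d
    D[, i] <- new_d
    D[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    id[i] <- s
    minlab[i] <- min(minlab[i], minlab[j])
    members[[i]] <- c(members[[i]], members[[j]])
  }
  structure(list(merge = merge, height = height, labels = labels,
                 order = members[[which(active)]]),
            class = "biofilm_dendrogram")
}

#' @export
print.biofilm_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, heights %.4g .. %.4g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.biofilm_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Cuts at a height yielding exactly `k` clusters (an error if tied merge
#' heights make that count unattainable). If per-leaf production values
#' are supplied, clusters are numbered 1..k by decreasing mean production
#' and tagged `best` / `intermediate` / `worst`.
#'
#' @param dend A `biofilm_dendrogram`.
#' @param k Number of clusters, 1..n.
#' @param production Optional named numeric vector (mean crystal-violet OD
#'   per leaf) used to rank clusters.
#' @return `data.frame` with columns `leaf`, `cluster` and (with
#'   `production`) `quality`.
#' @export
cut_clusters <- function(dend, k, production = NULL) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stopf("k must be in 1..%d", n)
  h <- dend$height
  n_merge <- n - k
  if (n_merge < n - 1 && n_merge >= 1 && h[n_merge] == h[n_merge + 1]) {
    stopf("cannot cut into exactly %d clusters: tied merge heights", k)
  }
  if (k == n && n >= 2 && h[1] == 0) {
    stopf("cannot cut into exactly %d clusters: duplicate leaves merge at height 0", k)
  }
  grp <- -seq_len(n)                   # cluster id per leaf: start singleton
  if (n_merge >= 1) {
    node_of <- integer(n_merge)        # which group label a merge produced
    for (s in seq_len(n_merge)) {
      a <- dend$merge[s, 1]
      b <- dend$merge[s, 2]
      ga <- if (a < 0) -a else node_of[a]
      gb <- if (b < 0) -b else node_of[b]
      # relabel: all leaves in groups ga/gb now belong to merge node s
      sel <- grp == grp[ga] | grp == grp[gb]
      grp[sel] <- s
      node_of[s] <- which(sel)[1]
    }
  }
  cluster <- as.integer(factor(grp, levels = unique(grp)))
  out <- data.frame(leaf = dend$labels, cluster = cluster,
                    stringsAsFactors = FALSE)
  if (!is.null(production)) {
    if (is.null(names(production)) || !all(out$leaf %in% names(production))) {
      stopf("production must be named for every leaf")
    }
    pm <- vapply(split(production[out$leaf], out$cluster), mean, numeric(1))
    ord <- order(-pm)
    relabel <- match(out$cluster, as.integer(names(pm)[ord]))
    out$cluster <- relabel
    qual <- rep("intermediate", k)
    qual[1] <- "best"
    if (k >= 2) qual[k] <- "worst"
    out$quality <- qual[out$cluster]
  }
  out[order(out$cluster, out$leaf), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Newick export / import of a dendrogram
#'
#' Branch lengths are half the height difference between a node and its
#' parent, so the tree is ultrametric and the path length between two
#' leaves equals their UPGMA merge height. `from_newick` parses with
#' \pkg{ape} and rebuilds the merge structure from the cophenetic
#' distances (exact for ultrametric trees), so a write/read round trip is
#' lossless.
#'
#' @param dend A `biofilm_dendrogram`.
#' @param digits Significant digits for branch lengths.
#' @return `to_newick`: a Newick string. `from_newick`: a
#'   `biofilm_dendrogram`.
#' @export
to_newick <- function(dend, digits = 17) {
  n <- length(dend$labels)
  node_h <- c(rep(0, n), dend$height)      # leaf heights 0, then merges
  lab <- function(i) gsub("[ ,;:()\\[\\]]", "_", dend$labels[i])
  bl <- function(child_h, parent_h) {
    sprintf("%.*g", digits, (parent_h - child_h) / 2)
  }
  build <- function(node) {                 # node: merge index 1..n-1
    parts <- vapply(dend$merge[node, ], function(ch) {
      if (ch < 0) {
        paste0(lab(-ch), ":", bl(0, dend$height[node]))
      } else {
        paste0(build(ch), ":", bl(dend$height[ch], dend$height[node]))
      }
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(n - 1), ";")
}

#' @rdname to_newick
#' @param text A Newick string (ultrametric).
#' @export
from_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stopf("could not parse Newick string")
  coph <- stats::as.dist(ape::cophenetic.phylo(tr))
  upgma(d = coph)
}
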