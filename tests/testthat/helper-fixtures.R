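# Small in-code fixtures shared across tests.

# A minimal consistent dataset: one plate, two isolates x 3 tech wells,
# two sterility wells, one timepoint, all three stages on both channels.
tiny_dataset <- function(tp = 24) {
  lay <- data.frame(
    plate_id = "p1",
    well = c("A1", "A2", "A3", "B1", "B2", "B3", "H11", "H12"),
    role = c(rep("sample", 6), rep("sterility_control", 2)),
    isolate_id = c(rep("iso1", 3), rep("iso2", 3), "", ""),
    factor = "baseline", level = NA_real_,
    bio_rep = 1L, tech_rep = c(1:3, 1:3, 1:2),
    stringsAsFactors = FALSE)
  mk <- function(well, channel, stage, ab) {
    data.frame(plate_id = "p1", well = well, channel = channel,
               timepoint_h = tp, stage = stage, absorbance = ab,
               stringsAsFactors = FALSE)
  }
  wells <- lay$well
  od600 <- rep(0.4, 8)
  cv <- c(0.30, 0.32, 0.34, 0.10, 0.12, 0.11, 0.09, 0.11)
  rd <- rbind(
    mk(wells, "OD570", "growth_endpoint", cv),
    mk(wells, "OD600", "rz_baseline", od600),
    mk(wells, "OD570", "rz_baseline", 1.25 * od600),
    mk(wells, "OD600", "rz_final", od600),
    mk(wells, "OD570", "rz_final",
       1.25 * od600 + c(0.2, 0.22, 0.21, 0.05, 0.04, 0.06, 0, 0)))
  list(readings = rd, layout = lay)
}

# Write a readings/layout pair to temp CSVs; returns the two paths.
write_dataset_csv <- function(ds, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("ds")
    dir.create(dir)
  }
  rp <- file.path(dir, "readings.csv")
  lp <- file.path(dir, "layout.csv")
  write.csv(ds$readings, rp, row.names = FALSE, quote = FALSE)
  write.csv(ds$layout, lp, row.names = FALSE, quote = FALSE)
  list(readings = rp, layout = lp)
}

# Brute-force rank-product oracle: enumerates every tuple of observed
# ranks (one per replicate column) and counts products <= observed.
# Independent of the package implementation.
oracle_rank_product <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  rk_up <- apply(-mat, 2, rank, ties.method = "average")
  rk_dn <- apply(mat, 2, rank, ties.method = "average")
  if (k == 1) { rk_up <- cbind(rk_up); rk_dn <- cbind(rk_dn) }
  tuples_up <- do.call(expand.grid, lapply(seq_len(k), function(j) rk_up[, j]))
  tuples_dn <- do.call(expand.grid, lapply(seq_len(k), function(j) rk_dn[, j]))
  prods <- function(tp) apply(tp, 1, function(r) Reduce(`*`, r))
  null_up <- prods(tuples_up)
  null_dn <- prods(tuples_dn)
  obs_up <- apply(rk_up, 1, function(r) Reduce(`*`, r))
  obs_dn <- apply(rk_dn, 1, function(r) Reduce(`*`, r))
  N <- n^k
  data.frame(
    p_up = vapply(obs_up, function(o) (sum(null_up <= o) + 1) / (N + 1),
                  numeric(1)),
    p_down = vapply(obs_dn, function(o) (sum(null_dn <= o) + 1) / (N + 1),
                    numeric(1)))
}

# Random ultrametric distance matrix built from a random binary tree;
# returns list(d, heights, merges) where merges are leaf-set partitions.
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  labels <- sprintf("L%02d", seq_len(n))
  clusters <- as.list(labels)
  hs <- sort(runif(n - 1, 0.5, 10))
  hs <- hs + seq_along(hs) * 1e-3          # strictly increasing heights
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  sets <- list()
  for (s in seq_len(n - 1)) {
    pick <- sample(length(clusters), 2)
    a <- clusters[[pick[1]]]
    b <- clusters[[pick[2]]]
    D[a, b] <- hs[s]
    D[b, a] <- hs[s]
    clusters[[pick[1]]] <- c(a, b)
    clusters <- clusters[-pick[2]]
    sets[[s]] <- sort(c(a, b))
  }
  list(d = as.dist(D), heights = hs, sets = sets, labels = labels)
}

# Canonical signature of a dendrogram: per merge, the sorted member set
# and the height, ordered by height then members.
dend_signature <- function(dend, digits = 8) {
  n <- length(dend$labels)
  members <- vector("list", n - 1)
  sig <- character(n - 1)
  for (s in seq_len(n - 1)) {
    get <- function(ch) if (ch < 0) dend$labels[-ch] else members[[ch]]
    members[[s]] <- sort(c(get(dend$merge[s, 1]), get(dend$merge[s, 2])))
    sig[s] <- paste(signif(dend$height[s], digits),
                    paste(members[[s]], collapse = ","))
  }
  sort(sig)
}
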