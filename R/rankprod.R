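#' Per-replicate 48 h / 24 h production ratios
#'
#' One ratio per isolate x biological replicate from per-replicate
#' crystal-violet means at the two timepoints. Pairs with a missing or
#' non-positive denominator are dropped with a warning.
#'
#' @param cv_by_rep From `aggregate_wells(..., per_bio_rep = TRUE)`.
#' @param timepoint_a Denominator timepoint (default 24 h).
#' @param timepoint_b Numerator timepoint (default 48 h).
#' @param factor,level Condition (defaults: baseline).
#' @return `data.frame` with columns `isolate_id`, `bio_rep`, `ratio`.
#' @export
ratio_24_48 <- function(cv_by_rep, timepoint_a = 24, timepoint_b = 48,
                        factor = "baseline", level = NA) {
  sel <- cv_by_rep$factor == factor &
    (if (is.na(level)) is.na(cv_by_rep$level) else
      !is.na(cv_by_rep$level) & cv_by_rep$level == level)
  dat <- cv_by_rep[sel, ]
  a <- dat[dat$timepoint_h == timepoint_a, c("isolate_id", "bio_rep", "mean_od")]
  b <- dat[dat$timepoint_h == timepoint_b, c("isolate_id", "bio_rep", "mean_od")]
  mg <- merge(a, b, by = c("isolate_id", "bio_rep"), suffixes = c("_a", "_b"))
  bad <- !is.finite(mg$mean_od_a) | mg$mean_od_a <= 0 | !is.finite(mg$mean_od_b)
  if (any(bad)) {
    warnf("dropping %d isolate x replicate ratio(s) with non-positive or missing denominator",
          sum(bad))
    mg <- mg[!bad, , drop = FALSE]
  }
  out <- data.frame(isolate_id = mg$isolate_id, bio_rep = mg$bio_rep,
                    ratio = mg$mean_od_b / mg$mean_od_a,
                    stringsAsFactors = FALSE)
  out <- out[order(out$isolate_id, out$bio_rep), ]
  rownames(out) <- NULL
  out
}

#' Rank-product test across replicate rankings
#'
#' For each replicate column, isolates are ranked by ratio: descending for
#' the "up" test (largest ratio gets rank 1) and ascending for "down";
#' ties receive mid-ranks. The rank product is the geometric mean of an
#' isolate's ranks across the k replicates. Under the null, an isolate's
#' rank in each replicate is an independent uniform draw from that
#' replicate's observed ranks; the one-sided p-value is
#' `(# null RP <= observed + 1) / (N + 1)` where N is the number of null
#' values. The null is enumerated exhaustively over all n^k rank tuples
#' when `n^k <= exact_limit`, otherwise sampled with `B` Monte Carlo
#' draws (one tuple per draw, shared across isolates, so results are
#' invariant to input row order at a fixed seed).
#'
#' Both one-sided p-values are reported together with a two-sided
#' `p_value = min(1, 2 * min(p_up, p_down))`; `significant` compares the
#' two-sided p (optionally Benjamini-Hochberg adjusted) against `alpha`.
#'
#' @param ratios `data.frame` from [ratio_24_48()] (columns `isolate_id`,
#'   `bio_rep`, `ratio`) or a numeric matrix isolates x replicates with
#'   rownames.
#' @param B Monte Carlo null size (ignored in exact mode).
#' @param seed Seed for the Monte Carlo null (required unless exact).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default, matching raw p < alpha reporting) or
#'   `"BH"` for Benjamini-Hochberg across isolates.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` decides by `exact_limit`.
#' @param exact_limit Largest n^k enumerated exhaustively.
#' @return `data.frame` with one row per isolate: `rp_up`, `rp_down`
#'   (geometric-mean ranks), `p_up`, `p_down`, `p_value`, `direction`,
#'   `significant`, plus attribute `"null_size"`.
#' @export
rank_product_test <- function(ratios, B = 10000, seed = NULL, alpha = 0.05,
                              adjust = c("none", "BH"), exact = NULL,
                              exact_limit = 20000) {
  adjust <- match.arg(adjust)
  if (B < 1) stopf("B must be >= 1")
  if (is.data.frame(ratios)) {
    ids <- sort(unique(ratios$isolate_id))
    reps <- sort(unique(ratios$bio_rep))
    mat <- matrix(NA_real_, length(ids), length(reps),
                  dimnames = list(ids, paste0("rep", reps)))
    mat[cbind(match(ratios$isolate_id, ids), match(ratios$bio_rep, reps))] <-
      ratios$ratio
  } else {
    mat <- as.matrix(ratios)
    if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  }
  if (anyNA(mat)) stopf("ratio matrix has missing cells")
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2) stopf("rank_product_test needs >= 2 isolates")
  if (k < 1) stopf("rank_product_test needs >= 1 replicate column")
  rk_up <- apply(-mat, 2, rank, ties.method = "average")
  rk_dn <- apply(mat, 2, rank, ties.method = "average")
  if (k == 1) { rk_up <- cbind(rk_up); rk_dn <- cbind(rk_dn) }
  # products accumulated left to right so identical tuples are bitwise equal
  prod_rows <- function(m) {
    p <- m[, 1]
    for (j in seq_len(ncol(m))[-1]) p <- p * m[, j]
    p
  }
  obs_up <- prod_rows(rk_up)
  obs_dn <- prod_rows(rk_dn)
  use_exact <- if (is.null(exact)) n^k <= exact_limit else isTRUE(exact)
  # null draws use each column's sorted rank multiset, so the null depends
  # only on the data's tie pattern, never on input row order
  sup <- apply(rk_up, 2, sort)
  sdn <- apply(rk_dn, 2, sort)
  if (k == 1) { sup <- cbind(sup); sdn <- cbind(sdn) }
  if (use_exact) {
    null_up <- sup[, 1]
    null_dn <- sdn[, 1]
    for (j in seq_len(k)[-1]) {
      null_up <- as.vector(outer(null_up, sup[, j]))
      null_dn <- as.vector(outer(null_dn, sdn[, j]))
    }
  } else {
    if (is.null(seed)) stopf("seed is required for the Monte Carlo null")
    nulls <- with_seed(seed, {
      u <- sample.int(n, B, replace = TRUE)
      nu <- sup[u, 1]
      nd <- sdn[u, 1]
      for (j in seq_len(k)[-1]) {
        u <- sample.int(n, B, replace = TRUE)
        nu <- nu * sup[u, j]
        nd <- nd * sdn[u, j]
      }
      list(nu, nd)
    })
    null_up <- nulls[[1]]
    null_dn <- nulls[[2]]
  }
  N <- length(null_up)
  p_up <- (findInterval(obs_up, sort(null_up)) + 1) / (N + 1)
  p_dn <- (findInterval(obs_dn, sort(null_dn)) + 1) / (N + 1)
  p_two <- pmin(1, 2 * pmin(p_up, p_dn))
  p_cmp <- if (adjust == "BH") stats::p.adjust(p_two, "BH") else p_two
  out <- data.frame(
    isolate_id = rownames(mat),
    rp_up = obs_up^(1 / k),
    rp_down = obs_dn^(1 / k),
    p_up = p_up,
    p_down = p_dn,
    p_value = p_two,
    direction = ifelse(p_up <= p_dn, "up", "down"),
    significant = p_cmp < alpha,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_size") <- N
  attr(out, "exact") <- use_exact
  out
}
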