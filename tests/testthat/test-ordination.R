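test_that("variance concentrated in one column loads on one component", {
  x <- cbind(a = c(1, 2, 3, 4), b = 5, c = 5)
  p <- assay_pca(x, n_components = 1, standardize = FALSE)
  expect_equal(p$variance_fraction, 1)
  expect_equal(abs(p$loadings[, 1]), c(a = 1, b = 0, c = 0))
})

test_that("variance fractions match an independent eigendecomposition", {
  set.seed(31)
  x <- matrix(rnorm(9), 3, 3)
  p <- assay_pca(x, n_components = 2, standardize = FALSE)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$variance_fraction, (ev / sum(ev))[1:2])
  # standardized route against eigen of the correlation matrix
  xs <- matrix(rnorm(40), 8, 5)
  ps <- assay_pca(xs, n_components = 3, standardize = TRUE)
  evs <- eigen(cor(xs), symmetric = TRUE)$values
  expect_equal(ps$variance_fraction, (evs / sum(evs))[1:3])
})

test_that("duplicated rows get identical scores and full rank reconstructs", {
  set.seed(17)
  x <- matrix(rnorm(24), 6, 4)
  x[2, ] <- x[5, ]
  p <- assay_pca(x, n_components = 4, standardize = FALSE)
  expect_equal(p$scores[2, ], p$scores[5, ])
  recon <- p$scores %*% t(p$loadings)
  centered <- sweep(x, 2, p$center)
  expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(assay_pca(x, 4, FALSE)$variance_fraction), 1)
  expect_error(assay_pca(x, n_components = 5), "rank")
})

test_that("component signs follow the largest-magnitude-loading convention", {
  set.seed(23)
  x <- matrix(rnorm(50), 10, 5)
  p <- assay_pca(x, n_components = 3, standardize = TRUE)
  for (j in 1:3) {
    l <- p$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("UPGMA reproduces the hand-derived three-leaf dendrogram", {
  # d(A,B) = 1, d(A,C) = d(B,C) = 4: merge {A,B} at 1, then C at 4
  D <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dd <- upgma(d = as.dist(D))
  expect_equal(dd$height, c(1, 4))
  expect_equal(dend_signature(dd), c("1 A,B", "4 A,B,C"))
})

test_that("two leaves merge once at their distance", {
  x <- rbind(p = c(0, 0), q = c(3, 4))
  dd <- upgma(x)
  expect_equal(dd$height, 5)
  expect_equal(dend_signature(dd), "5 p,q")
})

test_that("heights are non-decreasing and match hclust average linkage", {
  set.seed(41)
  for (i in 1:5) {
    x <- matrix(rnorm(8 * 4), 8, 4,
                dimnames = list(paste0("s", 1:8), NULL))
    dd <- upgma(x)
    expect_true(all(diff(dd$height) >= 0))
    hc <- hclust(dist(x), method = "average")
    expect_equal(sort(dd$height), sort(hc$height))
    expect_equal(dend_signature(dd),
                 dend_signature(list(merge = hc$merge, height = hc$height,
                                     labels = hc$labels)))
  }
})

test_that("UPGMA recovers generating topology and heights from ultrametric input", {
  for (seed in 1:6) {
    n <- sample(4:8, 1)
    u <- random_ultrametric(n, seed)
    dd <- upgma(d = u$d)
    expect_equal(dd$height, u$heights)
    # compare merged leaf-sets directly
    members <- vector("list", n - 1)
    for (s in seq_len(n - 1)) {
      get <- function(ch) if (ch < 0) dd$labels[-ch] else members[[ch]]
      members[[s]] <- sort(c(get(dd$merge[s, 1]), get(dd$merge[s, 2])))
    }
    expect_equal(members, u$sets)
  }
})

test_that("distance ties break towards the lexicographically smallest leaves", {
  # three mutually equidistant points: first merge must be {X1, X2}
  D <- matrix(2, 3, 3, dimnames = list(c("X3", "X1", "X2"),
                                       c("X3", "X1", "X2")))
  diag(D) <- 0
  dd <- upgma(d = as.dist(D))
  members1 <- sort(dd$labels[-dd$merge[1, ]])
  expect_equal(members1, c("X1", "X2"))
})

test_that("Newick export round-trips losslessly and respects heights", {
  set.seed(53)
  x <- matrix(rnorm(7 * 5), 7, 5, dimnames = list(paste0("iso", 1:7), NULL))
  dd <- upgma(x)
  nwk <- to_newick(dd)
  back <- from_newick(nwk)
  expect_equal(dend_signature(back), dend_signature(dd))
  # path length between two leaves equals their merge height
  tr <- ape::read.tree(text = nwk)
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph[dd$labels, dd$labels],
               as.matrix(cophenetic(stats::as.hclust(dd)))[dd$labels,
                                                           dd$labels],
               tolerance = 1e-10)
})

test_that("cut_clusters spans k = 1 to k = n and ranks by production", {
  set.seed(61)
  x <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
  dd <- upgma(x)
  expect_equal(length(unique(cut_clusters(dd, 1)$cluster)), 1)
  expect_equal(length(unique(cut_clusters(dd, 6)$cluster)), 6)
  prod <- setNames(c(10, 1, 1, 1, 1, 1), paste0("s", 1:6))
  cl <- cut_clusters(dd, 3, production = prod)
  expect_equal(unique(cl$quality[cl$cluster == 1]), "best")
  expect_equal(unique(cl$quality[cl$cluster == 3]), "worst")
  # cluster 1 has the highest mean production
  means <- tapply(prod[cl$leaf], cl$cluster, mean)
  expect_true(all(diff(means) <= 0))
})

test_that("tied merge heights make some cluster counts unattainable", {
  D <- matrix(2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(D) <- 0
  dd <- upgma(d = as.dist(D))   # both merges at height 2
  expect_error(cut_clusters(dd, 2), "tied merge heights")
  expect_equal(length(unique(cut_clusters(dd, 1)$cluster)), 1)
  dup <- rbind(u = c(0, 0), v = c(0, 0), w = c(1, 1))
  ddd <- upgma(dup)
  expect_error(cut_clusters(ddd, 3), "height 0")
})
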