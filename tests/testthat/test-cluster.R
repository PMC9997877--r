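three_leaf_D <- function() {
  matrix(c(0, 1, 4,
           1, 0, 5,
           4, 5, 0), 3, byrow = TRUE,
         dimnames = list(c("l1", "l2", "l3"), c("l1", "l2", "l3")))
}

test_that("euclidean feature distances are metric", {
  feats <- tibble::tibble(id = c("o", "p"), f1 = c(0, 3), f2 = c(0, 4))
  D <- feature_distances(feats)
  expect_equal(D["o", "p"], 5)
  expect_equal(diag(D), c(o = 0, p = 0))

  withr::local_seed(9)
  rf <- tibble::tibble(id = paste0("s", 1:8))
  for (j in 1:5) rf[[paste0("f", j)]] <- rnorm(8)
  D <- feature_distances(rf)
  expect_equal(D, t(D))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }

  # identical vectors at distance zero; standardization zeroes dead columns
  same <- tibble::tibble(id = c("a", "b"), f1 = c(1, 1), f2 = c(2, 2))
  expect_equal(max(feature_distances(same)), 0)
  expect_equal(max(feature_distances(same, standardize = TRUE)), 0)
})

test_that("three-leaf linkages have hand-derivable heights and cuts", {
  D <- three_leaf_D()
  single <- linkage(D, "single")
  expect_equal(single$merges$height, c(1, 4))
  expect_equal(linkage(D, "complete")$merges$height, c(1, 5))
  expect_equal(linkage(D, "average")$merges$height, c(1, 4.5))
  expect_equal(linkage(D, "upgma")$merges$height, c(1, 4.5))

  cut2 <- cut_tree(single, 2)
  expect_equal(cut2$cluster, c(0L, 0L, 1L))
  expect_equal(cut_tree(single, 1)$cluster, rep(0L, 3))
  expect_equal(cut_tree(single, 3)$cluster, 0:2)
  expect_error(cut_tree(single, 4), class = "dftree_validation_error")
  expect_error(cut_tree(single, 0), class = "dftree_validation_error")

  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (m in c("single", "complete", "average", "median")) {
    expect_equal(linkage(D2, m)$merges$height, 2)
  }
  expect_error(linkage(D, "ward"), class = "dftree_validation_error")
})

test_that("linkage agrees with the from-scratch brute-force agglomerator", {
  withr::local_seed(101)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    D <- random_symmetric_distances(n)
    for (m in c("single", "complete", "average")) {
      got <- linkage(D, m)$merges
      want <- brute_force_linkage(D, m)
      expect_equal(got$left, want$left)
      expect_equal(got$right, want$right)
      expect_equal(got$height, want$height, tolerance = 1e-10)
      expect_true(!is.unsorted(got$height))
    }
  }
})

test_that("median linkage agrees with the geometric midpoint oracle", {
  withr::local_seed(202)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    X <- matrix(rnorm(n * 3), n)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    got <- linkage(D, "median")$merges
    want <- median_linkage_from_points(X)
    expect_equal(got$left, want$left)
    expect_equal(got$right, want$right)
    expect_equal(got$height, want$height, tolerance = 1e-8)
    expect_equal(linkage(D, "wpgmc")$merges, got)
  }
})

test_that("tie-breaking picks the lexicographically smallest node pair", {
  ids <- c("a", "b", "c", "d")
  D <- matrix(1, 4, 4, dimnames = list(ids, ids))
  diag(D) <- 0
  for (m in c("single", "complete", "average")) {
    tr <- linkage(D, m)
    # ties everywhere: (1,2) first, then (3,4), then the two pairs
    expect_equal(tr$merges$left, c(1, 3, 5))
    expect_equal(tr$merges$right, c(2, 4, 6))
  }
  # median shrinks distances after the first merge: the new node 5 sits at
  # squared distance 0.75 from leaves 3 and 4, tying (3,5) and (4,5);
  # the lexicographically smallest pair (3,5) must win
  trm <- linkage(D, "median")
  expect_equal(trm$merges$left, c(1, 3, 4))
  expect_equal(trm$merges$right, c(2, 5, 6))
})

test_that("monotone linkages agree with hclust on tie-free matrices", {
  withr::local_seed(77)
  for (rep in 1:6) {
    n <- sample(5:11, 1)
    D <- random_symmetric_distances(n)
    for (m in c("single", "complete", "average")) {
      hc <- stats::hclust(as.dist(D), method = m)
      expect_equal(linkage(D, m)$merges$height, hc$height, tolerance = 1e-10)
    }
    hm <- stats::hclust(as.dist(D^2), method = "median")
    expect_equal(linkage(D, "median")$merges$height, sqrt(pmax(hm$height, 0)),
                 tolerance = 1e-10)
  }
})

test_that("cut_tree partitions leaves and cut-by-height matches threshold components", {
  withr::local_seed(55)
  n <- 10
  D <- random_symmetric_distances(n)
  tr <- linkage(D, "single")
  for (k in 1:n) {
    cut <- cut_tree(tr, k)
    expect_equal(sort(unique(cut$cluster)), 0:(k - 1))
    expect_equal(length(cut$cluster), n)
  }
  # single-linkage height cut = connected components of the d <= h graph
  for (h in quantile(D[lower.tri(D)], c(0.2, 0.5, 0.8))) {
    cut <- cut_tree_height(tr, h)
    adj <- (D <= h)
    g <- threshold_components(adj)
    expect_equal(ari(cut$cluster, g), 1)
  }
})

test_that("newick export round-trips through an independent parser", {
  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(to_newick(linkage(D2, "single")), "(a:2,b:2);")

  tr <- linkage(three_leaf_D(), "single")
  nwk <- to_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("l1", "l2", "l3"))
  # topology: l1,l2 together, l3 outside
  pair <- ape::getMRCA(phy, c("l1", "l2"))
  expect_false(pair == ape::getMRCA(phy, c("l1", "l3")))
  # ultrametric: leaf depths all equal the root height
  depths <- ape::node.depth.edgelength(phy)[1:3]
  expect_equal(depths, rep(4, 3))

  withr::local_seed(303)
  D <- random_symmetric_distances(9)
  for (m in c("single", "complete", "average")) {
    tr <- linkage(D, m)
    phy <- ape::read.tree(text = to_newick(tr))
    expect_setequal(phy$tip.label, rownames(D))
    # same topology as the implementation's own cut at every k
    for (k in c(2, 4)) {
      expect_equal(ari(cut_tree(tr, k)$cluster,
                       stats::cutree(as.hclust(tr), k)), 1)
    }
  }

  # metacharacter labels are quoted and survive parsing (ape keeps the
  # surrounding quotes in the tip label; strip them for comparison)
  Dq <- matrix(c(0, 3, 3, 0), 2,
               dimnames = list(c("GENE (v1)", "b:c"), c("GENE (v1)", "b:c")))
  phy <- ape::read.tree(text = to_newick(linkage(Dq, "average")))
  expect_setequal(gsub("^'|'$", "", phy$tip.label), c("GENE (v1)", "b:c"))
})

test_that("median height inversions are tolerated and clamped in newick", {
  # near-equilateral triangle: merging the closest pair pulls the median
  # centre inside, closer to the third point than the first merge height
  X <- rbind(c(0, 0), c(1, 0), c(0.5, 1.05 * sqrt(3) / 2))
  D <- as.matrix(dist(X))
  dimnames(D) <- list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))
  tr <- linkage(D, "median")
  expect_lt(tr$merges$height[2], tr$merges$height[1])  # inversion
  expect_warning(nwk <- to_newick(tr), "clamped")
  phy <- ape::read.tree(text = nwk)
  expect_true(all(phy$edge.length >= 0))
})

test_that("merge trees expose tidy, glance and hclust views", {
  tr <- linkage(three_leaf_D(), "average")
  td <- tidy(tr)
  expect_equal(td$merge, 1:2)
  expect_equal(td$size, c(2L, 3L))
  gl <- glance(tr)
  expect_equal(gl$n_leaves, 3L)
  expect_true(gl$monotone)
  hc <- as.hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_equal(sort(hc$order), 1:3)
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
})
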