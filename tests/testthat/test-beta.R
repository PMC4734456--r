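test_that("UniFrac trivial geometries", {
  tree <- fourTipTree()
  a <- c(A = 1, B = 2, C = 0, D = 0)
  expect_equal(unweightedUnifrac(a, c(A = 5, B = 1, C = 0, D = 0), tree), 0)
  expect_equal(weightedUnifrac(a / sum(a) * 10, a, tree), 0)

  cherry <- ape::read.tree(text = "(A:1,B:2);")
  expect_equal(unweightedUnifrac(c(A = 1, B = 0), c(A = 0, B = 3), cherry), 1)
  expect_equal(weightedUnifrac(c(A = 1, B = 0), c(A = 0, B = 3), cherry), 1)

  # disjoint supports on the 4-tip tree: both metrics hit 1
  expect_equal(unweightedUnifrac(c(A = 1, B = 1, C = 0, D = 0),
                                 c(A = 0, B = 0, C = 2, D = 1), tree), 1)
  expect_equal(weightedUnifrac(c(A = 1, B = 1, C = 0, D = 0),
                               c(A = 0, B = 0, C = 2, D = 1), tree), 1)
  expect_error(unweightedUnifrac(c(A = 0, B = 0, C = 0, D = 0), a, tree),
               "empty")
})

test_that("UniFrac equals brute-force edge enumeration on the worked tree", {
  tree <- fourTipTree()
  a <- c(A = 3, B = 1, C = 0, D = 0)
  b <- c(A = 2, B = 0, C = 4, D = 0)
  expect_equal(unweightedUnifrac(a, b, tree), bruteUnweightedUnifrac(a, b, tree))
  # hand count: unique edges B(1), C(1) and the right internal edge
  # (descendant C present only in b); shared: A and the left internal
  # edge; D contributes nowhere: d = 3 / 5
  expect_equal(unweightedUnifrac(a, b, tree), 3 / 5)
  expect_equal(weightedUnifrac(a, b, tree), bruteWeightedUnifrac(a, b, tree))
})

test_that("UniFrac matches brute force on 50 random trees (both metrics)", {
  set.seed(99)
  for (i in 1:50) {
    nTip <- sample(3:8, 1)
    tree <- ape::rtree(nTip)
    a <- setNames(rpois(nTip, 2), tree$tip.label)
    b <- setNames(rpois(nTip, 2), tree$tip.label)
    if (sum(a) == 0) a[1] <- 1
    if (sum(b) == 0) b[nTip] <- 1
    expect_equal(unweightedUnifrac(a, b, tree),
                 bruteUnweightedUnifrac(a, b, tree), tolerance = 1e-12)
    expect_equal(weightedUnifrac(a, b, tree),
                 bruteWeightedUnifrac(a, b, tree), tolerance = 1e-12)
    # symmetry and presence-only rescaling invariance
    expect_equal(unweightedUnifrac(b, a, tree), unweightedUnifrac(a, b, tree))
    expect_equal(weightedUnifrac(b, a, tree), weightedUnifrac(a, b, tree))
    expect_equal(unweightedUnifrac(a * 7, b, tree),
                 unweightedUnifrac(a, b, tree))
  }
})

test_that("UniFrac agrees with independent package implementations", {
  set.seed(5)
  tree <- ape::rtree(12)
  cm <- matrix(rpois(5 * 12, 3), 5, 12,
               dimnames = list(paste0("s", 1:5), tree$tip.label))
  cm[cm < 2] <- 0
  cm[1, ] <- cm[1, ] + 1
  ct <- CountTable(cm)
  du <- as.matrix(pairwiseDistances(ct, tree, "unweighted", rarefyDepth = NA))
  dp <- as.matrix(picante::unifrac(cm, tree))
  expect_equal(du, dp[rownames(du), colnames(du)], tolerance = 1e-12,
               ignore_attr = TRUE)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(cm, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tree))
  dw <- as.matrix(pairwiseDistances(ct, tree, "weighted", rarefyDepth = NA))
  dwp <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(dw, dwp[rownames(dw), colnames(dw)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pairwise distances: structure, duplicates, metric contrast", {
  tree <- fourTipTree()
  m <- matrix(c(4, 4, 0, 0,
                4, 4, 0, 0,
                8, 2, 2, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("A", "B", "C", "D")))
  D <- as.matrix(pairwiseDistances(CountTable(m), tree, "unweighted",
                                   rarefyDepth = 8, seed = 4))
  expect_equal(dim(D), c(3, 3))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # duplicate rows rarefy identically, so their distance is exactly 0
  expect_equal(D["S1", "S2"], 0)

  # presence-identical but abundance-different profiles
  m2 <- matrix(c(6, 2, 0, 0,
                 2, 6, 0, 0), 2, 4, byrow = TRUE,
               dimnames = list(c("S1", "S2"), c("A", "B", "C", "D")))
  ct2 <- CountTable(m2)
  expect_equal(as.matrix(pairwiseDistances(ct2, tree, "unweighted",
                                           rarefyDepth = NA))["S1", "S2"], 0)
  expect_gt(as.matrix(pairwiseDistances(ct2, tree, "weighted",
                                        rarefyDepth = NA))["S1", "S2"], 0)

  # OTUs absent from the tree: error unless pruned
  colnames(m2)[4] <- "Z"
  expect_error(pairwiseDistances(CountTable(m2), tree, "unweighted",
                                 rarefyDepth = NA), "absent from the tree")
  expect_warning(
    D3 <- pairwiseDistances(CountTable(m2), tree, "unweighted",
                            rarefyDepth = NA, pruneMissing = TRUE),
    "dropping")
  expect_equal(dim(as.matrix(D3)), c(2, 2))
})

test_that("Gower centering: closed forms and the trace identity", {
  z <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  expect_equal(gowerCenter(DistanceMatrix(z)), z)

  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  G2 <- gowerCenter(DistanceMatrix(d2))
  expect_equal(unname(G2), matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sum(diag(G2)), 2)

  D <- simulateNullDistance(15, seed = 3)
  G <- gowerCenter(D)
  expect_lt(max(abs(rowSums(G))), 1e-10)
  dm <- as.matrix(D)
  expect_equal(sum(diag(G)), sum(dm[upper.tri(dm)]^2) / nrow(dm),
               tolerance = 1e-10)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # 4 points on a line: one positive eigenvalue explains ~100%
  pts <- c(0, 1, 2, 3)
  D <- DistanceMatrix(as.matrix(dist(setNames(pts, paste0("s", 1:4)))))
  ord <- pcoaOrdination(D, k = 1)
  expect_equal(explainedVariance(ord)[1], 1, tolerance = 1e-8)
  rec <- as.matrix(dist(ordCoordinates(ord)))
  expect_equal(unname(rec), unname(as.matrix(D)), tolerance = 1e-8)

  # 2D cloud: distances recovered up to rotation/reflection
  set.seed(21)
  xy <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("s", 1:8), NULL))
  D2 <- DistanceMatrix(as.matrix(dist(xy)))
  ord2 <- pcoaOrdination(D2, k = 2)
  expect_equal(unname(as.matrix(dist(ordCoordinates(ord2)))),
               unname(as.matrix(D2)), tolerance = 1e-8)
  # agrees with classical MDS up to axis sign
  cm <- stats::cmdscale(as.matrix(D2), k = 2)
  expect_equal(abs(unname(ordCoordinates(ord2))), abs(unname(cm)),
               tolerance = 1e-8)

  z <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  ord0 <- pcoaOrdination(DistanceMatrix(z), k = 2)
  expect_equal(ncol(ordCoordinates(ord0)), 0)
  expect_warning(pcoaOrdination(D, k = 3), "truncating")
})
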