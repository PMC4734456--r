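test_that("design construction: degrees of freedom and aliasing", {
  meta <- smallMeta(20)
  # binary covariate, 2 batches: main + interaction = 2 df
  expect_equal(buildDesign(meta, designSpec("sex"))$p, 2)
  expect_equal(buildDesign(meta, designSpec("age"))$p, 2)

  md <- sampleData(meta)
  md$batch <- factor("b1")
  expect_warning(d1 <- buildDesign(SampleMetadata(md), designSpec("bmi")),
                 "interaction term omitted")
  expect_equal(d1$p, 1)

  # covariate constant within each batch: aliased columns dropped
  md2 <- sampleData(meta)
  md2$dup <- factor(ifelse(md2$batch == "b1", "u", "v"))
  expect_message(d2 <- buildDesign(SampleMetadata(md2), designSpec("dup")),
                 "aliased")
  expect_equal(d2$p, 0)
  expect_gt(length(d2$droppedColumns), 0)

  md3 <- sampleData(meta)
  md3$konst <- 1
  expect_error(buildDesign(SampleMetadata(md3), designSpec("konst")),
               "degenerate covariate")

  # complete-case handling drops samples with a missing covariate value
  md4 <- sampleData(meta)
  md4$bmi[c(2, 5)] <- NA
  d4 <- buildDesign(SampleMetadata(md4), designSpec("bmi"))
  expect_equal(d4$n, 18)
  expect_false(any(rownames(md4)[c(2, 5)] %in% d4$keep))
})

test_that("PERMANOVA detects perfectly separated clusters at the floor p-value", {
  n <- 20
  ids <- sprintf("S%04d", 1:n)
  grp <- rep(c("u", "v"), each = n / 2)
  pts <- ifelse(grp == "u", 0, 10) + runif(n, -0.01, 0.01)
  D <- DistanceMatrix(as.matrix(dist(setNames(pts, ids))))
  meta <- SampleMetadata(data.frame(
    g = factor(grp), batch = factor(rep(c("b1", "b2"), n / 2)),
    row.names = ids))
  res <- permanovaJoint(D, meta, designSpec("g"), nPerm = 99, seed = 2)
  expect_gt(res$statistic, 100)
  expect_equal(res$p_value, 1 / 100)
  expect_equal(res$n_perm, 99)
  expect_gt(res$r2, 0.9)
  expect_error(permanovaJoint(D, meta, designSpec("g"), nPerm = 0), "nPerm")
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F for Euclidean distances", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 18
    ids <- sprintf("S%02d", 1:n)
    meta <- SampleMetadata(data.frame(
      x = rnorm(n), batch = factor(rep(c("b1", "b2"), each = n / 2)),
      row.names = ids))
    y <- setNames(rnorm(n) + 0.5 * sampleData(meta)$x, ids)
    D <- DistanceMatrix(as.matrix(dist(y)))
    pr <- permanovaJoint(D, meta, designSpec("x"), nPerm = 5, seed = 1)
    md <- sampleData(meta)
    a <- anova(lm(y ~ batch, md), lm(y ~ batch + x + x:batch, md))
    expect_equal(pr$statistic, a$F[2], tolerance = 1e-8)
  }
})

test_that("pseudo-F and R2 are invariant to sample reordering", {
  set.seed(13)
  D <- simulateNullDistance(16, seed = 4)
  meta <- smallMeta(16, seed = 5)
  md <- sampleData(meta)
  rownames(md) <- sampleIDs(D)
  meta <- SampleMetadata(md)
  r1 <- permanovaJoint(D, meta, designSpec("bmi"), nPerm = 19, seed = 6)
  perm <- sample(16)
  D2 <- DistanceMatrix(as.matrix(D)[perm, perm])
  meta2 <- SampleMetadata(md[perm, , drop = FALSE])
  r2 <- permanovaJoint(D2, meta2, designSpec("bmi"), nPerm = 19, seed = 6)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-10)

  # permutation p-value exactly reproducible under a fixed seed
  r3 <- permanovaJoint(D, meta, designSpec("bmi"), nPerm = 19, seed = 6)
  expect_identical(r1$p_value, r3$p_value)
})

test_that("sequential R2 decomposes total dispersion and matches vegan", {
  D <- simulateNullDistance(20, seed = 8)
  meta <- smallMeta(20, seed = 9)
  md <- sampleData(meta)
  rownames(md) <- sampleIDs(D)
  meta <- SampleMetadata(md)
  spec <- designSpec("sex")
  G <- gowerCenter(D)
  trG <- sum(diag(G))
  des <- buildDesign(meta, spec)
  r2batch <- (microdemog:::.projTrace(G, des$reduced) -
                microdemog:::.projTrace(G, matrix(1, 20, 1))) / trG
  r2joint <- distanceR2(D, meta, spec)$r2
  r2res <- 1 - r2batch - r2joint
  Hf <- microdemog:::.projTrace(G, des$full)
  expect_equal(r2batch + r2joint + (trG - Hf) / trG, 1, tolerance = 1e-10)

  ad <- vegan::adonis2(as.matrix(D) ~ batch + sex + sex:batch, data = md,
                       permutations = 2, by = "terms")
  expect_equal(r2joint, sum(ad$R2[2:3]), tolerance = 1e-10)
  expect_equal(r2batch, ad$R2[1], tolerance = 1e-10)
})

test_that("adjusted R2 follows the small-sample formula", {
  # R2 = 0, n = 100, p = 1 gives -1/98
  expect_equal(microdemog:::.adjustR2(0, 100, 1), -1 / 98)
  expect_equal(microdemog:::.adjustR2(1, 30, 2), 1)
  expect_error(microdemog:::.adjustR2(0.5, 3, 2), "undefined")

  # saturated Euclidean design: R2 = 1 via a full-rank factor
  ids <- paste0("s", 1:6)
  D <- DistanceMatrix(as.matrix(dist(setNames(c(1, 4, 9, 16, 25, 36), ids))))
  meta <- SampleMetadata(data.frame(g = factor(ids), batch = factor(rep("b", 6)),
                                    row.names = ids))
  suppressWarnings(r <- distanceR2(D, meta, designSpec("g")))
  expect_equal(r$r2, 1, tolerance = 1e-10)
})

test_that("alpha LRT: exact fits flagged, null p-values uniform, batch-only safe", {
  meta <- smallMeta(40, seed = 10)
  md <- sampleData(meta)
  y <- setNames(2 * md$bmi + as.numeric(md$batch), rownames(md))
  ex <- alphaLRT(y, meta, designSpec("bmi"))
  expect_equal(ex$flag, "exact-fit")
  expect_equal(ex$p_value, 0)

  # null calibration: KS test against uniform over 500 replicates
  set.seed(31)
  n <- 200
  meta2 <- smallMeta(n, seed = 11)
  ids <- sampleIDs(meta2)
  ps <- vapply(1:500, function(i) {
    y <- setNames(rnorm(n), ids)
    alphaLRT(y, meta2, designSpec("bmi"))$p_value
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # alpha differing only by batch must not implicate the covariate
  set.seed(32)
  rej <- mean(vapply(1:300, function(i) {
    y <- setNames(rnorm(n) + 3 * (sampleData(meta2)$batch == "b2"), ids)
    alphaLRT(y, meta2, designSpec("sex"))$p_value < 0.05
  }, TRUE))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})
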