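test_that("rarefaction conserves depth, never adds reads, and is unbiased", {
  ct <- CountTable(matrix(c(5, 0, 0, 10, 3, 2), 2, 3, byrow = TRUE,
                          dimnames = list(c("S1", "S2"), c("a", "b", "c"))))
  r <- rarefy(ct, depth = 5, seed = 1)
  expect_equal(unname(counts(r)["S1", ]), c(5, 0, 0))
  expect_true(all(sampleDepths(r) == 5))
  expect_true(all(counts(r) <= counts(ct)[sampleIDs(r), ]))

  one <- CountTable(matrix(c(10, 0), 1, 2,
                           dimnames = list("S1", c("a", "b"))))
  expect_equal(unname(counts(rarefy(one, 4, seed = 2))["S1", ]), c(4, 0))

  expect_error(rarefy(ct, depth = 0), "positive")
  shallow <- CountTable(matrix(c(3, 1, 50, 50), 2, 2, byrow = TRUE,
                               dimnames = list(c("S1", "S2"), c("a", "b"))))
  expect_warning(rs <- rarefy(shallow, 10, seed = 1), "dropped")
  expect_equal(sampleIDs(rs), "S2")

  # hypergeometric mean: [500, 500] at depth 100 draws ~50 from OTU 1
  m <- matrix(c(500, 500), 1, 2, dimnames = list("S", c("a", "b")))
  firsts <- vapply(1:2000, function(i)
    counts(rarefy(CountTable(m), 100, seed = i))[1, 1], 0)
  expect_gt(mean(firsts), 45)
  expect_lt(mean(firsts), 55)
})

test_that("identical count rows rarefy identically", {
  m <- matrix(c(40, 10, 5, 40, 10, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  r <- counts(rarefy(CountTable(m), 20, seed = 3))
  expect_identical(unname(r["S1", ]), unname(r["S2", ]))
})

test_that("Shannon index matches closed forms and vegan", {
  expect_equal(shannonIndex(7), 0)
  expect_equal(shannonIndex(c(5, 5, 5, 5)), log(4))
  expect_equal(shannonIndex(c(1, 1, 2)), 1.0397, tolerance = 1e-4)
  expect_error(shannonIndex(c(0, 0)), "all-zero")
  x <- c(9, 4, 1, 7, 0, 2)
  expect_equal(shannonIndex(x),
               unname(vegan::diversity(x, index = "shannon")))
})

test_that("frequency counts satisfy the read-sum identity", {
  x <- c(4, 1, 1, 2, 0, 9)
  fc <- frequencyCounts(x)
  expect_equal(sum(fc$k * fc$fk), sum(x))
  expect_equal(fc$fk[fc$k == 1], 2)
  expect_error(frequencyCounts(c(0, 0)), "no reads")
})

test_that("singleton correction follows the documented closed form", {
  # fallback when higher-order counts vanish
  fc <- list(k = c(1, 5), fk = c(7, 2), n = 17)
  expect_identical(correctSingletons(fc), fc)

  # no singletons in: none out
  fc0 <- list(k = c(2, 3), fk = c(4, 1), n = 11)
  out0 <- correctSingletons(fc0)
  expect_equal(sum(out0$fk[out0$k == 1]), 0)

  # frozen arithmetic for (f2, f3, f4) = (30, 20, 10): the log-linear
  # fit of ln(k f_k) through (2, ln60), (3, ln60), (4, ln40) predicts
  # f1 = 1.5 * (60 * 60 * 40)^(1/3) = 78.62..., rounded to 79
  fc1 <- list(k = 1:4, fk = c(100L, 30L, 20L, 10L), n = 100 + 60 + 60 + 40)
  out1 <- correctSingletons(fc1)
  expect_equal(out1$fk[out1$k == 1], 79)
  expect_equal(out1$fk[out1$k %in% 2:4], c(30L, 20L, 10L))
  expect_equal(out1$n, 79 + 60 + 60 + 40)

  # capped at the observed singleton count
  fc2 <- list(k = 1:4, fk = c(5L, 30L, 20L, 10L), n = 5 + 160)
  expect_equal(correctSingletons(fc2)$fk[1], 5)
})

test_that("Good-Turing coverage matches its closed form", {
  expect_equal(sampleCoverage(list(k = c(2, 4), fk = c(3, 1), n = 10)), 1)
  # n species with 1 read each collapses to zero coverage
  expect_equal(sampleCoverage(list(k = 1, fk = 5, n = 5)), 0)
  # f1 = 2, f2 = 1, n = 10: 1 - 0.2 * 18/20 = 0.82
  expect_equal(sampleCoverage(list(k = c(1, 2, 6), fk = c(2, 1, 1), n = 10)),
               0.82)
})

test_that("interpolated richness and Shannon match exhaustive enumeration", {
  x <- c(4, 2, 1)
  for (m in 1:6) {
    expect_equal(richnessAtSize(x, m),
                 enumerateSubsamples(x, m, function(s) sum(s > 0)),
                 tolerance = 1e-9)
    expect_equal(shannonAtSize(x, m),
                 enumerateSubsamples(x, m, function(s)
                   if (sum(s) == 0) 0 else shannonIndex(s)),
                 tolerance = 1e-9)
  }
  expect_equal(richnessAtSize(c(9, 3, 1), 1), 1)
})

test_that("richness and coverage are non-decreasing in subsample size", {
  set.seed(42)
  for (rep in 1:100) {
    x <- rpois(8, 3) + rbinom(8, 1, 0.5)
    if (sum(x) < 2) next
    n <- sum(x)
    ms <- seq_len(2 * n)
    S <- vapply(ms, function(m) richnessAtSize(x, m), 0)
    C <- vapply(ms, function(m) coverageAtSize(x, m), 0)
    expect_true(all(diff(S) >= -1e-9))
    expect_true(all(diff(C) >= -1e-9))
  }
})

test_that("coverage standardization recovers observed values at own coverage", {
  x <- c(10, 5, 3, 1, 1, 2)
  target <- sampleCoverage(frequencyCounts(x))
  std <- standardizeAtCoverage(x, target, corrected = FALSE)
  expect_equal(std$m[1], sum(x))
  expect_equal(std$value[std$metric == "observed_otus"], sum(x > 0))
  expect_equal(std$value[std$metric == "shannon"], shannonIndex(x))
  expect_false(any(std$extrapolated))

  # unreachable target is flagged at the extrapolation cap
  expect_warning(far <- standardizeAtCoverage(c(1, 1, 1, 1), 0.999999,
                                              corrected = FALSE),
                 "unreachable")
  expect_true(all(far$flagged))
  expect_equal(far$m[1], 8)
})

test_that("target coverage is the cohort minimum", {
  m <- matrix(c(50, 30, 5, 1, 1, 1,
                8, 3, 1, 1, 1, 1), 2, 6, byrow = TRUE,
              dimnames = list(c("deep", "shallow"), paste0("o", 1:6)))
  ct <- CountTable(m)
  tc <- pickTargetCoverage(ct, corrected = FALSE)
  covs <- apply(m, 1, function(x) sampleCoverage(frequencyCounts(x[x > 0])))
  expect_equal(tc, min(covs))
  expect_true(all(tc <= covs))

  one <- CountTable(m[1, , drop = FALSE])
  expect_equal(pickTargetCoverage(one, corrected = FALSE), covs[["deep"]])
})

test_that("alphaDiversity returns standardized and raw metrics per sample", {
  ch <- simulateCohort(testSimConfig(seed = 8, nSamples = 12, nOtus = 60))
  a <- alphaDiversity(ch$table)
  expect_equal(nrow(a), 2 * length(sampleIDs(ch$table)))
  expect_setequal(unique(a$metric), c("observed_otus", "shannon"))
  expect_true(all(a$value[a$metric == "observed_otus"] >= 1))
  expect_true(all(a$value[a$metric == "shannon"] >= 0))
  expect_true(all(a$coverage_level > 0 & a$coverage_level <= 1))
})
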