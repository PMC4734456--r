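# Alpha diversity: rarefaction, frequency-count corrections, and
# richness/Shannon standardized at a common sample coverage rather
# than a common depth. Binomial-coefficient ratios are evaluated in
# log space (lchoose) so depths of a few hundred thousand reads do
# not overflow.

.contentHash <- function(x) {
  h <- 0
  for (v in x) h <- (h * 31 + v) %% 2047483647
  h
}

#' Rarefy a count table to a fixed depth
#'
#' Uniform random subsampling without replacement to exactly `depth`
#' reads per sample. Samples shallower than `depth` are dropped with a
#' warning. Each sample's subsample is drawn from a substream keyed by
#' the master seed and a hash of the sample's count vector, so
#' identical count rows subsample identically (duplicates stay at
#' distance zero downstream) and results are reproducible per sample.
#'
#' @param table a [CountTable-class].
#' @param depth target depth (>= 1); `"auto"` uses the minimum sample
#'   depth.
#' @param seed integer seed.
#' @return a rarefied [CountTable-class].
#' @export
rarefy <- function(table, depth = "auto", seed = 1L) {
  m <- counts(table)
  tot <- rowSums(m)
  if (identical(depth, "auto")) depth <- min(tot)
  if (!is.numeric(depth) || depth < 1) stop("depth must be a positive integer")
  depth <- as.integer(round(depth))
  shallow <- tot < depth
  if (any(shallow)) {
    warning(sum(shallow), " sample(s) shallower than depth ", depth,
            " dropped: ", paste(rownames(m)[shallow], collapse = ", "))
    m <- m[!shallow, , drop = FALSE]
    tot <- tot[!shallow]
  }
  if (nrow(m) == 0) stop("no samples at or above the rarefaction depth")
  out <- m
  for (i in seq_len(nrow(m))) {
    if (tot[i] == depth) next
    x <- m[i, ]
    set.seed(.substream(seed, sprintf("rarefy-%.0f", .contentHash(x))))
    cs <- cumsum(x)
    reads <- sample.int(tot[i], depth)
    out[i, ] <- tabulate(findInterval(reads - 1L, cs) + 1L, nbins = length(x))
  }
  CountTable(out)
}

#' Shannon index of one sample
#'
#' `H = -sum(p_i * ln(p_i))` over the positive proportions, in nats.
#'
#' @param x count (or proportion) vector with at least one positive
#'   entry.
#' @return Shannon entropy in nats.
#' @examples
#' shannonIndex(c(5, 5, 5, 5))  # log(4)
#' @export
shannonIndex <- function(x) {
  p <- x[x > 0]
  if (length(p) == 0) stop("all-zero vector has no Shannon index")
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Frequency counts of one sample
#'
#' `f_k` = number of OTUs observed exactly `k` times; `n` = sample
#' depth. Satisfies `sum(k * f_k) == n`.
#'
#' @param x count vector for one sample.
#' @return list with `k` (observed multiplicities), `fk` (their
#'   counts) and `n`.
#' @export
frequencyCounts <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0) stop("sample has no reads")
  tab <- table(pos)
  list(k = as.integer(names(tab)), fk = as.integer(tab), n = sum(pos))
}

.fcGet <- function(fc, k) {
  i <- match(k, fc$k)
  ifelse(is.na(i), 0L, fc$fk[i])
}

#' Estimate the true singleton count from higher frequency counts
#'
#' Sequencing errors inflate the observed singleton count f1, biasing
#' richness and coverage. This replaces f1 by a closed-form estimate
#' obtained by least-squares log-linear extrapolation of `ln(k * f_k)`
#' over the reliable counts k = 2, 3, 4 back to k = 1 (with only f2
#' and f3 positive this reduces to `4 f2^2 / (3 f3)`). The estimate is
#' capped at the observed f1 (the correction removes spurious
#' singletons, never adds) and falls back to the observed f1 when
#' fewer than two of f2, f3, f4 are positive. Other f_k are unchanged;
#' `n` is recomputed.
#'
#' @param fc frequency counts from [frequencyCounts].
#' @return corrected frequency counts, same structure.
#' @export
correctSingletons <- function(fc) {
  f1 <- .fcGet(fc, 1L)
  if (f1 == 0) return(fc)
  kk <- 2:4
  fk <- .fcGet(fc, kk)
  use <- fk > 0
  if (sum(use) < 2) return(fc)
  fit <- stats::lm.fit(cbind(1, kk[use]), log(kk[use] * fk[use]))
  f1hat <- exp(sum(fit$coefficients * c(1, 1)))
  f1new <- as.integer(min(f1, max(0, round(f1hat))))
  k <- fc$k; f <- fc$fk
  f[k == 1L] <- f1new
  keep <- f > 0
  list(k = k[keep], fk = f[keep], n = sum(k[keep] * f[keep]))
}

.applySingletonCorrection <- function(x) {
  x <- x[x > 0]
  fc <- frequencyCounts(x)
  f1new <- .fcGet(correctSingletons(fc), 1L)
  drop <- .fcGet(fc, 1L) - f1new
  if (drop > 0) {
    singles <- which(x == 1)
    x <- x[-singles[seq_len(drop)]]
  }
  x
}

#' Good-Turing sample coverage
#'
#' Estimated fraction of the community's individuals belonging to
#' species already observed:
#' `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`.
#'
#' @param fc frequency counts from [frequencyCounts] (optionally after
#'   [correctSingletons]).
#' @return coverage in \[0, 1\].
#' @examples
#' sampleCoverage(list(k = c(1, 2, 6), fk = c(2, 1, 1), n = 10)) # 0.82
#' @export
sampleCoverage <- function(fc) {
  if (fc$n < 1) stop("coverage undefined for empty sample")
  f1 <- .fcGet(fc, 1L); f2 <- .fcGet(fc, 2L)
  if (f1 == 0) return(1)
  den <- (fc$n - 1) * f1 + 2 * f2
  A <- if (den > 0) (fc$n - 1) * f1 / den else 1
  1 - (f1 / fc$n) * A
}

#' Expected coverage of a subsample (or extrapolated sample) of size m
#'
#' For `m < n` the interpolated estimator
#' `1 - sum_i (x_i/n) * choose(n - x_i, m) / choose(n - 1, m)`; at
#' `m = n` the Good-Turing coverage; for `m > n` the exponential
#' extrapolation `1 - (f1/n) * A^(m - n + 1)`.
#'
#' @param x positive count vector of one sample.
#' @param m target size (>= 1).
#' @return estimated coverage in \[0, 1\]; non-decreasing in `m`.
#' @export
coverageAtSize <- function(x, m) {
  x <- x[x > 0]
  n <- sum(x)
  if (m >= n) {
    fc <- frequencyCounts(x)
    f1 <- .fcGet(fc, 1L); f2 <- .fcGet(fc, 2L)
    if (m == n || f1 == 0) {
      cov <- sampleCoverage(fc)
      if (m == n) return(cov)
      return(1)
    }
    den <- (n - 1) * f1 + 2 * f2
    A <- if (den > 0) (n - 1) * f1 / den else 1
    return(1 - (f1 / n) * A^(m - n + 1))
  }
  1 - sum((x / n) * exp(lchoose(n - x, m) - lchoose(n - 1, m)))
}

#' Expected richness of a subsample (or extrapolated sample) of size m
#'
#' For `m <= n` the exact hypergeometric expectation
#' `S_obs - sum_i choose(n - x_i, m) / choose(n, m)`; for `m > n` the
#' Chao1-based extrapolation
#' `S_obs + f0 * (1 - (1 - f1 / (n f0 + f1))^(m - n))` with
#' `f0 = ((n-1)/n) f1^2 / (2 f2)`.
#'
#' @inheritParams coverageAtSize
#' @return expected number of OTUs; non-decreasing in `m`.
#' @export
richnessAtSize <- function(x, m) {
  x <- x[x > 0]
  n <- sum(x)
  S <- length(x)
  if (m <= n) return(S - sum(exp(lchoose(n - x, m) - lchoose(n, m))))
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  f0 <- if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
        else ((n - 1) / n) * f1 * (f1 - 1) / 2
  if (f1 == 0 || f0 <= 0) return(S)
  S + f0 * (1 - (1 - f1 / (n * f0 + f1))^(m - n))
}

# Chao-Shih-Jost asymptotic Shannon entropy (nats)
.shannonAsymptotic <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  part1 <- sum((x / n) * (digamma(n) - digamma(x)))
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else if (f1 > 0) 2 / ((n - 1) * (f1 - 1) + 2)
       else 1
  part2 <- 0
  if (f1 > 0 && A < 1) {
    r <- seq_len(n - 1)
    part2 <- (f1 / n) * (1 - A)^(1 - n) *
      (-log(A) - sum((1 / r) * (1 - A)^r))
    if (!is.finite(part2)) part2 <- 0
  }
  part1 + part2
}

#' Expected Shannon index of a subsample of size m
#'
#' For `m <= n`, the exact expectation of the subsample entropy under
#' hypergeometric subsampling:
#' `sum_i E[-(X_i/m) ln(X_i/m)]`, `X_i ~ Hypergeometric(n, x_i, m)`.
#' For `m > n`, a depth-weighted blend of the observed entropy and the
#' Chao-Shih-Jost asymptotic entropy estimator:
#' `(n/m) H_obs + ((m-n)/m) H_asy`.
#'
#' @inheritParams coverageAtSize
#' @return expected Shannon entropy in nats.
#' @export
shannonAtSize <- function(x, m) {
  x <- x[x > 0]
  n <- sum(x)
  if (m > n) {
    hObs <- shannonIndex(x)
    hAsy <- max(.shannonAsymptotic(x), hObs)
    return((n / m) * hObs + ((m - n) / m) * hAsy)
  }
  H <- 0
  for (xi in x) {
    k <- seq(max(1L, m - (n - xi)), min(xi, m))
    w <- dhyper(k, xi, n - xi, m)
    q <- k / m
    H <- H + sum(w * ifelse(q < 1, -q * log(q), 0))
  }
  H
}

#' Standardize richness and Shannon diversity at a target coverage
#'
#' Finds the smallest (possibly extrapolated) sample size `m*` whose
#' estimated coverage reaches `target` and returns the richness and
#' Shannon expectations at `m*`. Extrapolation is capped at `m* = 2n`;
#' a target unreachable within the cap yields a flagged result at the
#' cap.
#'
#' @param x count vector of one sample.
#' @param target coverage in (0, 1\].
#' @param corrected apply the singleton correction
#'   ([correctSingletons]) before standardizing (default TRUE).
#' @param cap extrapolation cap as a multiple of the depth.
#' @return data.frame with one row per metric (`observed_otus`,
#'   `shannon`): `value`, `coverage_target`, `m`, `n`, `extrapolated`,
#'   `flagged`.
#' @export
standardizeAtCoverage <- function(x, target, corrected = TRUE, cap = 2) {
  if (!(target > 0 && target <= 1)) stop("target coverage must lie in (0, 1]")
  x <- x[x > 0]
  if (length(x) == 0) stop("sample has no reads")
  if (corrected) x <- .applySingletonCorrection(x)
  n <- sum(x)
  mMax <- as.integer(cap * n)
  flagged <- FALSE
  if (coverageAtSize(x, mMax) < target - 1e-12) {
    flagged <- TRUE
    warning(sprintf("target coverage %.4f unreachable within m = %d*n; using the cap",
                    target, cap))
    m <- mMax
  } else {
    lo <- 1L; hi <- mMax
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (coverageAtSize(x, mid) >= target - 1e-12) hi <- mid else lo <- mid + 1L
    }
    m <- lo
  }
  data.frame(metric = c("observed_otus", "shannon"),
             value = c(richnessAtSize(x, m), shannonAtSize(x, m)),
             coverage_target = target, m = m, n = n,
             extrapolated = m > n, flagged = flagged)
}

#' Minimum sample coverage of a cohort
#'
#' The coverage-standardization target: the minimum, over samples, of
#' the Good-Turing coverage (after singleton correction by default).
#'
#' @param table a [CountTable-class].
#' @param corrected apply [correctSingletons] first.
#' @return a fraction in \[0, 1\].
#' @export
pickTargetCoverage <- function(table, corrected = TRUE) {
  m <- counts(table)
  covs <- apply(m, 1, function(x) {
    x <- if (corrected) .applySingletonCorrection(x) else x[x > 0]
    sampleCoverage(frequencyCounts(x))
  })
  min(covs)
}

#' Coverage-standardized alpha diversity for every sample
#'
#' Computes, per sample, observed-OTU richness and the Shannon index
#' standardized at a common coverage (default: the cohort minimum,
#' mirroring comparisons "at equal completeness" rather than equal
#' depth). Raw full-depth values are reported alongside.
#'
#' @param table a [CountTable-class].
#' @param targetCoverage `"auto"` (minimum sample coverage) or a
#'   fraction in (0, 1\].
#' @param corrected apply the singleton correction (default TRUE).
#' @return data.frame with columns `sample_id`, `metric`, `value`
#'   (standardized), `raw` (full-depth value), `coverage_level`, `m`,
#'   `extrapolated`, `flagged`.
#' @export
alphaDiversity <- function(table, targetCoverage = "auto", corrected = TRUE) {
  m <- counts(table)
  if (identical(targetCoverage, "auto"))
    targetCoverage <- pickTargetCoverage(table, corrected = corrected)
  rows <- lapply(rownames(m), function(s) {
    x <- m[s, ]
    std <- standardizeAtCoverage(x, targetCoverage, corrected = corrected)
    data.frame(sample_id = s, metric = std$metric, value = std$value,
               raw = c(sum(x > 0), shannonIndex(x)),
               coverage_level = targetCoverage, m = std$m,
               extrapolated = std$extrapolated, flagged = std$flagged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
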