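# Overall covariate-microbiota association: linear models on alpha
# diversity and PERMANOVA on beta diversity, both under the model
#   outcome ~ Batch + X + X:Batch
# testing the joint (main + interaction) covariate effect, i.e. the
# null of no association in either batch. Effect sizes are the
# sequential (batch-first) distance-based R2 and its small-sample
# adjustment.

#' Specify one association design
#'
#' @param covariate name of the covariate under test (continuous
#'   covariates enter as single columns; categoricals are
#'   reference-coded).
#' @param batch name of the batch column (default `"batch"`).
#' @param strata permute within batch strata (default TRUE,
#'   preserving batch structure under the null); FALSE gives
#'   unrestricted row permutation.
#' @return a `DesignSpec` list.
#' @export
designSpec <- function(covariate, batch = "batch", strata = TRUE) {
  structure(list(covariate = covariate, batch = batch, strata = strata),
            class = "DesignSpec")
}

.fullDesign <- function(x, batch) {
  if (nlevels(batch) > 1) model.matrix(~ batch + x + x:batch)
  else model.matrix(~ x)
}

.dropAliased <- function(X, quiet = FALSE) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    if (!quiet)
      message("dropping aliased design column(s): ",
              paste(dropped, collapse = ", "))
    X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
    attr(X, "dropped") <- dropped
  }
  X
}

#' Build reduced and full design matrices
#'
#' Reduced model: `~ Batch`; full model: `~ Batch + X + X:Batch` (the
#' interaction is omitted with a warning when there is a single batch
#' level). Rank deficiency is resolved by dropping aliased columns
#' with a report; samples with a missing covariate or batch value are
#' dropped (complete-case per analysis).
#'
#' @param meta a [SampleMetadata-class].
#' @param spec a [designSpec].
#' @return list with `reduced`, `full` (full-rank design matrices),
#'   `p` (rank difference = covariate degrees of freedom), `n`,
#'   `rankReduced`, `rankFull`, `keep` (sample ids used), `x`,
#'   `batch`, and `droppedColumns`.
#' @export
buildDesign <- function(meta, spec) {
  md <- sampleData(meta)
  for (nm in c(spec$covariate, spec$batch))
    if (!nm %in% names(md)) stop(sprintf("column '%s' not in metadata", nm))
  ok <- complete.cases(md[, c(spec$covariate, spec$batch)])
  if (sum(ok) < sum(!ok) || sum(ok) < 3)
    if (sum(ok) < 3) stop("fewer than 3 complete cases for ", spec$covariate)
  md <- md[ok, , drop = FALSE]
  x <- md[[spec$covariate]]
  if (is.factor(x)) x <- droplevels(x)
  if (length(unique(x)) < 2) stop("degenerate covariate: ", spec$covariate,
                                  " is constant")
  batch <- droplevels(factor(md[[spec$batch]]))
  if (nlevels(batch) < 2)
    warning("single batch level; interaction term omitted")
  reduced <- if (nlevels(batch) > 1) model.matrix(~ batch)
             else matrix(1, nrow(md), 1, dimnames = list(NULL, "(Intercept)"))
  full <- .dropAliased(.fullDesign(x, batch))
  rr <- qr(reduced)$rank; rf <- qr(full)$rank
  list(reduced = reduced, full = full, p = rf - rr, n = nrow(md),
       rankReduced = rr, rankFull = rf, keep = rownames(md),
       x = x, batch = batch,
       droppedColumns = attr(full, "dropped") %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trace of H G H for H the projector onto the column space of X;
# equals tr(G H) = sum(Q * (G Q)) with Q an orthonormal basis
.projTrace <- function(G, X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  sum(Q * (G %*% Q))
}

.permuteWithin <- function(n, strata) {
  idx <- seq_len(n)
  if (is.null(strata)) return(sample(idx))
  for (lev in levels(strata)) {
    i <- which(strata == lev)
    if (length(i) > 1) idx[i] <- i[sample.int(length(i))]
  }
  idx
}

#' Joint PERMANOVA of one covariate against a distance matrix
#'
#' Permutational multivariate ANOVA of `D ~ Batch + X + X:Batch`
#' testing the covariate's main and interaction terms jointly. With
#' `G` the Gower matrix and `H_r`, `H_f` the projections onto the
#' reduced/full design column spaces:
#' `SS_joint = tr(H_f G H_f) - tr(H_r G H_r)`,
#' `SS_res = tr((I - H_f) G (I - H_f))`, and
#' `pseudo-F = (SS_joint / p) / (SS_res / (n - rank_full))`.
#' The p-value uses the add-one permutation convention
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` (ties counted as
#' exceedances); permutations shuffle the covariate's sample rows,
#' within batch strata by default.
#'
#' @param D a [DistanceMatrix-class].
#' @param meta a [SampleMetadata-class] sharing sample ids with `D`.
#' @param spec a [designSpec].
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed; the permutation p-value is reproducible
#'   exactly under a fixed seed.
#' @return one-row data.frame: `covariate`, `statistic` (pseudo-F),
#'   `df`, `p_value`, `n_perm`, `r2`, `r2_adj`, `n`.
#' @export
permanovaJoint <- function(D, meta, spec, nPerm = 1000, seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  des <- .alignedDesign(D, meta, spec)
  G <- gowerCenter(des$D)
  n <- des$n; p <- des$p
  if (p < 1) stop("covariate fully aliased with batch; no degrees of freedom")
  if (n < p + 2) stop("too few samples for the design")
  trG <- sum(diag(G))
  trHr <- .projTrace(G, des$reduced)
  trHf <- .projTrace(G, des$full)
  ssJoint <- trHf - trHr
  ssRes <- trG - trHf
  fObs <- (ssJoint / p) / (ssRes / (n - des$rankFull))
  set.seed(.substream(seed, sprintf("permanova-%s", spec$covariate)))
  strata <- if (isTRUE(spec$strata) && nlevels(des$batch) > 1) des$batch else NULL
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    idx <- .permuteWithin(n, strata)
    Xp <- .dropAliased(.fullDesign(des$x[idx], des$batch), quiet = TRUE)
    trHp <- .projTrace(G, Xp)
    fPerm <- ((trHp - trHr) / p) / ((trG - trHp) / (n - des$rankFull))
    if (fPerm >= fObs - 1e-12) exceed <- exceed + 1L
  }
  r2 <- ssJoint / trG
  data.frame(covariate = spec$covariate, statistic = fObs, df = p,
             p_value = (1 + exceed) / (1 + nPerm), n_perm = nPerm,
             r2 = r2, r2_adj = .adjustR2(r2, n, p), n = n)
}

.alignedDesign <- function(D, meta, spec) {
  ids <- intersect(sampleIDs(D), sampleIDs(meta))
  if (length(ids) < 3) stop("distance matrix and metadata share too few samples")
  meta <- SampleMetadata(sampleData(meta)[ids, , drop = FALSE])
  des <- buildDesign(meta, spec)
  dm <- as.matrix(D)[des$keep, des$keep, drop = FALSE]
  c(des, list(D = dm))
}

.adjustR2 <- function(r2, n, p) {
  if (r2 >= 1 - 1e-12) return(1)  # saturated design: adjustment is the limit 1
  if (n <= p + 1) stop("adjusted R2 undefined: n <= p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Distance-based R2 and adjusted R2 of one covariate
#'
#' The fraction of total dispersion attributable to the covariate:
#' `R2 = tr(H G H) / tr(G)`. The default (`scope = "sequential"`)
#' credits batch first and uses the incremental
#' `tr(H_f G H_f) - tr(H_r G H_r)` over `tr(G)`, so batch variance is
#' not attributed to the covariate; `scope = "marginal"` ignores batch
#' entirely. The small-sample adjustment is
#' `R2_adj = 1 - (1 - R2)(n - 1)/(n - p - 1)`; it may be negative and
#' is never floored internally.
#'
#' @inheritParams permanovaJoint
#' @param scope `"sequential"` (batch-first, default) or `"marginal"`.
#' @return one-row data.frame: `covariate`, `r2`, `r2_adj`, `df`, `n`.
#' @export
distanceR2 <- function(D, meta, spec, scope = c("sequential", "marginal")) {
  scope <- match.arg(scope)
  des <- .alignedDesign(D, meta, spec)
  G <- gowerCenter(des$D)
  trG <- sum(diag(G))
  if (scope == "sequential") {
    num <- .projTrace(G, des$full) - .projTrace(G, des$reduced)
    p <- des$p
  } else {
    X <- .dropAliased(model.matrix(~ x, data.frame(x = des$x)), quiet = TRUE)
    num <- .projTrace(G, X) - .projTrace(G, matrix(1, des$n, 1))
    p <- qr(X)$rank - 1L
  }
  r2 <- num / trG
  data.frame(covariate = spec$covariate, r2 = r2,
             r2_adj = .adjustR2(r2, des$n, p), df = p, n = des$n)
}

#' Likelihood-ratio association test for an alpha-diversity outcome
#'
#' Ordinary least squares fits of the reduced (`~ Batch`) and full
#' (`~ Batch + X + X:Batch`) models; the likelihood-ratio statistic is
#' `n * ln(RSS_r / RSS_f)`, referred to a chi-square with p (the
#' covariate's joint degrees of freedom). A zero-residual full model
#' is returned flagged rather than producing an infinite statistic.
#'
#' @param alpha named numeric vector of per-sample alpha-diversity
#'   values (names = sample ids), e.g. one metric's column from
#'   [alphaDiversity].
#' @param meta a [SampleMetadata-class].
#' @param spec a [designSpec].
#' @return one-row data.frame: `covariate`, `statistic`, `df`,
#'   `p_value`, `r2`, `r2_adj`, `n`, `flag`.
#' @export
alphaLRT <- function(alpha, meta, spec) {
  ids <- intersect(names(alpha), sampleIDs(meta))
  if (length(ids) < 3) stop("alpha values and metadata share too few samples")
  meta <- SampleMetadata(sampleData(meta)[ids, , drop = FALSE])
  des <- buildDesign(meta, spec)
  y <- alpha[des$keep]
  if (des$n < des$p + des$rankReduced + 2) stop("too few samples for the design")
  rssR <- sum(stats::lm.fit(des$reduced, y)$residuals^2)
  rssF <- sum(stats::lm.fit(des$full, y)$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- (rssR - rssF) / tss
  if (rssF <= 1e-10 * max(tss, 1e-300)) {
    return(data.frame(covariate = spec$covariate, statistic = Inf,
                      df = des$p, p_value = 0, r2 = r2,
                      r2_adj = .adjustR2(r2, des$n, des$p), n = des$n,
                      flag = "exact-fit"))
  }
  stat <- des$n * log(rssR / rssF)
  data.frame(covariate = spec$covariate, statistic = stat, df = des$p,
             p_value = pchisq(stat, df = des$p, lower.tail = FALSE),
             r2 = r2, r2_adj = .adjustR2(r2, des$n, des$p), n = des$n,
             flag = "")
}
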