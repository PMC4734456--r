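# Taxon-level signatures: aggregate OTUs to phylum/family/genus,
# filter to non-rare taxa, permutation F-tests of square-root
# transformed relative abundances under the batch-adjusted joint
# model, BH-FDR control, and a report with group means and log2 fold
# changes.

.taxonLabels <- function(otus, taxonomy, rank) {
  i <- match(otus, taxonomy$otu_id)
  phylum <- ifelse(is.na(i), "unclassified", taxonomy$phylum[i])
  if (rank == "phylum") return(phylum)
  v <- ifelse(is.na(i), "unclassified", taxonomy[[rank]][i])
  ifelse(phylum == "unclassified", "unclassified", paste(phylum, v, sep = "; "))
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts within each rank label (labels below phylum carry the
#' lineage prefix, e.g. `"Firmicutes; Blautia"`; unmapped or blank
#' ranks aggregate to `"<phylum>; unclassified"`), then converts to
#' per-sample proportions. Aggregation conserves reads: rank-level
#' counts sum to the sample depth before the proportion conversion.
#'
#' @param table a [CountTable-class].
#' @param taxonomy taxonomy data.frame (see [readTaxonomy]).
#' @param rank `"phylum"`, `"family"` or `"genus"`.
#' @param proportions convert to proportions (default); FALSE returns
#'   the aggregated count matrix.
#' @return a [TaxaTable-class] (or a samples x taxa count matrix).
#' @export
aggregateTaxa <- function(table, taxonomy, rank = c("phylum", "family", "genus"),
                          proportions = TRUE) {
  rank <- match.arg(rank)
  if (is.null(taxonomy) || nrow(taxonomy) == 0) stop("empty taxonomy")
  m <- counts(table)
  labels <- .taxonLabels(colnames(m), taxonomy, rank)
  agg <- t(rowsum(t(m), group = labels))
  if (!proportions) return(agg)
  new("TaxaTable", props = agg / rowSums(agg), rank = rank)
}

#' Filter taxa by prevalence and typical nonzero abundance
#'
#' Keeps a taxon iff its prevalence (fraction of samples with a
#' positive proportion) exceeds `minPrevalence` and the median of its
#' nonzero proportions exceeds `minMedianNonzero` (defaults 10% and
#' 0.05%, confining tests to taxa observable in a meaningful share of
#' subjects). The removed taxa are reported via a message.
#'
#' @param taxa a [TaxaTable-class].
#' @param minPrevalence strict lower bound on prevalence.
#' @param minMedianNonzero strict lower bound on the median nonzero
#'   proportion.
#' @return the filtered [TaxaTable-class] (row sums are not
#'   renormalized; proportions keep their cohort meaning). Taxa may be
#'   empty after filtering.
#' @export
filterTaxa <- function(taxa, minPrevalence = 0.10, minMedianNonzero = 5e-4) {
  p <- taxaProportions(taxa)
  prev <- colMeans(p > 0)
  medNZ <- apply(p, 2, function(v) if (any(v > 0)) median(v[v > 0]) else 0)
  keep <- prev > minPrevalence & medNZ > minMedianNonzero
  message(sum(!keep), " of ", length(keep), " ", taxaRank(taxa),
          "-level taxa removed by the prevalence/abundance filter")
  out <- taxa
  out@props <- p[, keep, drop = FALSE]
  out
}

# permutation F-tests of all columns of Y under the joint
# (main + interaction) covariate model, batch-adjusted; one shared
# permutation stream across columns
.permFMatrix <- function(Y, des, nPerm, seed, strata) {
  n <- nrow(Y); p <- des$p
  orthoBasis <- function(X) {
    q <- qr(X)
    qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  }
  Qr <- orthoBasis(des$reduced)
  Qf <- orthoBasis(des$full)
  totSS <- colSums(Y^2)
  rssR <- totSS - colSums(crossprod(Qr, Y)^2)
  rssF <- totSS - colSums(crossprod(Qf, Y)^2)
  dfRes <- n - des$rankFull
  fStat <- ((rssR - rssF) / p) / (rssF / dfRes)
  constant <- rssR <= 1e-12 * pmax(totSS, 1e-300)
  exceed <- integer(ncol(Y))
  set.seed(seed)
  for (b in seq_len(nPerm)) {
    idx <- .permuteWithin(n, strata)
    Qp <- orthoBasis(.dropAliased(.fullDesign(des$x[idx], des$batch),
                                  quiet = TRUE))
    rssP <- totSS - colSums(crossprod(Qp, Y)^2)
    fPerm <- ((rssR - rssP) / p) / (rssP / dfRes)
    exceed <- exceed + (fPerm >= fStat - 1e-12)
  }
  pval <- (1 + exceed) / (1 + nPerm)
  pval[constant] <- 1
  fStat[constant] <- 0
  list(statistic = fStat, p_value = pval, flag = ifelse(constant, "constant", ""))
}

#' Permutation F-test for one taxon's relative abundance
#'
#' Square-root transforms the proportions, fits the batch-adjusted
#' linear model and tests the covariate's joint (main + interaction)
#' terms with the F-statistic; significance comes from permutations of
#' the covariate (within batch strata by default) with the add-one
#' convention. A constant outcome is flagged and given p = 1.
#'
#' @param y named numeric vector of one taxon's per-sample proportions.
#' @param meta a [SampleMetadata-class].
#' @param spec a [designSpec].
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return one-row data.frame: `covariate`, `statistic`, `df`,
#'   `p_value`, `n_perm`, `n`, `flag`.
#' @export
taxonTest <- function(y, meta, spec, nPerm = 1000, seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  ids <- intersect(names(y), sampleIDs(meta))
  if (length(ids) < 3) stop("taxon vector and metadata share too few samples")
  meta <- SampleMetadata(sampleData(meta)[ids, , drop = FALSE])
  des <- buildDesign(meta, spec)
  strata <- if (isTRUE(spec$strata) && nlevels(des$batch) > 1) des$batch else NULL
  res <- .permFMatrix(matrix(sqrt(y[des$keep]), ncol = 1), des, nPerm,
                      .substream(seed, sprintf("taxon-%s", spec$covariate)),
                      strata)
  data.frame(covariate = spec$covariate, statistic = res$statistic,
             df = des$p, p_value = res$p_value, n_perm = nPerm, n = des$n,
             flag = res$flag)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR control: `q_i = min over j with p_(j) >= p_(i) of
#' m * p_(j) / j`, capped at 1 (via [stats::p.adjust]).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, order-preserving on ranks.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Log2 fold change of group mean proportions
#'
#' `log2(mean_a / mean_b)` with group a the exposed/obese group and b
#' the reference. Zero means give `NA` with a warning (no pseudo-count
#' is added).
#'
#' @param meanA,meanB group mean proportions (vectorized).
#' @return log2 fold changes.
#' @examples
#' log2FoldChange(4.339e-1, 5.004e-1)  # about -0.206
#' @export
log2FoldChange <- function(meanA, meanB) {
  out <- rep(NA_real_, length(meanA))
  ok <- meanA > 0 & meanB > 0
  if (any(!ok)) warning("zero group mean(s); fold change undefined for ",
                        sum(!ok), " taxa")
  out[ok] <- log2(meanA[ok] / meanB[ok])
  out
}

.reportGroups <- function(covariate, values, bmiCutoff) {
  if (covariate == "bmi") {
    list(a = "obese", b = "normal", inA = values >= bmiCutoff)
  } else if (is.numeric(values)) {
    list(a = "high", b = "low", inA = values >= median(values))
  } else {
    exposed <- switch(covariate, sex = "M", race = "white",
                      alcohol = "Y", tobacco = "Y", levels(values)[2])
    list(a = exposed, b = setdiff(levels(values), exposed)[1],
         inA = values == exposed)
  }
}

#' Taxon signature report
#'
#' For each rank and covariate: aggregate, filter, permutation-F test
#' every taxon, control FDR (BH) within the rank x covariate family,
#' and report taxa with q below the threshold together with raw group
#' mean proportions and log2 fold changes. Continuous BMI is tested as
#' continuous but displayed by normal/obese groups split at
#' `bmiCutoff` (30 kg/m^2), reporting only.
#'
#' @param table a [CountTable-class].
#' @param taxonomy taxonomy data.frame.
#' @param meta a [SampleMetadata-class].
#' @param covariates covariates to test (default: BMI, sex, race,
#'   tobacco, alcohol; age can be added explicitly).
#' @param ranks taxonomic ranks to test.
#' @param qThreshold report taxa with `q_value < qThreshold`
#'   (default 0.10).
#' @param nPerm,seed permutation settings.
#' @param batch batch column name.
#' @param bmiCutoff BMI group cutoff for reporting (kg/m^2).
#' @return data.frame with columns `rank`, `covariate`, `taxon`,
#'   `group_a`, `group_b`, `mean_a`, `mean_b`, `log2_fold_change`,
#'   `p_value`, `q_value`, `flag`, sorted by q within rank/covariate.
#' @export
signatureReport <- function(table, taxonomy, meta,
                            covariates = c("bmi", "sex", "race", "tobacco",
                                           "alcohol"),
                            ranks = c("phylum", "family", "genus"),
                            qThreshold = 0.10, nPerm = 1000, seed = 1L,
                            batch = "batch", bmiCutoff = 30) {
  empty <- data.frame(rank = character(), covariate = character(),
                      taxon = character(), group_a = character(),
                      group_b = character(), mean_a = numeric(),
                      mean_b = numeric(), log2_fold_change = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      flag = character())
  out <- list(empty)
  for (rk in ranks) {
    taxa <- filterTaxa(aggregateTaxa(table, taxonomy, rk))
    P <- taxaProportions(taxa)
    if (ncol(P) == 0) next
    for (cv in covariates) {
      spec <- designSpec(cv, batch = batch)
      md <- sampleData(meta)[rownames(P), , drop = FALSE]
      ok <- complete.cases(md[, c(cv, batch)])
      sub <- SampleMetadata(md[ok, , drop = FALSE])
      des <- buildDesign(sub, spec)
      strata <- if (nlevels(des$batch) > 1) des$batch else NULL
      Y <- sqrt(P[des$keep, , drop = FALSE])
      res <- .permFMatrix(Y, des, nPerm,
                          .substream(seed, sprintf("sig-%s-%s", rk, cv)),
                          strata)
      q <- bhFdr(res$p_value)
      hit <- which(q < qThreshold)
      if (!length(hit)) next
      grp <- .reportGroups(cv, des$x, bmiCutoff)
      Praw <- P[des$keep, , drop = FALSE]
      meanA <- colMeans(Praw[grp$inA, hit, drop = FALSE])
      meanB <- colMeans(Praw[!grp$inA, hit, drop = FALSE])
      lfc <- suppressWarnings(log2FoldChange(meanA, meanB))
      flag <- res$flag[hit]
      flag[is.na(lfc)] <- paste0(flag[is.na(lfc)], ";zero-mean")
      block <- data.frame(rank = rk, covariate = cv,
                          taxon = colnames(P)[hit],
                          group_a = grp$a, group_b = grp$b,
                          mean_a = meanA, mean_b = meanB,
                          log2_fold_change = lfc,
                          p_value = res$p_value[hit], q_value = q[hit],
                          flag = sub("^;", "", flag))
      out[[length(out) + 1L]] <- block[order(block$q_value, block$taxon), ]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
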