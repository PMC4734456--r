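#' @import methods
#' @importFrom stats median rnorm runif rexp rgamma rbinom rmultinom plogis
#'   qlogis p.adjust pchisq setNames complete.cases dhyper quantile var sd cor
#'   model.matrix lm.fit dist
#' @importFrom utils read.delim write.table head
NULL

.checkIDs <- function(ids, what) {
  if (is.null(ids) || any(!nzchar(ids))) {
    return(sprintf("%s must be named with non-empty ids", what))
  }
  if (anyDuplicated(ids)) {
    return(sprintf("duplicate %s: %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  NULL
}

#' CountTable: sample x OTU read counts
#'
#' The pipeline's central object: a matrix of non-negative integer read
#' counts with samples as rows and OTUs as columns. Row and column names
#' carry the sample and OTU identifiers and must be unique; all-zero
#' sample rows are rejected because they carry no community information.
#'
#' @slot counts numeric matrix of non-negative integers, samples x OTUs.
#' @export
setClass("CountTable", representation(counts = "matrix"))

setValidity("CountTable", function(object) {
  m <- object@counts
  msgs <- c(.checkIDs(rownames(m), "sample ids"),
            .checkIDs(colnames(m), "OTU ids"))
  if (!is.numeric(m)) msgs <- c(msgs, "counts must be numeric")
  else {
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      msgs <- c(msgs, sprintf(
        "counts must be non-negative integers; offending cell sample '%s', OTU '%s'",
        rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    } else if (nrow(m) > 0 && any(rowSums(m) == 0)) {
      z <- rownames(m)[rowSums(m) == 0]
      msgs <- c(msgs, sprintf("all-zero sample rows not allowed: %s",
                              paste(z, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CountTable
#'
#' @param counts matrix of non-negative integer read counts, samples as
#'   rows (canonical orientation), with sample ids as rownames and OTU
#'   ids as colnames.
#' @return a validated [CountTable-class] object.
#' @examples
#' m <- matrix(c(3, 0, 1, 5), 2, 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), c("O1", "O2")))
#' CountTable(m)
#' @export
CountTable <- function(counts) {
  storage.mode(counts) <- "double"
  new("CountTable", counts = counts)
}

#' SampleMetadata: per-sample covariates
#'
#' Per-sample demographic and technical covariates. The canonical schema
#' used throughout the package is: `age` (years, continuous), `sex`
#' (F/M), `race` (white/non-white), `bmi` (kg/m^2, continuous),
#' `alcohol` (Y/N), `tobacco` (Y/N) and `batch` (sequencing batch,
#' factor with >= 1 level), but arbitrary additional covariates are
#' allowed. Missing values are permitted; association tests drop
#' incomplete cases per analysis.
#'
#' @slot data data.frame with unique sample ids as rownames.
#' @export
setClass("SampleMetadata", representation(data = "data.frame"))

setValidity("SampleMetadata", function(object) {
  d <- object@data
  msgs <- .checkIDs(rownames(d), "sample ids")
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]]) && any(is.infinite(d[[j]]))) {
      msgs <- c(msgs, sprintf("non-finite values in column '%s'", names(d)[j]))
    }
  }
  if ("batch" %in% names(d) && all(is.na(d$batch))) {
    msgs <- c(msgs, "batch must have at least one non-missing level")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct SampleMetadata
#'
#' @param data data.frame of covariates with sample ids as rownames (or
#'   in a column named `sample_id`, which is moved to rownames).
#' @return a validated [SampleMetadata-class] object.
#' @export
SampleMetadata <- function(data) {
  if ("sample_id" %in% names(data)) {
    rownames(data) <- as.character(data$sample_id)
    data$sample_id <- NULL
  }
  new("SampleMetadata", data = data)
}

#' DistanceMatrix: pairwise sample dissimilarities
#'
#' Symmetric matrix of pairwise sample dissimilarities d_ij with zero
#' diagonal and finite non-negative entries; UniFrac distances
#' additionally lie in \[0, 1\]. Feeds Gower centering, PERMANOVA and
#' principal coordinate analysis.
#'
#' @slot d symmetric numeric matrix with matching row/column sample ids.
#' @export
setClass("DistanceMatrix", representation(d = "matrix"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  msgs <- .checkIDs(rownames(d), "sample ids")
  if (nrow(d) != ncol(d)) msgs <- c(msgs, "matrix must be square")
  else if (!identical(rownames(d), colnames(d)))
    msgs <- c(msgs, "row and column ids must match")
  if (any(!is.finite(d))) msgs <- c(msgs, "all distances must be finite")
  else {
    if (any(d < 0)) msgs <- c(msgs, "distances must be non-negative")
    if (max(abs(d - t(d))) > 1e-8) msgs <- c(msgs, "matrix must be symmetric")
    if (nrow(d) > 0 && max(abs(diag(d))) > 1e-12)
      msgs <- c(msgs, "diagonal must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DistanceMatrix
#'
#' @param d square symmetric numeric matrix with sample ids as dimnames,
#'   or a [stats::dist] object.
#' @return a validated [DistanceMatrix-class] object.
#' @export
DistanceMatrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d[abs(d) < 1e-15] <- 0
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new("DistanceMatrix", d = d)
}

#' TaxaTable: sample x taxon relative abundances
#'
#' Relative abundances (per-sample proportions, rows summing to one)
#' after aggregating OTU counts to a taxonomic rank. Taxon labels carry
#' a lineage prefix below phylum level, e.g. `"Firmicutes; Blautia"`.
#'
#' @slot props numeric matrix of proportions, samples x taxa.
#' @slot rank single string: "phylum", "family" or "genus".
#' @export
setClass("TaxaTable", representation(props = "matrix", rank = "character"))

setValidity("TaxaTable", function(object) {
  p <- object@props
  msgs <- c(.checkIDs(rownames(p), "sample ids"), .checkIDs(colnames(p), "taxa"))
  if (length(object@rank) != 1L)
    msgs <- c(msgs, "rank must be a single string")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    msgs <- c(msgs, "proportions must lie in [0, 1]")
  else if (nrow(p) > 0 && max(abs(rowSums(p) - 1)) > 1e-9)
    msgs <- c(msgs, "rows must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Ordination: principal coordinates of a distance matrix
#'
#' @slot coordinates samples x k matrix of principal coordinates.
#' @slot explained fraction of positive-eigenvalue variance per axis
#'   (non-increasing, each in \[0, 1\]).
#' @slot eigenvalues all eigenvalues of the Gower matrix, decreasing.
#' @export
setClass("Ordination", representation(coordinates = "matrix",
                                      explained = "numeric",
                                      eigenvalues = "numeric"))

setValidity("Ordination", function(object) {
  e <- object@explained
  msgs <- character()
  if (length(e)) {
    if (any(e < -1e-12 | e > 1 + 1e-12)) msgs <- c(msgs, "explained fractions must lie in [0, 1]")
    if (any(diff(e) > 1e-12)) msgs <- c(msgs, "explained fractions must be non-increasing")
    if (length(e) != ncol(object@coordinates))
      msgs <- c(msgs, "one explained fraction per coordinate axis required")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: synthetic cohort configuration
#'
#' Configuration of the Dirichlet-multinomial cohort simulator. Defaults
#' emulate a two-batch 16S cohort of 118 subjects and 1,745 OTUs whose
#' abundance/prevalence profile is dominated by rare, low-abundance
#' lineages, with sequencing depths log-uniform between 30,000 and
#' 390,000 reads and covariate marginals matching a Midwestern US adult
#' population (see `simulateMetadata`).
#'
#' @slot nSamples number of subjects.
#' @slot nOtus number of OTUs (tree tips).
#' @slot nBatches number of sequencing batches (>= 1), assigned in
#'   contiguous index blocks.
#' @slot depthRange numeric(2); sequencing depth is drawn log-uniformly
#'   between these bounds (equal bounds give fixed depth).
#' @slot alphaSdlog sdlog of the log-normal base Dirichlet
#'   concentrations (larger = more uneven, more rare-dominated).
#' @slot totalMass total Dirichlet concentration (smaller = more
#'   between-sample overdispersion).
#' @slot occupancyBaseline baseline probability that a presence-mode
#'   effect clade is occupied in an unexposed sample.
#' @slot cladeFraction approximate fraction of tips in an effect clade.
#' @slot effects list of effect specifications, each a list with
#'   elements `covariate`, `mode` ("presence" or "abundance"),
#'   `magnitude` (>= 0; log odds / log concentration scale) and
#'   optionally `exposedLevel`.
#' @slot batchMagnitude log-scale concentration tilt applied to a
#'   random OTU subset in non-reference batches.
#' @slot batchFraction fraction of OTUs carrying the batch tilt.
#' @slot seed master seed; all stochastic stages consume named
#'   substreams derived from it.
#' @export
setClass("SimConfig", representation(
  nSamples = "numeric", nOtus = "numeric", nBatches = "numeric",
  depthRange = "numeric", alphaSdlog = "numeric", totalMass = "numeric",
  occupancyBaseline = "numeric", cladeFraction = "numeric",
  effects = "list", batchMagnitude = "numeric", batchFraction = "numeric",
  seed = "numeric"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nSamples < 2 || object@nOtus < 2 || object@nBatches < 1)
    msgs <- c(msgs, "sizes must satisfy nSamples >= 2, nOtus >= 2, nBatches >= 1")
  if (length(object@depthRange) != 2 || any(object@depthRange <= 0) ||
      diff(object@depthRange) < 0)
    msgs <- c(msgs, "depthRange must be two positive non-decreasing values")
  for (e in object@effects) {
    if (!all(c("covariate", "mode", "magnitude") %in% names(e)))
      msgs <- c(msgs, "each effect needs covariate, mode and magnitude")
    else {
      if (!e$mode %in% c("presence", "abundance"))
        msgs <- c(msgs, sprintf("unknown effect mode '%s'", e$mode))
      if (e$magnitude < 0) msgs <- c(msgs, "effect magnitudes must be >= 0")
    }
  }
  if (object@batchMagnitude < 0) msgs <- c(msgs, "batchMagnitude must be >= 0")
  if (object@occupancyBaseline <= 0 || object@occupancyBaseline >= 1)
    msgs <- c(msgs, "occupancyBaseline must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})
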