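#' Accessors for package data classes
#'
#' `counts` returns the sample x OTU count matrix, `sampleIDs` and
#' `otuIDs` the identifier vectors, `sampleDepths` the per-sample read
#' totals, `sampleData` the covariate data.frame, `taxaProportions` and
#' `taxaRank` the aggregated relative-abundance matrix and its rank,
#' and `ordCoordinates` / `explainedVariance` the PCoA coordinates and
#' per-axis explained fractions.
#'
#' @param object an object of the corresponding class.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("otuIDs", function(object) standardGeneric("otuIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleDepths", function(object) standardGeneric("sampleDepths"))
#' @rdname accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setGeneric("taxaProportions", function(object) standardGeneric("taxaProportions"))
#' @rdname accessors
#' @export
setGeneric("taxaRank", function(object) standardGeneric("taxaRank"))
#' @rdname accessors
#' @export
setGeneric("ordCoordinates", function(object) standardGeneric("ordCoordinates"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))

#' @rdname accessors
setMethod("counts", "CountTable", function(object) object@counts)
#' @rdname accessors
setMethod("sampleIDs", "CountTable", function(object) rownames(object@counts))
#' @rdname accessors
setMethod("otuIDs", "CountTable", function(object) colnames(object@counts))
#' @rdname accessors
setMethod("sampleDepths", "CountTable",
          function(object) rowSums(object@counts))
#' @rdname accessors
setMethod("sampleIDs", "SampleMetadata", function(object) rownames(object@data))
#' @rdname accessors
setMethod("sampleData", "SampleMetadata", function(object) object@data)
#' @rdname accessors
setMethod("sampleIDs", "DistanceMatrix", function(object) rownames(object@d))
#' @rdname accessors
setMethod("sampleIDs", "TaxaTable", function(object) rownames(object@props))
#' @rdname accessors
setMethod("taxaProportions", "TaxaTable", function(object) object@props)
#' @rdname accessors
setMethod("taxaRank", "TaxaTable", function(object) object@rank)
#' @rdname accessors
setMethod("ordCoordinates", "Ordination", function(object) object@coordinates)
#' @rdname accessors
setMethod("explainedVariance", "Ordination", function(object) object@explained)

#' @export
#' @method as.matrix CountTable
as.matrix.CountTable <- function(x, ...) x@counts
#' @export
#' @method as.matrix DistanceMatrix
as.matrix.DistanceMatrix <- function(x, ...) x@d
#' @export
#' @method as.matrix TaxaTable
as.matrix.TaxaTable <- function(x, ...) x@props

setMethod("show", "CountTable", function(object) {
  m <- object@counts
  cat(sprintf("CountTable: %d samples x %d OTUs\n", nrow(m), ncol(m)))
  cat(sprintf("  depth: median %s (range %s-%s)\n",
              format(median(rowSums(m))), format(min(rowSums(m))),
              format(max(rowSums(m)))))
  cat(sprintf("  nonzero entries: %.1f%%\n", 100 * mean(m > 0)))
})

setMethod("show", "SampleMetadata", function(object) {
  cat(sprintf("SampleMetadata: %d samples, %d covariates (%s)\n",
              nrow(object@data), ncol(object@data),
              paste(names(object@data), collapse = ", ")))
})

setMethod("show", "DistanceMatrix", function(object) {
  d <- object@d
  off <- d[upper.tri(d)]
  cat(sprintf("DistanceMatrix: %d samples", nrow(d)))
  if (length(off)) cat(sprintf("; distances %.4g-%.4g (median %.4g)",
                               min(off), max(off), median(off)))
  cat("\n")
})

setMethod("show", "TaxaTable", function(object) {
  cat(sprintf("TaxaTable (%s): %d samples x %d taxa\n",
              object@rank, nrow(object@props), ncol(object@props)))
})

setMethod("show", "Ordination", function(object) {
  cat(sprintf("Ordination: %d samples, %d axes\n",
              nrow(object@coordinates), ncol(object@coordinates)))
  if (length(object@explained))
    cat("  explained:", paste(sprintf("%.1f%%", 100 * head(object@explained, 5)),
                              collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d samples, %d OTUs, %d batch(es), depth %s-%s, seed %d\n",
              object@nSamples, object@nOtus, object@nBatches,
              format(object@depthRange[1]), format(object@depthRange[2]),
              as.integer(object@seed)))
  if (length(object@effects)) {
    for (e in object@effects)
      cat(sprintf("  effect: %s [%s] magnitude %.3g\n",
                  e$covariate, e$mode, e$magnitude))
  } else cat("  no planted covariate effects\n")
})
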