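# Readers and writers for the classic tab-separated microbiome formats:
# counts (BIOM-style classic TSV), Newick trees, taxonomy and metadata
# TSVs. All writers emit the same dialect the readers accept, so
# write-then-read round-trips reproduce values exactly.

#' Read a sample x OTU count table from TSV
#'
#' Reads a classic BIOM-style tab-separated count table. Both
#' orientations are accepted via `orientation`; the returned object is
#' always in the package's canonical samples-as-rows form.
#'
#' @param path path to a TSV file whose first column holds row ids and
#'   whose header holds column ids (a leading `#OTU ID` comment-style
#'   header cell is tolerated).
#' @param orientation `"samples"` if rows are samples (default),
#'   `"otus"` if rows are OTUs (the classic BIOM dialect).
#' @return a [CountTable-class].
#' @export
readCountTable <- function(path, orientation = c("samples", "otus")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("no samples: count table needs a header and at least one row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncolumns <- length(header) - 1L
  if (ncolumns < 1) stop("no samples: count table has no data columns")
  rowids <- vapply(fields[-1], `[`, "", 1L)
  m <- matrix(NA_real_, nrow = length(rowids), ncol = ncolumns,
              dimnames = list(rowids, header[-1]))
  for (i in seq_along(fields[-1])) {
    f <- fields[-1][[i]]
    if (length(f) != ncolumns + 1L)
      stop(sprintf("format error: row '%s' has %d cells, expected %d",
                   rowids[i], length(f) - 1L, ncolumns))
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("format error: cell '%s' at row '%s', column '%s' is not a non-negative integer",
                   f[-1][bad[1]], rowids[i], header[-1][bad[1]]))
    m[i, ] <- v
  }
  if (orientation == "otus") m <- t(m)
  CountTable(m)
}

#' Write a CountTable as TSV
#'
#' @param table a [CountTable-class].
#' @param path output path; samples-as-rows dialect.
#' @export
writeCountTable <- function(table, path) {
  m <- counts(table)
  .writeTSV(data.frame(sample_id = rownames(m),
                       as.data.frame(m, check.names = FALSE),
                       check.names = FALSE), path)
}

.writeTSV <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, "")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Parses a single-tree Newick file via [ape::read.tree]. Missing branch
#' lengths default to zero with a warning; duplicate tip labels,
#' unbalanced parentheses (reported with the offending character
#' position) and unrooted trees are errors.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] rooted tree with non-negative branch lengths.
#' @export
readNewick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("parse error: unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L) stop(sprintf("parse error: %d unclosed '(' in Newick string", depth))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("parse error: not a valid Newick tree")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, found several")
  validatePhylo(tree)
}

#' Validate a phylo object for use in UniFrac
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, with absent branch lengths replaced by zeros (a
#'   warning is emitted in that case).
#' @export
validatePhylo <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Default metadata schema
#'
#' Field specification used by [readSampleMetadata]: types and
#' canonical categorical levels for the cohort covariates. Categorical
#' values are canonicalized case-insensitively, e.g. `"female"` /
#' `"f"` to `"F"`, `"w"` to `"white"`, `"yes"` to `"Y"`.
#'
#' @return a named list of field specs (`type`, and for categoricals a
#'   `canon` map from lower-cased synonyms to canonical levels).
#' @export
metadataSchema <- function() {
  list(
    age     = list(type = "numeric"),
    sex     = list(type = "categorical",
                   canon = c(f = "F", female = "F", m = "M", male = "M")),
    race    = list(type = "categorical",
                   canon = c(white = "white", w = "white",
                             "non-white" = "non-white", nonwhite = "non-white",
                             nw = "non-white")),
    bmi     = list(type = "numeric"),
    alcohol = list(type = "categorical",
                   canon = c(y = "Y", yes = "Y", n = "N", no = "N")),
    tobacco = list(type = "categorical",
                   canon = c(y = "Y", yes = "Y", n = "N", no = "N")),
    batch   = list(type = "factor")
  )
}

#' Read per-sample metadata from TSV
#'
#' @param path TSV with a header; one row per sample. The sample id is
#'   taken from a `sample_id` column or, failing that, the first column.
#' @param schema field specification, see [metadataSchema]. Fields in
#'   the schema must be present; extra columns are kept as-is.
#' @return a [SampleMetadata-class].
#' @export
readSampleMetadata <- function(path, schema = metadataSchema()) {
  d <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  if (nrow(d) == 0) stop("no samples in metadata file")
  idcol <- if ("sample_id" %in% names(d)) "sample_id" else names(d)[1]
  ids <- d[[idcol]]
  d[[idcol]] <- NULL
  missing <- setdiff(names(schema), names(d))
  if (length(missing))
    stop("missing required metadata column(s): ", paste(missing, collapse = ", "))
  for (fld in names(schema)) {
    spec <- schema[[fld]]
    x <- d[[fld]]
    x[x %in% c("", "NA")] <- NA
    if (spec$type == "numeric") {
      v <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(v))
      if (length(bad))
        stop(sprintf("cannot parse numeric value '%s' in column '%s', sample '%s'",
                     x[bad[1]], fld, ids[bad[1]]))
      d[[fld]] <- v
    } else if (spec$type == "categorical") {
      key <- tolower(trimws(x))
      v <- unname(spec$canon[key])
      bad <- which(!is.na(x) & is.na(v))
      if (length(bad))
        stop(sprintf("unknown level '%s' in column '%s', sample '%s' (expected one of: %s)",
                     x[bad[1]], fld, ids[bad[1]],
                     paste(unique(spec$canon), collapse = ", ")))
      d[[fld]] <- factor(v, levels = unique(unname(spec$canon)))
    } else {
      d[[fld]] <- factor(x)
    }
  }
  rownames(d) <- ids
  SampleMetadata(d)
}

#' Write SampleMetadata as TSV
#' @param meta a [SampleMetadata-class].
#' @param path output path.
#' @export
writeSampleMetadata <- function(meta, path) {
  d <- sampleData(meta)
  .writeTSV(data.frame(sample_id = rownames(d), d, check.names = FALSE), path)
}

#' Read an OTU taxonomy map from TSV
#'
#' @param path TSV with columns `otu_id`, `phylum`, `family`, `genus`
#'   (header required). Blank or missing ranks become `"unclassified"`.
#' @return data.frame with those four columns, one row per OTU.
#' @export
readTaxonomy <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                  check.names = FALSE, strip.white = TRUE)
  need <- c("otu_id", "phylum", "family", "genus")
  if (!all(need %in% names(d)))
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$otu_id))
    stop("duplicate OTU ids in taxonomy: ",
         paste(unique(d$otu_id[duplicated(d$otu_id)]), collapse = ", "))
  for (r in c("phylum", "family", "genus")) {
    d[[r]][is.na(d[[r]]) | !nzchar(d[[r]])] <- "unclassified"
  }
  d[need]
}

#' Write a taxonomy map as TSV
#' @param taxonomy data.frame as returned by [readTaxonomy].
#' @param path output path.
#' @export
writeTaxonomy <- function(taxonomy, path) .writeTSV(taxonomy, path)

#' Write a DistanceMatrix as a square TSV
#' @param D a [DistanceMatrix-class].
#' @param path output path.
#' @export
writeDistanceMatrix <- function(D, path) {
  m <- as.matrix(D)
  .writeTSV(data.frame(sample_id = rownames(m),
                       as.data.frame(m, check.names = FALSE),
                       check.names = FALSE), path)
}

#' Read a DistanceMatrix from a square TSV
#' @param path TSV written by [writeDistanceMatrix].
#' @return a [DistanceMatrix-class].
#' @export
readDistanceMatrix <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  rownames(d) <- d[[1]]
  DistanceMatrix(as.matrix(d[-1]))
}

#' Align a count table, metadata, tree and taxonomy
#'
#' Restricts samples to the intersection of count-table and metadata
#' ids (keeping the count table's order), reports OTUs absent from the
#' tree or taxonomy, and logs every dropped entity. Idempotent.
#'
#' @param table a [CountTable-class].
#' @param meta a [SampleMetadata-class].
#' @param tree optional [ape::phylo]; extra tips are pruned (they carry
#'   no branch mass for the observed communities).
#' @param taxonomy optional taxonomy data.frame; OTUs without an entry
#'   are reported (they aggregate to "unclassified" downstream).
#' @return list with elements `table`, `meta`, `tree`, `taxonomy` and a
#'   `dropped` list of dropped/unmapped ids.
#' @export
alignExperiment <- function(table, meta, tree = NULL, taxonomy = NULL) {
  keep <- intersect(sampleIDs(table), sampleIDs(meta))
  if (length(keep) == 0) stop("no samples shared between count table and metadata")
  droppedTab <- setdiff(sampleIDs(table), keep)
  droppedMeta <- setdiff(sampleIDs(meta), keep)
  if (length(droppedTab))
    message("dropping ", length(droppedTab), " sample(s) absent from metadata: ",
            paste(droppedTab, collapse = ", "))
  if (length(droppedMeta))
    message("dropping ", length(droppedMeta), " sample(s) absent from count table: ",
            paste(droppedMeta, collapse = ", "))
  table <- CountTable(counts(table)[keep, , drop = FALSE])
  meta <- SampleMetadata(sampleData(meta)[keep, , drop = FALSE])
  otusNoTip <- character()
  if (!is.null(tree)) {
    otusNoTip <- setdiff(otuIDs(table), tree$tip.label)
    if (length(otusNoTip))
      message(length(otusNoTip), " OTU(s) absent from the tree (UniFrac will refuse them unless pruned)")
    extraTips <- setdiff(tree$tip.label, otuIDs(table))
    if (length(extraTips)) {
      message("pruning ", length(extraTips), " tree tip(s) not in the count table")
      tree <- ape::drop.tip(tree, extraTips)
    }
  }
  otusNoTax <- character()
  if (!is.null(taxonomy)) {
    otusNoTax <- setdiff(otuIDs(table), taxonomy$otu_id)
    if (length(otusNoTax))
      message(length(otusNoTax), " OTU(s) without taxonomy (will aggregate to 'unclassified')")
  }
  list(table = table, meta = meta, tree = tree, taxonomy = taxonomy,
       dropped = list(samples_table = droppedTab, samples_meta = droppedMeta,
                      otus_not_in_tree = otusNoTip, otus_unmapped = otusNoTax))
}
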