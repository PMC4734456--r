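# Phylogenetic beta diversity: unweighted and weighted UniFrac from a
# count table and a rooted tree, Gower centering of squared distances,
# and principal coordinate analysis. Edge-wise community mass is
# accumulated through a sparse tip x edge incidence matrix; the edge
# above the root (not represented in the edge matrix of a rooted ape
# tree) contributes to neither community, by convention.

# sparse tips x edges incidence: inc[t, e] = 1 if tip t descends from
# the child end of edge e
.edgeIncidence <- function(tree) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  Matrix::sparseMatrix(i = unlist(desc),
                       j = rep(seq_along(desc), lengths(desc)),
                       x = 1,
                       dims = c(length(tree$tip.label), nrow(tree$edge)))
}

.edgeMass <- function(m, tree) {
  # m: samples x tips count matrix, columns ordered as tree$tip.label
  as.matrix(m %*% .edgeIncidence(tree))
}

.checkUnifracInput <- function(a, b, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  for (v in list(a, b)) {
    if (length(v) != length(tree$tip.label))
      stop("count vectors must be indexed by the tree's tips")
    if (sum(v) == 0) stop("UniFrac undefined for an empty community")
  }
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of total branch length leading exclusively to tips present
#' in only one of the two communities: `sum(b_e unique) / sum(b_e
#' either)`, where a branch "leads to" present tips if any descendant
#' tip has a positive count. Depends on presence/absence only.
#'
#' @param a,b count vectors ordered as `tree$tip.label`.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return distance in \[0, 1\].
#' @export
unweightedUnifrac <- function(a, b, tree) {
  .checkUnifracInput(a, b, tree)
  mass <- .edgeMass(rbind(a, b), tree)
  pa <- mass[1, ] > 0; pb <- mass[2, ] > 0
  bl <- tree$edge.length
  den <- sum(bl[pa | pb])
  if (den == 0) stop("no branch length subtends either community")
  sum(bl[xor(pa, pb)]) / den
}

#' Weighted (normalized) UniFrac distance between two communities
#'
#' Abundance-weighted UniFrac in its normalized, \[0, 1\]-bounded form:
#' `sum(b_e * |pA_e - pB_e|) / sum(b_e * (pA_e + pB_e))`, where `pX_e`
#' is the fraction of community X's reads descending from edge `e`.
#' Set `raw = TRUE` for the unnormalized numerator.
#'
#' @inheritParams unweightedUnifrac
#' @param raw return the unnormalized branch-length-weighted sum.
#' @return normalized distance in \[0, 1\] (or the raw sum).
#' @export
weightedUnifrac <- function(a, b, tree, raw = FALSE) {
  .checkUnifracInput(a, b, tree)
  mass <- .edgeMass(rbind(a, b), tree)
  pa <- mass[1, ] / sum(a); pb <- mass[2, ] / sum(b)
  bl <- tree$edge.length
  num <- sum(bl * abs(pa - pb))
  if (raw) return(num)
  den <- sum(bl * (pa + pb))
  if (den == 0) stop("no branch length subtends either community")
  num / den
}

#' All pairwise UniFrac distances of a cohort
#'
#' Rarefies the count table to a common depth (a single seeded draw;
#' see [rarefy]) and computes all pairwise unweighted or weighted
#' UniFrac distances.
#'
#' @param table a [CountTable-class] whose OTUs appear among the
#'   tree's tips; OTUs missing from the tree are an error unless
#'   `pruneMissing = TRUE` drops them with a warning.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param metric `"unweighted"` or `"weighted"`.
#' @param rarefyDepth depth for [rarefy]; `"auto"` (default) uses the
#'   minimum sample depth; `NA` skips rarefaction.
#' @param seed seed forwarded to [rarefy].
#' @return a [DistanceMatrix-class].
#' @export
pairwiseDistances <- function(table, tree, metric = c("unweighted", "weighted"),
                              rarefyDepth = "auto", seed = 1L,
                              pruneMissing = FALSE) {
  metric <- match.arg(metric)
  missing <- setdiff(otuIDs(table), tree$tip.label)
  if (length(missing)) {
    if (!pruneMissing)
      stop(length(missing), " OTU(s) absent from the tree, e.g. ",
           paste(head(missing, 3), collapse = ", "),
           "; set pruneMissing = TRUE to drop them")
    warning("dropping ", length(missing), " OTU(s) absent from the tree")
    kept <- counts(table)[, setdiff(otuIDs(table), missing), drop = FALSE]
    kept <- kept[rowSums(kept) > 0, , drop = FALSE]
    table <- CountTable(kept)
  }
  extra <- setdiff(tree$tip.label, otuIDs(table))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  if (!is.null(rarefyDepth) && !is.na(rarefyDepth))
    table <- rarefy(table, depth = rarefyDepth, seed = seed)
  m <- counts(table)[, tree$tip.label, drop = FALSE]
  ns <- nrow(m)
  if (ns < 2) stop("need at least 2 samples after rarefaction")
  mass <- .edgeMass(m, tree)
  bl <- tree$edge.length
  d <- matrix(0, ns, ns, dimnames = list(rownames(m), rownames(m)))
  if (metric == "unweighted") {
    pres <- mass > 0
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      den <- sum(bl[pres[i, ] | pres[j, ]])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else
        sum(bl[xor(pres[i, ], pres[j, ])]) / den
    }
  } else {
    prop <- mass / rowSums(m)
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      den <- sum(bl * (prop[i, ] + prop[j, ]))
      d[i, j] <- d[j, i] <- if (den == 0) 0 else
        sum(bl * abs(prop[i, ] - prop[j, ])) / den
    }
  }
  DistanceMatrix(d)
}

#' Gower-centered matrix of a distance matrix
#'
#' `G = (I - 11'/n) A (I - 11'/n)` with `A = (-d_ij^2 / 2)`. Rows and
#' columns of G sum to zero and `tr(G)` equals the total multivariate
#' dispersion `sum_{i<j} d_ij^2 / n`.
#'
#' @param D a [DistanceMatrix-class] (or a square symmetric matrix).
#' @return the centered matrix G (plain matrix, same dimnames).
#' @export
gowerCenter <- function(D) {
  d <- if (is(D, "DistanceMatrix")) as.matrix(D) else D
  A <- -d^2 / 2
  rm <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), rm) + gm
  dimnames(G) <- dimnames(d)
  G
}

#' Principal coordinate analysis
#'
#' Eigendecomposition of the Gower-centered matrix; coordinates are
#' eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues (non-Euclidean distances) are
#' dropped with a diagnostic message; `explained` is each retained
#' eigenvalue over the sum of positive eigenvalues.
#'
#' @param D a [DistanceMatrix-class].
#' @param k number of axes requested; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return an [Ordination-class].
#' @export
pcoaOrdination <- function(D, k = 2) {
  if (k < 1) stop("k must be >= 1")
  G <- gowerCenter(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-9
  pos <- which(e$values > tol)
  neg <- sum(e$values < -tol)
  if (neg > 0)
    message(neg, " negative eigenvalue(s) dropped (non-Euclidean distances)")
  if (length(pos) == 0) {
    return(new("Ordination",
               coordinates = matrix(0, nrow(G), 0,
                                    dimnames = list(rownames(G), NULL)),
               explained = numeric(), eigenvalues = e$values))
  }
  if (k > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); truncating k")
    k <- length(pos)
  }
  idx <- pos[seq_len(k)]
  coords <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(e$values[idx]), nrow = k)
  dimnames(coords) <- list(rownames(G), sprintf("PC%d", seq_len(k)))
  new("Ordination", coordinates = coords,
      explained = e$values[idx] / sum(e$values[pos]),
      eigenvalues = e$values)
}
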