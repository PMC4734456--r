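# Independent brute-force oracles and small fixtures shared by the
# tests. The oracles deliberately use different algorithms from the
# package internals: edge tip-sets are found by walking each tip's
# path to the root, not by postorder accumulation.

fourTipTree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# tips under each edge, by climbing parent pointers from every tip
bruteTipsets <- function(tree) {
  nTip <- length(tree$tip.label)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  lapply(seq_len(nrow(tree$edge)), function(e) {
    under <- integer()
    for (t in seq_len(nTip)) {
      node <- t
      repeat {
        i <- match(node, child)
        if (is.na(i)) break
        if (i == e) { under <- c(under, t); break }
        node <- parent[i]
      }
    }
    under
  })
}

bruteUnweightedUnifrac <- function(a, b, tree) {
  sets <- bruteTipsets(tree)
  bl <- tree$edge.length
  inA <- vapply(sets, function(s) any(a[s] > 0), TRUE)
  inB <- vapply(sets, function(s) any(b[s] > 0), TRUE)
  sum(bl[xor(inA, inB)]) / sum(bl[inA | inB])
}

bruteWeightedUnifrac <- function(a, b, tree) {
  sets <- bruteTipsets(tree)
  bl <- tree$edge.length
  pA <- vapply(sets, function(s) sum(a[s]), 0) / sum(a)
  pB <- vapply(sets, function(s) sum(b[s]), 0) / sum(b)
  sum(bl * abs(pA - pB)) / sum(bl * (pA + pB))
}

# exact mean over all subsamples of size m (n small)
enumerateSubsamples <- function(x, m, statistic) {
  reads <- rep(seq_along(x), x)
  combs <- utils::combn(length(reads), m)
  mean(apply(combs, 2, function(ix)
    statistic(tabulate(reads[ix], nbins = length(x)))))
}

smallCounts <- function() {
  CountTable(matrix(c(3, 0, 2, 1, 5, 4, 0, 6), 2, 4, byrow = TRUE,
                    dimnames = list(c("S1", "S2"),
                                    c("O1", "O2", "O3", "O4"))))
}

smallMeta <- function(n, seed = 1, nBatches = 2) {
  set.seed(seed)
  SampleMetadata(data.frame(
    age = runif(n, 20, 79), sex = factor(sample(c("F", "M"), n, TRUE)),
    race = factor(sample(c("white", "non-white"), n, TRUE, prob = c(.8, .2))),
    bmi = rnorm(n, 27, 4), alcohol = factor(sample(c("Y", "N"), n, TRUE)),
    tobacco = factor(sample(c("Y", "N"), n, TRUE, prob = c(.15, .85))),
    batch = factor(rep(c("b1", "b2"), length.out = n)),
    row.names = sprintf("S%04d", seq_len(n))))
}

# small, quick cohort for end-to-end tests
testSimConfig <- function(seed = 1, ...) {
  args <- list(nSamples = 40, nOtus = 120, depthRange = c(1500, 3000),
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}
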