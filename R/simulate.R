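# Seeded Dirichlet-multinomial cohort simulator. One master seed; every
# stochastic stage consumes a named substream derived from it, so
# stages can be re-run independently and still reproduce.

.substream <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2047483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate a two-batch cohort of 118 subjects and 1,745 OTUs
#' with rare-dominated abundance/prevalence, sequencing depth
#' log-uniform in 30,000-390,000 reads, and small planted
#' presence-mode (rare-clade occupancy) effects for race, BMI, alcohol,
#' sex and tobacco, none for age. See [SimConfig-class] for the slots.
#'
#' @param nSamples,nOtus,nBatches cohort dimensions.
#' @param depthRange two positive bounds for log-uniform depth.
#' @param alphaSdlog,totalMass log-normal base-concentration shape and
#'   total Dirichlet mass.
#' @param occupancyBaseline,cladeFraction presence-effect clade
#'   occupancy baseline and approximate clade size fraction.
#' @param effects list of effect specs (`covariate`, `mode`,
#'   `magnitude`, optional `exposedLevel`); `NULL` gives the default
#'   planted-effect set, `list()` gives a null cohort.
#' @param batchMagnitude,batchFraction batch tilt size and affected OTU
#'   fraction.
#' @param seed master seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nSamples = 118, nOtus = 1745, nBatches = 2,
                      depthRange = c(30000, 390000),
                      alphaSdlog = 1.6, totalMass = 150,
                      occupancyBaseline = 0.25, cladeFraction = 0.05,
                      effects = NULL,
                      batchMagnitude = 0.4, batchFraction = 0.2,
                      seed = 1L) {
  if (is.null(effects)) {
    effects <- list(
      list(covariate = "race",    mode = "presence", magnitude = 1.2),
      list(covariate = "bmi",     mode = "presence", magnitude = 1.0),
      list(covariate = "alcohol", mode = "presence", magnitude = 0.8),
      list(covariate = "sex",     mode = "presence", magnitude = 0.7),
      list(covariate = "tobacco", mode = "presence", magnitude = 0.6))
  }
  new("SimConfig", nSamples = nSamples, nOtus = nOtus, nBatches = nBatches,
      depthRange = as.numeric(depthRange), alphaSdlog = alphaSdlog,
      totalMass = totalMass, occupancyBaseline = occupancyBaseline,
      cladeFraction = cladeFraction, effects = effects,
      batchMagnitude = batchMagnitude, batchFraction = batchFraction,
      seed = seed)
}

#' Simulate a random rooted OTU tree
#'
#' Random-joining rooted bifurcating topology (via [ape::rtree]) with
#' exponential branch lengths (mean 0.1). A rooted bifurcating tree on
#' `n` tips has `2n - 2` edges.
#'
#' @param nTips number of tips (>= 2); labels `OTU000001`, ...
#' @param seed integer seed; identical seeds give identical trees.
#' @return an [ape::phylo] rooted tree.
#' @export
simulateTree <- function(nTips, seed = 1L) {
  if (nTips < 2) stop("nTips must be >= 2")
  set.seed(.substream(seed, "tree"))
  tree <- ape::rtree(nTips, rooted = TRUE,
                     br = function(k) rexp(k, rate = 10))
  tree$tip.label <- sprintf("OTU%06d", seq_len(nTips))
  tree
}

.table1Marginals <- function() {
  # stratum-specific covariate marginals of a Midwestern US adult cohort
  list(under50 = c(F = 0.517, white = 0.845, alcohol = 0.707, tobacco = 0.155,
                   bmiMean = 27.0, bmiSd = 4.5),
       over50  = c(F = 0.500, white = 0.900, alcohol = 0.650, tobacco = 0.133,
                   bmiMean = 28.0, bmiSd = 4.5))
}

#' Simulate per-sample metadata
#'
#' Ages are uniform over 20-79 years; sex, race, alcohol and tobacco
#' are drawn with age-stratum-specific marginals matching the cohort
#' the package emulates (about 51% female, 84-90% white, 65-71%
#' alcohol users, 13-16% smokers); BMI is normal within stratum
#' (fraction above 30 kg/m^2 about 0.25 / 0.33) and clamped to
#' [16, 60]. Batches are assigned in contiguous sample-index blocks,
#' mimicking two recruitment rounds.
#'
#' @param config a [SimConfig-class].
#' @return a [SampleMetadata-class] with the canonical schema.
#' @export
simulateMetadata <- function(config) {
  set.seed(.substream(config@seed, "meta"))
  n <- config@nSamples
  marg <- .table1Marginals()
  age <- runif(n, 20, 79.999)
  strat <- ifelse(age < 50, "under50", "over50")
  draw <- function(key) {
    p <- vapply(strat, function(s) marg[[s]][[key]], 0)
    rbinom(n, 1, p)
  }
  sex <- factor(ifelse(draw("F") == 1, "F", "M"), levels = c("F", "M"))
  race <- factor(ifelse(draw("white") == 1, "white", "non-white"),
                 levels = c("white", "non-white"))
  alcohol <- factor(ifelse(draw("alcohol") == 1, "Y", "N"), levels = c("Y", "N"))
  tobacco <- factor(ifelse(draw("tobacco") == 1, "Y", "N"), levels = c("Y", "N"))
  bmi <- rnorm(n,
               mean = vapply(strat, function(s) marg[[s]][["bmiMean"]], 0),
               sd = vapply(strat, function(s) marg[[s]][["bmiSd"]], 0))
  bmi <- pmin(pmax(bmi, 16), 60)
  block <- ceiling(seq_len(n) / (n / config@nBatches))
  batch <- factor(sprintf("batch%d", pmin(block, config@nBatches)))
  d <- data.frame(age = age, sex = sex, race = race, bmi = round(bmi, 1),
                  alcohol = alcohol, tobacco = tobacco, batch = batch,
                  row.names = sprintf("S%04d", seq_len(n)))
  SampleMetadata(d)
}

#' Simulate an OTU taxonomy map
#'
#' Random phylum/family/genus hierarchy (defaults: 11 phyla, 80
#' families, 171 genera, matching the richness of a deep 16S gut
#' survey) with log-normal genus sizes; a fraction of OTUs is left
#' unclassified at the genus and/or family level.
#'
#' @param nOtus number of OTUs; labels match [simulateTree].
#' @param seed integer seed.
#' @param nPhyla,nFamilies,nGenera hierarchy sizes.
#' @return taxonomy data.frame (`otu_id`, `phylum`, `family`, `genus`).
#' @export
simulateTaxonomy <- function(nOtus, seed = 1L, nPhyla = 11, nFamilies = 80,
                             nGenera = 171) {
  set.seed(.substream(seed, "taxonomy"))
  phyla <- sprintf("Phylum%02d", seq_len(nPhyla))
  famPhylum <- sample(phyla, nFamilies, replace = TRUE,
                      prob = exp(rnorm(nPhyla, 0, 1)))
  families <- sprintf("Family%03d", seq_len(nFamilies))
  genFamily <- sample(seq_len(nFamilies), nGenera, replace = TRUE,
                      prob = exp(rnorm(nFamilies, 0, 1)))
  genera <- sprintf("Genus%03d", seq_len(nGenera))
  g <- sample(seq_len(nGenera), nOtus, replace = TRUE,
              prob = exp(rnorm(nGenera, 0, 1.5)))
  d <- data.frame(otu_id = sprintf("OTU%06d", seq_len(nOtus)),
                  phylum = famPhylum[genFamily[g]],
                  family = families[genFamily[g]],
                  genus = genera[g])
  dropGenus <- runif(nOtus) < 0.15
  d$genus[dropGenus] <- "unclassified"
  d$family[dropGenus & runif(nOtus) < 0.5] <- "unclassified"
  d
}

.effectCovariateValues <- function(e, metaData) {
  if (!e$covariate %in% names(metaData))
    stop(sprintf("effect references unknown covariate '%s'", e$covariate))
  x <- metaData[[e$covariate]]
  if (is.numeric(x)) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  } else {
    exposed <- e$exposedLevel
    if (is.null(exposed)) {
      exposed <- switch(e$covariate, sex = "M", race = "white",
                        alcohol = "Y", tobacco = "Y", levels(x)[1])
    }
    as.numeric(x == exposed)
  }
}

# pick disjoint low-abundance clades (tips below an internal node) of
# roughly the requested size, rarest (smallest base mass) first
.pickEffectClades <- function(tree, baseAlpha, nClades, fraction) {
  nTip <- length(tree$tip.label)
  target <- max(2, round(fraction * nTip))
  nodes <- (nTip + 1):(nTip + tree$Nnode)
  tipsets <- phangorn::Descendants(tree, nodes, type = "tips")
  sizes <- lengths(tipsets)
  ok <- which(sizes >= max(2, round(0.5 * target)) & sizes <= round(1.8 * target))
  if (length(ok) < nClades)
    ok <- which(sizes >= 2 & sizes <= max(3, round(2.5 * target)))
  mass <- vapply(ok, function(i) sum(baseAlpha[tipsets[[i]]]), 0)
  ord <- ok[order(mass)]
  clades <- list(); used <- integer()
  for (i in ord) {
    tips <- tipsets[[i]]
    if (!length(intersect(tips, used))) {
      clades[[length(clades) + 1L]] <- tips
      used <- c(used, tips)
      if (length(clades) == nClades) break
    }
  }
  if (length(clades) < nClades)
    stop("could not find enough disjoint effect clades; lower cladeFraction")
  clades
}

#' Simulate a sample x OTU count table
#'
#' Per sample, a composition is drawn from a Dirichlet whose base
#' concentrations are log-normal (rare-dominated), tilted by batch and
#' planted covariate effects, and counts are multinomial at the
#' sample's log-uniform sequencing depth. Abundance-mode effects tilt
#' the concentrations of a designated rare clade by
#' `exp(magnitude * x)`; presence-mode effects multiply the odds that
#' the clade is occupied at all by `exp(magnitude * x)` (baseline
#' occupancy `occupancyBaseline`), concentrating the signal on
#' community membership of rare lineages. With all magnitudes zero the
#' samples are exchangeable.
#'
#' @param config a [SimConfig-class].
#' @param meta a [SampleMetadata-class] from [simulateMetadata] (or
#'   user-supplied with the same schema and a `batch` column).
#' @param tree an [ape::phylo] whose tips are the OTUs.
#' @return a [CountTable-class]; deterministic given `config@seed`.
#' @export
simulateCounts <- function(config, meta, tree) {
  md <- sampleData(meta)
  n <- nrow(md)
  nOtu <- length(tree$tip.label)
  set.seed(.substream(config@seed, "alpha"))
  baseAlpha <- exp(rnorm(nOtu, 0, config@alphaSdlog))
  baseAlpha <- baseAlpha / sum(baseAlpha) * config@totalMass

  set.seed(.substream(config@seed, "batch-effect"))
  nBatchOtus <- round(config@batchFraction * nOtu)
  batchIdx <- sample.int(nOtu, nBatchOtus)
  batchSign <- sample(c(-1, 1), nBatchOtus, replace = TRUE)
  batchLevels <- levels(factor(md$batch))

  effects <- config@effects
  clades <- list()
  if (length(effects)) {
    set.seed(.substream(config@seed, "clades"))
    clades <- .pickEffectClades(tree, baseAlpha, length(effects),
                                config@cladeFraction)
  }
  xvals <- lapply(effects, .effectCovariateValues, metaData = md)

  set.seed(.substream(config@seed, "depth"))
  lo <- config@depthRange[1]; hi <- config@depthRange[2]
  depths <- round(exp(runif(n, log(lo), log(hi))))

  set.seed(.substream(config@seed, "counts"))
  m <- matrix(0, n, nOtu, dimnames = list(rownames(md), tree$tip.label))
  logit0 <- qlogis(config@occupancyBaseline)
  for (s in seq_len(n)) {
    a <- baseAlpha
    if (config@batchMagnitude > 0 && length(batchLevels) > 1 &&
        !is.na(md$batch[s]) && md$batch[s] != batchLevels[1]) {
      a[batchIdx] <- a[batchIdx] * exp(config@batchMagnitude * batchSign)
    }
    for (k in seq_along(effects)) {
      e <- effects[[k]]; tips <- clades[[k]]; x <- xvals[[k]][s]
      if (e$mode == "abundance") {
        a[tips] <- a[tips] * exp(e$magnitude * x)
      } else {
        pOcc <- plogis(logit0 + e$magnitude * x)
        if (rbinom(1, 1, pOcc) == 0) a[tips] <- a[tips] * 1e-9
      }
    }
    g <- rgamma(nOtu, shape = a, rate = 1)
    tot <- sum(g)
    p <- if (tot > 0) g / tot else rep(1 / nOtu, nOtu)
    m[s, ] <- rmultinom(1, size = depths[s], prob = p)
  }
  keep <- rowSums(m) > 0
  CountTable(m[keep, , drop = FALSE])
}

#' Simulate a null distance matrix
#'
#' Euclidean distances between i.i.d. standard-normal points (default
#' 10 dimensions): a distance matrix carrying no covariate signal, for
#' type-I-error calibration of distance-based tests.
#'
#' @param n number of samples (>= 3).
#' @param seed integer seed.
#' @param dim latent dimension.
#' @return a [DistanceMatrix-class].
#' @export
simulateNullDistance <- function(n, seed = 1L, dim = 10) {
  if (n < 3) stop("n must be >= 3")
  set.seed(.substream(seed, "null-distance"))
  pts <- matrix(rnorm(n * dim), n, dim,
                dimnames = list(sprintf("S%04d", seq_len(n)), NULL))
  DistanceMatrix(as.matrix(stats::dist(pts)))
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: tree, metadata, taxonomy and counts from one
#' configuration.
#'
#' @param config a [SimConfig-class].
#' @return list with `tree`, `meta`, `taxonomy`, `table`.
#' @export
simulateCohort <- function(config) {
  tree <- simulateTree(config@nOtus, seed = config@seed)
  meta <- simulateMetadata(config)
  taxonomy <- simulateTaxonomy(config@nOtus, seed = config@seed)
  table <- simulateCounts(config, meta, tree)
  meta <- SampleMetadata(sampleData(meta)[sampleIDs(table), , drop = FALSE])
  list(tree = tree, meta = meta, taxonomy = taxonomy, table = table)
}
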