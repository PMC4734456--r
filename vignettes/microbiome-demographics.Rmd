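---
title: "Quantifying demographic effects on gut microbiota diversity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying demographic effects on gut microbiota diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdemog)
```

## The problem

Demographic and health-behavior covariates — age, sex, race, body mass
index, alcohol and tobacco use — are associated with the composition of
the human gut microbiota, but their effects are small: typically well
under 1% of overall between-subject community variability. At that
scale they are easy to miss, easy to confound with technical batch
effects, and still large enough to distort case-control biomarker
studies when the groups differ demographically. `microdemog`
implements a complete, testable pipeline for measuring such effects in
16S rRNA OTU tables: coverage-standardized alpha diversity,
UniFrac-based beta diversity, batch-adjusted association tests with
distance-based effect sizes, taxon-level signature screens, and a
synthetic cohort generator so every stage can be validated against
known ground truth.

## The association model

Every test in the package uses one model form per covariate X:

```
outcome ~ Batch + X + X:Batch
```

Batch is the sequencing batch (a nuisance covariate), and the X:Batch
interaction allows the association strength to differ between batches.
The hypothesis tested is always the *joint* null — no main effect and
no interaction — which is equivalent to "no association in either
batch". Continuous covariates (age, BMI) enter as single columns;
categorical covariates are reference-coded. The covariate degrees of
freedom `p` equal `rank(full) - rank(reduced)`; aliased columns
(e.g. a covariate constant within each batch) are dropped with a
report. Samples missing the covariate or batch value are dropped for
that test only (complete-case per analysis).

### Alpha diversity: likelihood-ratio tests

Coverage-standardized richness and Shannon diversity are approximately
normal across subjects, so `alphaLRT()` fits both models by ordinary
least squares and uses the large-sample likelihood-ratio statistic
`n * ln(RSS_reduced / RSS_full)` against a chi-square with `p` degrees
of freedom. (The chi-square flavor was chosen over a permutation F
here because the outcome is a single well-behaved scalar; an exact
zero-residual fit is flagged instead of producing an infinite
statistic.)

### Beta diversity: joint PERMANOVA and distance-based R²

For a distance matrix `D`, let `A = (-d_ij^2 / 2)` and
`G = (I - 11'/n) A (I - 11'/n)` (the Gower-centered matrix; its trace
is the total dispersion). With `H_r`, `H_f` the projections onto the
reduced and full design column spaces:

* `SS_joint = tr(H_f G H_f) - tr(H_r G H_r)`
* `SS_res  = tr((I - H_f) G (I - H_f))`
* `pseudo-F = (SS_joint / p) / (SS_res / (n - rank(full)))`

When `D` is the Euclidean distance of a scalar response this reduces
exactly to the classical joint ANOVA F — the package's tests verify
that identity to 1e-8.

Significance comes from permutations (default 1,000) of the
covariate's sample rows. Two conventions matter:

* **Add-one p-values**: `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`,
  so p is never zero, and ties count as exceedances (conservative).
* **Restricted permutations**: by default rows are shuffled *within*
  batch strata, preserving the batch structure under the null. The
  widely used unrestricted shuffle is available via
  `designSpec(..., strata = FALSE)`; this is a deliberate divergence
  from the common default, documented here, because the model treats
  batch as a fixed nuisance.

Effect size is the distance-based coefficient of determination
`R2 = tr(HGH) / tr(G)`. One R² is reported per covariate; the package
defines it **sequentially** (batch first): `SS_joint / tr(G)`, so
batch variance is never credited to the covariate. A marginal
(batch-ignored) version is available via `distanceR2(..., scope =
"marginal")` for sensitivity analysis. The small-sample adjustment is

```
R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)
```

which may be negative; it is floored at zero only in written reports,
never internally (a saturated design with R² exactly 1 returns
`R2_adj = 1`, the formula's limit).

## Alpha diversity in detail

Comparing richness at a common *depth* still biases comparisons when
samples differ in completeness; the package therefore standardizes at
a common estimated *coverage* (the Good-Turing fraction of the
community's individuals belonging to already-observed species):

* Coverage of the full sample:
  `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`, where `f_k` is
  the number of OTUs seen exactly `k` times.
* The target is the *minimum* coverage over samples
  (`pickTargetCoverage()`), so every sample can reach it mostly by
  interpolation.
* For each sample, `standardizeAtCoverage()` finds the smallest
  integer size `m*` whose estimated coverage reaches the target
  (coverage is non-decreasing in `m`, so a bisection search suffices)
  and evaluates richness and Shannon diversity at `m*`.

Interpolated richness is the exact hypergeometric expectation
`S(m) = S_obs - sum_i C(n - x_i, m) / C(n, m)`; interpolated Shannon
is the exact expectation `sum_i E[-(X_i/m) ln(X_i/m)]` with
`X_i ~ Hypergeometric(n, x_i, m)`. Both are verified against
exhaustive enumeration of all subsamples at small depth. All binomial
coefficient ratios are evaluated in log space (`lchoose`), so depths
of several hundred thousand reads do not overflow.

**Extrapolation** (needed only when the target exceeds a sample's
full-depth coverage) uses the Chao1-based form for richness, and for
Shannon a depth-weighted blend of the observed entropy and the
Chao-Shih-Jost asymptotic entropy estimator — a pragmatic choice the
package makes for the rarely-exercised `m > n` branch. Extrapolation
is capped at `m* = 2n` (reliability degrades beyond that); an
unreachable target returns a flagged result at the cap. Whether
Shannon should be coverage-standardized at all is genuinely open; the
package computes both and reports the standardized value by default,
with the raw value alongside.

**Singleton correction.** Sequencing errors inflate the observed
singleton count `f1`, and with it richness and coverage estimates.
`correctSingletons()` replaces `f1` with a closed-form estimate
obtained by least-squares log-linear extrapolation of `ln(k * f_k)`
over the reliable counts `k = 2, 3, 4` back to `k = 1` (with only
`f2`, `f3` positive this reduces to `4 f2^2 / (3 f3)`). The estimate
is capped at the observed `f1` — the correction removes spurious
singletons, never invents them — and falls back to the observed count
when fewer than two of `f2, f3, f4` are positive. The correction is
isolated behind one function and a `corrected = FALSE` /
`--no-singleton-correction` switch so its influence can always be
examined.

## Beta diversity in detail

Two phylogeny-aware distances are implemented directly on the tree's
edge set (with per-edge community mass accumulated through a sparse
tip-by-edge incidence matrix):

* **Unweighted UniFrac** — fraction of branch length leading
  exclusively to tips present in only one community; pure
  membership, invariant to count rescaling, most sensitive to rare
  lineages.
* **Weighted UniFrac (normalized)** —
  `sum(b_e |pA_e - pB_e|) / sum(b_e (pA_e + pB_e))` with `pX_e` the
  fraction of community X's reads under edge `e`; bounded in [0, 1]
  like a distance, which is why the normalized form is the default
  (`raw = TRUE` gives the unnormalized sum).

Conventions: the edge above the root contributes to neither community;
tree tips absent from the count table are pruned (they carry no branch
mass); OTUs absent from the tree are an error unless explicitly pruned
(`pruneMissing = TRUE`) — silent dropping would change the metric.
Both metrics are tested to 1e-12 against a brute-force implementation
that classifies edges by explicit tip-path enumeration, and against
independent implementations in other packages.

**Rarefaction before UniFrac** uses a single seeded draw per sample at
a common depth (default: the minimum sample depth; the number of
rarefaction draws and the depth are not uniquely determined choices,
and a single draw keeps the pipeline deterministic). Each sample's
subsample is drawn from a substream keyed by the master seed and a
hash of the sample's count vector, so identical count rows subsample
identically — duplicated samples stay at distance zero — while
results remain reproducible sample-by-sample.

PCoA is the eigendecomposition of `G`; axes are eigenvectors scaled by
the square root of their eigenvalues, negative eigenvalues are dropped
with a diagnostic (UniFrac matrices are generally non-Euclidean), and
explained fractions are relative to the positive-eigenvalue total.

## Taxon-level signatures

OTUs are aggregated to phylum / family / genus with lineage-prefixed
labels (`"Firmicutes; Blautia"`); unmapped or blank ranks aggregate to
`"<phylum>; unclassified"`. To limit the test family, taxa are kept
only when prevalence exceeds 10% *and* the median nonzero proportion
exceeds 0.05% (both strict). Each remaining taxon's proportions are
square-root transformed (a variance stabilizer for proportions) and
tested with the same joint batch-adjusted F-statistic, with
permutation p-values as above. FDR is controlled by Benjamini-Hochberg
within each rank-by-covariate family (whether the published analyses
pooled ranks is not stated; within-rank families are the conservative
reading and are what `signatureReport()` uses). Reports list taxa with
q below 10% with raw (untransformed) group mean proportions and
`log2(mean_exposed / mean_reference)`; BMI is tested as continuous but
displayed by normal/obese groups split at 30 kg/m², and a zero group
mean yields a flagged undefined fold change rather than a
pseudo-count. Age is excluded from the default taxon screen (it shows
no overall association signal) but can be added explicitly.

A practical note on permutation resolution: with `m` taxa and `B`
permutations the smallest attainable BH q-value is `m / (B + 1)`, so
a 50-taxon family needs `B` of at least roughly 500 for anything to
clear a 10% threshold. The package default is `B = 1000`; the
validation simulations use 200-500 where the quantity being checked
(a rejection rate or an ordering) does not require finer resolution.

## The synthetic cohort generator

There is no public generative model for these cohorts, so the package
defines one — a Dirichlet-multinomial, the standard choice for 16S
count overdispersion — and treats it as a first-class, tested module:

* **Base composition**: log-normal Dirichlet concentrations
  (`alphaSdlog = 1.6`), scaled to a total mass of 150. These two
  values were calibrated once against the published cohort profile —
  median OTU prevalence about 11%, roughly 400 observed OTUs per
  subject, about 3.5% of OTUs present in more than 95% of samples —
  and then frozen.
* **Cohort structure**: 118 subjects, 1,745 OTUs, two batches
  assigned in contiguous index blocks, sequencing depth log-uniform
  between 30,000 and 390,000 reads.
* **Covariate marginals**: age uniform over 20-79; sex, race, alcohol
  and tobacco drawn with age-stratum marginals matching the published
  cohort table (about 51% female, 84-90% white, 65-71% alcohol users,
  13-16% smokers); BMI normal within stratum with about 25% / 33%
  above 30 kg/m².
* **Planted effects**: each effect targets a designated rare clade
  (tips below an internal node, chosen rarest-first and disjoint
  across effects, about 5% of tips). *Presence-mode* effects multiply
  the odds that the clade is occupied at all
  (baseline occupancy 0.25) by `exp(magnitude * x)` — a membership
  signal that unweighted UniFrac should dominate, mirroring the
  rare-biosphere interpretation of the cohort findings.
  *Abundance-mode* effects tilt the clade's concentrations by
  `exp(magnitude * x)`. Magnitude zero is exactly null (samples
  exchangeable). The default configuration plants small presence
  effects (race, BMI, alcohol, sex, tobacco in decreasing magnitude,
  none for age) that land well under 1% of adjusted distance-based
  R² — the regime the pipeline is meant to resolve.
* **Batch effect**: a random 20% of OTUs get a ±0.4 log-concentration
  tilt in the second batch.
* **Seeding**: one master seed; every stochastic stage (tree,
  metadata, taxonomy, concentrations, clade choice, depths, counts,
  rarefaction, permutations) consumes a named substream derived from
  it, so stages re-run independently and reproducibly.

What the generator deliberately does **not** emulate: sequencing
error, chimeras and primer bias (so the singleton correction is
exercised only arithmetically, not against a realistic error process);
taxonomy is simulated independently of the tree (signature tests are
validated with their own planted-taxon constructions); batch is
assigned by index blocks independent of age, so the batch-age
entanglement seen in real two-round recruitment is absent. Passing
tests therefore demonstrate the statistical machinery's correctness
and calibration, not robustness to those real-data pathologies.

## Numerical and design choices

* Permutation F ties are counted with a 1e-12 slack, as exceedances.
* Eigenvalues within `1e-9 * max|eigenvalue|` of zero are treated as
  zero in PCoA.
* Continuous covariates are not standardized (projections are
  scale-invariant).
* Distance-matrix construction symmetrizes and zeroes the diagonal to
  absorb floating-point asymmetries, and validates everything else.
* Reports round as conventionally printed (percentages to 1 decimal
  half-up, R² as percentages to 2 decimals, fold changes at full
  precision in TSVs); full-precision values are always what is
  written to the machine-readable columns.
* Problem sizes in the validation suite are the package's own
  choices: UniFrac oracles on 50 random trees of up to 8 tips;
  PERMANOVA calibration on 500 signal-free replicates of 50 samples
  at 200 permutations; effect-size recovery and the
  unweighted-dominance check on 60-subject, 150-OTU cohorts at
  depths of 2,000-4,000 reads (20 replicates per condition); the
  all-null FDR screen on 200 replicates of 50 taxa. These sizes give
  Monte-Carlo error comfortably inside the asserted bands while
  keeping the whole suite runnable in minutes.

## Known limitations

* The distance-based R² decomposition is sequential; with strongly
  unbalanced batch-covariate confounding the sequential and marginal
  versions diverge, and neither recovers a causal effect size.
* The chi-square LRT for alpha diversity is a large-sample
  approximation; at very small n a permutation version would be
  preferable.
* Shannon extrapolation beyond the observed depth is a blended
  estimate without finite-sample guarantees; it is flagged whenever
  used.
* Unweighted UniFrac after rarefaction still depends on the rarefied
  depth; cross-study comparability requires a shared depth policy.
* The cohort-scale published numbers (specific p-values and R²
  percentages) depend on the original sequence data and are not
  reproducible from synthetic cohorts; the package instead validates
  every computational claim behind them.
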