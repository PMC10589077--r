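---
title: "Methods and design of the crossdeg pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the crossdeg pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crossdeg` asks a comparative question: does the set of genes
differentially expressed in a focal species' plastic contrast overlap
its orthologs' differential expression in a second species more than
chance would produce? This vignette documents the statistical model
behind each stage, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the design
choices made where more than one reasonable convention exists.

## Abundance units and the expression filter

Counts enter at the gene level (an optional transcript-to-gene
aggregation step, `aggregate_transcripts()`, sums transcript counts via
a two-column map). `compute_tpm()` converts counts to transcripts per
million using per-gene effective lengths: per sample, the
length-normalized rate $c_g / \ell_g$ rescaled to sum to $10^6$.
`filter_low_expression()` excludes genes below 1 TPM; the retained set
is the species' *expression-filtered universe*, which later serves as
the sampling frame of the permutation test, so the filter choice
propagates into the null distribution.

The filter's aggregation rule is genuinely underdetermined: "below
1 TPM" can be read per sample or in aggregate. The default averages
TPM across samples — the least aggressive common reading, and the one
whose universe size most plausibly matches a pipeline that filters a
combined abundance table. `all-samples` and `any-sample` rules are
selectable. A gene at exactly the threshold is retained (the exclusion
is strictly "less than").

`log2_cpm()` uses a prior count of 2 scaled proportionally to library
size (the convention of the major DE toolkits; verified against
`edgeR::cpm(log = TRUE)` to 1e-8 in the tests), so zeros stay finite
and equal count profiles give equal columns at any depth.
`mds_coordinates()` performs classical (Torgerson) metric MDS on
Euclidean sample distances over the 500 most variable genes of the
log2-CPM matrix. This deviates from the leading-logFC pairwise distance
some toolkits plot: classical MDS is deterministic, has an exact
eigendecomposition, and reconstructs planar configurations to 1e-8,
which makes it both an adequate QC ordination and a testable one.

## The differential expression test

Normalization is trimmed-mean-of-M-values: reference sample = the one
whose 75th-percentile count fraction is closest to the mean of those;
log2 ratios against the reference are trimmed 30% at each end jointly
with a 5% trim on average log abundance, then averaged with inverse
asymptotic-variance weights; factors are rescaled to geometric mean 1.
The implementation matches `edgeR::calcNormFactors(method = "TMM")` to
1e-6 on random data.

Each gene is modeled as negative binomial with log link:
$\log \mu = \beta_0 + \beta_c x_c + \text{block} + \log(\text{effective
library size})$, fit by iteratively reweighted least squares with a
ridge of 1e-8 on the normal equations (guards separable patterns) and
step halving whenever a step increases the deviance; convergence is a
relative deviance change below 1e-8 within 50 iterations, and
non-convergent genes are reported untested rather than given a
fabricated p-value. Significance is a likelihood-ratio test of the
condition coefficient against $\chi^2_1$, two-sided by construction;
direction comes from the coefficient sign; `logFC` is the coefficient
divided by $\log 2$, oriented `condition_b` over `condition_a`. BH
adjustment is applied per contrast over tested genes only; genes with
no counts in the contrast's samples, or outside the supplied universe,
are excluded from the family.

This is a deliberately self-contained specification rather than a
wrapper around an existing toolkit: every step is stated exactly and
reimplementable, and the acceptance standard is *calibration* (type-I
error and power on data with known truth), not numerical identity with
any package. The tests nevertheless cross-check logFC and p-value
rankings against an independent NB-GLM implementation (correlations
above 0.98 and 0.9 respectively on simulated data).

### Dispersion estimation

Per-gene dispersions use method-of-moments estimates
$(\hat v - \hat m)/\hat m^2$ on counts scaled to a common effective
library size, pooled across design cells (condition, or condition ×
block) with degree-of-freedom weights, floored at 1e-6, and shrunk
toward a common dispersion with weight
$\text{prior\_df}/(\text{prior\_df} + \text{residual df})$
(prior_df = 10 by default). For the common value, the obvious
summary — the median of the per-gene moment estimates — is badly
biased downward when cells contribute only one or two residual degrees
of freedom: the estimates are heavily right-skewed, their median sits
well below their mean, and plugging that median in inflates the null
type-I error of the LRT (measured: common 0.11 against a true 0.17,
giving a 10.5% rejection rate at nominal 5%). The common dispersion is
therefore estimated by maximizing the NB log-likelihood conditional on
each cell's total count, pooled over all genes — for equal-size NB
observations the total is sufficient for the cell mean, so this
profile is free of the fitted means and does not pay their degrees of
freedom. With it, the global-null rejection rate at p < 0.05 is 0.054
(10,000 null genes pooled over five simulations), and the estimator
recovers a true common dispersion of 0.4 to within 0.02.

## Ortholog mapping

`build_rbh_map()` pairs genes across species by reciprocal best hit
from two 12-column tabular alignment files (the conventional tab
format of nucleotide aligners). Records with e-value above 1e-5 are
dropped — the threshold the motivating analyses used for their other
sequence searches, configurable since the RBH step itself states none.
Multiple HSPs of a query-subject pair collapse to the single best HSP
before best-hit selection (no HSP summing), and ties break
deterministically: higher bitscore, then lower e-value, then higher
percent identity, then lexicographically smallest subject id. A pair
is kept iff each member is the other's best hit, which makes the map
one-to-one by construction; tests verify injectivity, symmetry under
swapping the species' roles, and agreement with a comparison-sort
oracle on random tables. Alignment execution is out of scope — the
module consumes precomputed hit tables at whatever identifier level
the analysis uses; inputs must already be at that level.

## The overlap statistic

With expression-filtered universes of sizes $N_A, N_B$, DEG sets of
sizes $n_A, n_B$ and $M$ mapped pairs inside the universes, the
observed statistic is the number $k$ of mapped pairs DE in both
species. The null draws $n_A$ genes from universe A and $n_B$ from
universe B uniformly without replacement, independently per species,
and recounts; the draws deliberately ignore the ortholog map (a
map-restricted variant exists behind a flag but is not the default,
since the reference scheme samples from the full filtered catalogs).
The test is one-sided (greater), and
$p = \#\{\text{perm} \ge k\}/N_\text{perm}$ — the counting rule of the
motivating analyses. Because that rule can return exactly 0, the
add-one estimator $(\#+1)/(N+1)$ is reported alongside; fidelity
first, statistical hygiene second.

Linearity over mapped pairs gives the exact mean
$E[k] = M \frac{n_A}{N_A}\frac{n_B}{N_B}$, and because the map is
injective, distinct pairs share no genes, so the exact variance
follows from the pairwise hypergeometric inclusion probabilities
$\frac{n(n-1)}{N(N-1)}$ per species. These closed forms are a
cross-check oracle, not the test itself: tests verify them against
exhaustive enumeration of all draw combinations on instances up to 12
genes (1e-9), and the permutation machinery against both the
enumeration (total variation below 0.01 at $10^5$ draws) and the
closed-form mean (within 4 standard errors).

Each focal DEG falls in exactly one class: *shared* (ortholog DE in
the reference), *not significant* (ortholog tested but not DE),
*unaligned* (no ortholog in the map), or *mapped-but-untested*
(ortholog filtered out in the reference species). The fourth class is
kept explicit rather than folded into "not significant" so the classes
partition the DEG set exactly — a property tested on 1000 random
instances.

Fold-change concordance of shared pairs is tabulated under a
*declared* correspondence of condition orientations across species
(`orientation = c(1, 1)` means each contrast's second condition
corresponds). The correspondence is never inferred from data: which
reference timepoint "matches" a focal morph is a biological claim the
pipeline has no basis to make, so it reports raw higher-expression
sides and flips flags only as told.

## Over-representation analysis

`ora_test()` is a self-contained hypergeometric upper-tail test of a
query list against GMT gene sets restricted to a background, with BH
across sets reaching a minimum overlap (default 2). It stands in for
web-service enrichment tools whose proprietary multiple-testing
corrections and live annotation databases are not reproducible
offline; enriched-term lists from those services are not expected to
match term-for-term. The background defaults to the supplied
expression-filtered universe, with the option of an external
proteome-style background. Correctness is tested against exhaustive
enumeration of draws (1e-10) and a hand-evaluated tail
(76/15504 on a 20-gene background).

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not raw sequencing: NB counts with mean = library-size factor
× baseline × $2^{\text{logFC} \cdot \text{indicator}}$ × block effect
and dispersion $\phi(\mu) = \phi_0 + a/\mu$; a focal species with two
morphs across family blocks; a reference species with a shared control
and treatment timepoints; hit tables encoding the true ortholog map as
mutual best hits plus decoys; and exact truth tables. Key defaults and
their reasoning:

* `frac_shared_orthologs = 0.562` — the shared fraction of the joint
  ortholog catalog reported for the motivating species pair.
* `frac_de_a = 0.35` — roughly one-third of tested genes were
  morph-biased in the focal species; `frac_de_b_per_timepoint = 0.02`
  emulates the order-of-magnitude-smaller per-timepoint DEG counts in
  the reference species.
* `rho_shared = 0` — the fraction of DE ortholog pairs forced DE in
  both species; the default reflects the motivating finding of no
  excess sharing. Forced pairs are concordant in direction with
  probability 0.5 (both concordant and discordant shared pairs occur
  empirically), and are DE at every timepoint, which keeps the truth
  tables simple and the forced count exact. DE assignment in the focal
  species is stratified over paired and unpaired genes so the realized
  shared-pair count is exactly `round(rho_shared × frac_de_a × pairs)`.
* `logfc_range = (0.8, 3)` — spanning the magnitude range of the
  published shared-DEG table.
* `baseline_logmean_params = (4, 1)` (log-normal, natural log; median
  ≈ 55 counts) and `dispersion_params = (0.16, 0.5)` (biological CV
  ≈ 0.4 at high abundance, rising at low counts) — typical of bulk
  RNA-seq on outbred, field-derived animals.
* `libsize_cv = 0.2`, `block_sigma = 0.1` — moderate depth variation
  and a small multiplicative per-(gene, family) effect, enough that a
  model omitting the block covariate is distinguishable from one
  including it.
* `frac_low_expression = 0.1` — genes scaled ×0.001, far below the
  1 TPM filter, to exercise the universe construction.
* Decoy alignments (0–2 per gene) always target *paired* genes of the
  other species with strictly lower bitscores, so they exercise
  best-hit selection without ever creating spurious reciprocal pairs;
  `inject_ties = TRUE` instead gives decoys exact bitscore and e-value
  ties with strictly lower identity, exercising the full tie-break
  cascade while keeping recovery exact.
* One RNG stream per dataset, seeded from the config; identical
  configs reproduce byte-identical bundles.

What it does not emulate: read-level artifacts (assembly chimeras, 3'
bias, multi-mapping), isoform structure, GC or length biases in
counting, correlated gene modules, or annotation error beyond decoy
hits. Passing tests therefore demonstrate that the inference chain is
correct and calibrated under its own model assumptions — not that
those assumptions hold for any particular real dataset.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen to keep
Monte Carlo error well inside the asserted bands: DE calibration uses
2,000 genes × 5 seeds (10,000 null p-values pooled); overlap
calibration uses 10,000-gene universes, 5,000 mapped pairs, 500 DEGs
per species, 1,000 permutations × 50 replicates; enumeration oracles
run on instances up to 12 genes. Headline dataset-scale numbers from
the motivating study depend on SRA-scale raw reads and a stochastic de
novo assembly and are not reproduced here; the packaged shared-DEG
table is the one dataset-scale artifact carried verbatim, guarded by a
checksum.

Numerical conventions worth knowing: TPM columns of an all-zero sample
are all zero rather than an error; a gene at exactly the filter
threshold is retained; `q_threshold = 1` saturates the DEG set to all
tested genes (BH q-values reach exactly 1, so a strict inequality
would silently exclude them); empty hit tables and empty queries warn
and return empty results; permutation and simulation seeds below
2^31 − 1.

## Known limitations

* The DE test uses a plug-in shrunk dispersion in a $\chi^2_1$ LRT; at
  two or three replicates per cell its type-I error is calibrated by
  construction checks, not by exact small-sample theory.
* RBH produces strictly one-to-one maps; genuine many-to-many ortholog
  groups are represented by at most one pair, and the rest count as
  "unaligned" in the classification.
* The permutation null treats genes as exchangeable within a universe;
  expression-level-matched or GC-matched nulls are out of scope.
* Enrichment ignores ontology topology (no DAG propagation, no
  pathway structure).
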