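---
title: "Methods: simulating epistasis and scoring SNP pairs on data subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating epistasis and scoring SNP pairs on data subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipair)
```

`epipair` exists to answer one methodological question: when ranking SNP
pairs by an interaction score, does *replication-groups scoring* — split
the samples into `r` disjoint class-balanced subsets, score each pair on
every subset, rank by the minimum — admit fewer false positives than
scoring the whole data set directly? This vignette documents the models,
the estimators, the generator, and every numerical choice a maintainer
might want to revisit.

## The disease models

A two-locus penetrance model is a 3×3 table `f(gA, gB)` of disease
probabilities over the genotypes of two biallelic SNPs (rows AA/Aa/aa,
columns BB/Bb/bb; the package encodes genotypes 0 = homozygous major,
1 = heterozygous, 2 = homozygous minor, fixed repo-wide). All six
simulation models are *pure* epistasis models: the HWE-weighted penetrance
is constant along every row and column, so neither locus is marginally
associated with disease and the entire signal lives in the pair.

Models 1 and 2 are the classical tables at allele frequencies
`p = q = 0.5`: the XOR table (penetrance 0.10 when exactly one locus is
heterozygous, prevalence 0.05) and the "ZZ" table (0.10 on the AAbb/aaBB
corners, 0.05 on AaBb, prevalence 0.025). Models 3–6 extend the family to
minor allele frequencies 0.25 and 0.1 by a rank-one construction: with `g`
a contrast vector orthogonal to the HWE genotype weights, any table
`f = K + d·g gᵀ` has zero marginal effect at both loci and prevalence
exactly `K`. We fix `K = 0.10` and choose `d` so that one cell class is
exactly 0, alternating a centre-zero (XOR-like) and an edge-zero shape.
Purity is load-bearing, not cosmetic: with marginally-associated models,
*cross-pairs* — one SNP from each of two different embedded pairs —
inherit an association through the marginals, and these labelled-false
pairs dominate the top of the ranking, turning the evaluation into a
measurement of an artifact. The test suite asserts row/column constancy
for all six tables.

```{r}
epistasis_model(1)
```

The HFCC-like score uses a separate, deliberately crude model family: the
nine single-high-risk-cell partitions of the 3×3 table, enumerated
row-major over (gA, gB) so orderings are reproducible.

## The generator

`simulate_dataset()` produces exactly `n_cases` cases and `n_controls`
controls (defaults 200/200). Presets: `syn1` = 100 SNPs with 24 embedded
pairs (four per model), `syn2` = 500 SNPs with 60 (ten per model);
embedded pairs occupy the lowest column indices in model order, making
truth manifests human-checkable. Each SNP belongs to at most one pair.

Genotypes at an embedded pair are drawn from the exact case- or
control-conditional two-locus distribution — the HWE prior times `f`
(cases) or `1 − f` (controls), normalised. These are precisely the
distributions that rejection-sampling whole individuals into fixed-size
case/control bins converges to; we sample them in closed form because the
conditional is available exactly and this keeps class totals exact by
construction rather than by loop termination. Because every embedded pair
is conditioned on the same phenotype vector, each pair individually looks
like a single-interaction simulation at full strength — which is what
lets a 24-pair data set exercise 24 detection problems at once.
Background SNPs are phenotype-independent HWE draws with per-SNP minor
allele frequency uniform on [0.05, 0.5] (a realistic spread; the choice
is configurable and the exchangeability of background pairs with the
phenotype is property-tested).

### Noise

Four transforms, applied in the fixed order heterogeneity → phenocopies →
genotyping error → missingness (biological corruption precedes
measurement corruption; the `AN` preset applies all four):

* **mN, missing data** (default rate 0.05): each entry set to `NA`
  independently.
* **gN, genotyping error** (default 0.05): each non-missing entry
  replaced, with the given probability, by one of the other two genotype
  values uniformly.
* **pN, phenocopies** (default 0.5): `floor(rate · n_cases)` cases, drawn
  uniformly, get control-distribution genotypes at *all* embedded pairs —
  their disease is no longer genetic. At rate 1 the true pairs are
  statistically indistinguishable from background (tested over 50
  replicates).
* **hN, genetic heterogeneity** (default 0.5): each model's embedded
  pairs are split into a primary and a secondary half (hence
  `pairs_per_model ≥ 2` is required); the selected fraction of cases is
  attributed to the secondary mechanism (control-distribution genotypes
  at primary pairs, case-conditional at secondary), and the remaining
  cases get control-distribution genotypes at the secondary pairs. The
  last step is what makes the transform heterogeneity — two case
  subpopulations with different causal pairs — rather than merely extra
  signal; a selection that rounds to zero cases is the identity. Both
  halves stay in the truth manifest, so `syn1` keeps exactly 24 true
  pairs under every noise setting.

The default rates follow the common settings of the simulation protocol
this generator emulates; none are printed in the study this package
accompanies, so all are configurable. A single RNG stream seeded from the
preset drives generation; every transform also accepts its own seed when
used standalone.

### Permutation mode

For data whose true interactions are unknown, `permute_half_snps()`
imputes *known false* interactions: `floor(m/2)` uniformly chosen columns
are independently permuted across samples, preserving each column's value
multiset while destroying any association. Pairs containing a permuted SNP
are known false positives; pairs of two unpermuted SNPs have unknown
status and are excluded from false-positive counting (in simulated data
every non-embedded pair is instead labelled false — the two evaluation
settings are never conflated). Any embedded pair hit by permutation is
dropped from the true list. We permute phenotype-unconditionally; family
structure, which some real series have, is not modelled.

## The scores

Both scores are computed from the 3×3×2 contingency table of a pair.
Missing genotypes are handled pairwise-complete (a sample counts only if
non-missing at both SNPs) — the standard choice that maximises usable
data per pair, at the price that different pairs see slightly different
sample sizes.

**Interaction gain** `I(XY;C) − I(X;C) − I(Y;C)`, with the 9-valued joint
genotype `XY`: plug-in (maximum-likelihood) probabilities, no smoothing,
base-2 logarithms, `0·log 0 = 0`. It is symmetric in X and Y, bounded by
1 bit in absolute value for a binary phenotype, and negative for
redundant pairs. The implementation is a vectorised indicator-matrix
cross-product over all pairs; the test suite checks it against a naive
three-term entropy oracle on 1000 random small tables to 1e−12 and
against the per-pair path under missingness.

**HFCC-like score**: per risk model, collapse the nine cells into
high/low risk, form the 2×2 risk-by-phenotype table, take the Pearson χ²
when the high-risk cell is case-enriched and 0 otherwise, and return the
maximum over the nine models. The exact fit statistic of the original
HFCC binary is not public; this score mirrors the described mechanism
(best-fitting simple disease model, one high-risk combination each) and
is documented as HFCC-like, not a bit-exact reimplementation. Degenerate
collapses (an empty margin) contribute 0, avoiding division by zero. The
statistic is not normalised by subset size; within one aggregation all
subsets have (near-)equal `n`, and since min-aggregation is invariant to
per-subset monotone transforms, a normalisation would not change any
ranking this package produces.

## Aggregation

`subset_plan()` implements three strategies. Replication groups: each
class's indices are shuffled and dealt round-robin into `r` groups, with
the dealing position carried over between classes — per-class *and*
total subset sizes then differ by at most one (200/200 samples at `r = 3`
give sizes 134/133/133). Bootstrap resamples are drawn within class so
every subset keeps exact class totals; an unstratified draw could produce
a single-class subset, which is an error condition for scoring. Direct is
the trivial one-subset plan. `aggregate_scores()` computes each subset's
scores independently (no cross-subset caching — auditability over speed
at this scale) and returns the per-pair minimum; thresholding the
min-aggregated list is provably the same as demanding the threshold in
every subset, and the suite checks that equivalence by brute force.

## Evaluation

Rankings are sorted by descending score with lexicographic `(i, j)`
tie-breaks, so false-positive counts are deterministic. The FP curve
reports, for each `k`, the number of labelled-false pairs among the top
`k`; envelopes are `best(k) = max(0, k − n_true)` and
`worst(k) = min(k, n_false)`. The `k` grid is every integer when the pair
universe has at most 10⁴ pairs (all of `syn1`), otherwise a log-spaced
grid of at most 512 points (`syn2`). Curves average pointwise across
replicates; performance plots are log-log with zero counts clipped to 0.5
for the log scale, envelopes in gray.

`run_experiment()` composes the pipeline — simulate, optionally permute,
plan, aggregate per strategy, label, curve — with one derived seed per
replicate (`(seed·1000 + rep) mod (2³¹ − 1)`), sharing each subset's
cross-tabulation between scoring methods. Replicate defaults follow the
study design: 100 repetitions for simulated presets, 50 for
permutation-mode runs.

## Problem sizes and test design

The acceptance-level comparison runs `syn1` (4950 pairs) at 100
repetitions for both scores, noise-free and under `AN`, with direct, rg2
and rg3 — a few minutes on one CPU. Property tests that need many
replicates (background exchangeability, phenocopy saturation,
heterogeneity saturation) use reduced custom presets (one or two pairs
per model, 14–30 SNPs, 100–200 samples) so that 30–100 replicates stay
cheap while exercising the same code paths. Statistical properties are
asserted at fixed seeds with wide test levels (e.g. t-test p > 0.001 for
"no difference" claims) to keep them meaningful but stable.

## What the generator does and does not emulate

It emulates: exact case/control totals, multiple simultaneous pure
interactions, Hardy-Weinberg background, the four classical noise types,
and permutation-imputed false interactions. It does not emulate linkage
disequilibrium (SNP columns are independent), family or pedigree
structure, covariates, genotype-calling artifacts beyond uniform error,
or continuous phenotypes. Conclusions from passing tests therefore speak
to the sampling behaviour of min-over-subsets aggregation under clean
independence assumptions, not to cohort-specific structure in real
arrays. Splits are stratified by phenotype alone (the only class
information the procedure defines); bootstrap aggregation reuses the same
min rule with a configurable number of resamples (default 3).

## Known limitations

* The HFCC-like score is a reconstruction of a described mechanism, not
  of an undisclosed statistic; absolute values are not comparable to the
  original program's output, though rankings behave analogously.
* Figure-level penetrance values beyond model 1 are not published in the
  accompanying text; models 3–6 are this package's own pure-epistasis
  family at the stated allele frequencies, chosen once and fixed.
* Pairs with an empty pairwise-complete table (possible only at extreme
  missingness) score `NA` and rank last rather than raising an error
  mid-scan.
* `choose(m, 2)` score matrices are dense in memory: fine to a few
  thousand SNPs, not intended for array-scale scans.
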