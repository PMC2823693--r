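# epipair

Case-control studies of complex diseases look for *epistasis*: pairs of
SNPs whose combined genotype predicts disease where neither SNP does on its
own. An exhaustive scan must score every candidate pair — about 5·10¹¹
hypotheses on a million-probe array — from only hundreds of samples, so the
top of any ranked pair list is contaminated with false positives. One
proposed remedy is *replication-groups scoring*: split the samples into
`r` disjoint, class-balanced subsets, score each pair on every subset, and
keep only pairs whose **minimum** score across subsets clears a threshold,
on the intuition that spurious pairs will not replicate in every subset.

`epipair` is a compact apparatus for putting that intuition to the test. It
provides, in one package:

* a **two-locus epistasis simulator** — six pure-epistasis penetrance
  models (3×3 tables of disease probability over the genotypes of two
  biallelic loci, constructed so neither locus has a marginal effect),
  presets with 100 SNPs / 24 embedded interacting pairs (`syn1`) and
  500 SNPs / 60 pairs (`syn2`), 200 cases + 200 controls, and four noise
  types: missing data (mN), genotyping error (gN), phenocopies (pN) and
  genetic heterogeneity (hN);
* two **pairwise interaction scores** computed for all `choose(m, 2)`
  pairs: the information-theoretic *interaction gain*

  `IG(X, Y; C) = I(XY; C) − I(X; C) − I(Y; C)`  (bits)

  and an *HFCC-like* score: the best case-enrichment Pearson χ² over nine
  single-high-risk-cell disease models, each collapsing the 3×3 genotype
  table into high-risk vs low-risk;
* three **aggregation strategies** — direct (whole data set),
  replication groups (stratified split, min over `r` subsets) and
  bootstrap (stratified resamples, min) — plus threshold selection;
* **evaluation**: permutation-based imputation of known false interactions
  (permute half the SNP columns; any pair containing a permuted SNP is a
  known false positive), top-k false-positive curves with theoretical
  best/worst envelopes, replicate averaging, and log-log performance
  plots;
* a command-line interface (`simulate`, `score`, `aggregate`, `evaluate`,
  `plot`) via `inst/cli/epipair.R`, with reproducible run manifests.

## Worked example

```r
library(epipair)

d <- simulate_dataset(sim_preset("syn1", seed = 1))
d
#> genotype_dataset: 400 samples (200 cases / 200 controls) x 100 SNPs
#>   missing genotypes: 0.00%
#>   truth: 24 embedded interacting pair(s), 0 permuted SNP(s)

score_pairs(d, "igain")
#> pair_scores: 4950 pairs of 100 SNPs, method = igain
#>    i  j snp_i snp_j     score
#> 1 13 14 snp13 snp14 0.4482306
#> 2  9 10  snp9 snp10 0.4422823
#> 3 15 16 snp15 snp16 0.4390521
#> ...
```

The top-ranked pairs are embedded interactions (the simulator places them
at the lowest SNP indices, paired consecutively: 13–14, 9–10, …); their
scores are the synergy, in bits, the pair carries about the phenotype
beyond the two single-SNP effects. Comparing strategies under heavy noise
(all four noise types at once):

```r
ex <- run_experiment(sim_preset("syn1", noise = noise_preset("AN")),
                     methods = "igain",
                     strategies = c("direct", "rg2", "rg3"),
                     n_reps = 10, seed = 1)
ex
#> epi_experiment: preset syn1 (100 SNPs), simulation mode, 10 replicate(s)
#> mean false positives among the top k pairs:
#>  method strategy fp.10 fp.24 fp.100 fp.1000
#>   igain   direct   8.1  21.3   95.4   988.3
#>   igain      rg2   9.0  22.4   97.2   991.7
#>   igain      rg3   9.7  23.4   97.8   992.7

plot(ex)   # log-log FP curves with best/worst envelopes
```

Each row gives the mean number of false positives among the top `k`
ranked pairs (of 4950; 24 are true). Direct whole-data scoring admits the
fewest false positives at every cutoff, two replication groups come next,
and three groups — scoring on thirds of the data — do worst: min-over-
subsets aggregation pays for its consistency requirement with undersampling.

The same comparison runs from the shell:

```sh
Rscript inst/cli/epipair.R evaluate --preset syn1 --noise AN \
    --method igain --strategies direct,rg2,rg3 --reps 10 --seed 1 --out run1
```

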