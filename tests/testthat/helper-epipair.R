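# Shared fixtures, all built in code.

# Six-sample, two-SNP toy data set with a hand-tallied contingency table.
#   sample: 1  2  3  4  5  6
#   snp1:   0  1  2  0  1  NA
#   snp2:   0  0  1  2  0  1
#   pheno:  1  1  0  0  1  0
toy_dataset <- function() {
  g <- cbind(c(0L, 1L, 2L, 0L, 1L, NA),
             c(0L, 0L, 1L, 2L, 0L, 1L))
  genotype_dataset(g, c(1L, 1L, 0L, 0L, 1L, 0L))
}

# Four samples realising phenotype = XOR(snp1, snp2) on binary genotypes,
# all four configurations equally frequent: 1 full bit of pure synergy.
xor_dataset <- function() {
  g <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  genotype_dataset(g, c(0L, 1L, 1L, 0L))
}

# Small custom preset: one pair per model (12 interacting SNPs) plus
# background SNPs, reduced sample size; fast enough to replicate many times.
small_preset <- function(n_snps = 20L, n_cases = 100L, n_controls = 100L,
                         noise = noise_config(), seed = NULL) {
  sim_preset("custom", n_snps = n_snps, pairs_per_model = 1L,
             n_cases = n_cases, n_controls = n_controls,
             noise = noise, seed = seed)
}

# Independent plug-in mutual information I(V; C) in bits from two aligned
# vectors, by explicit probability loops (test oracle, kept naive).
naive_mi <- function(v, cl) {
  n <- length(v)
  mi <- 0
  for (a in unique(v)) {
    for (b in unique(cl)) {
      pab <- sum(v == a & cl == b) / n
      if (pab > 0) {
        mi <- mi + pab * log2(pab / (sum(v == a) / n * sum(cl == b) / n))
      }
    }
  }
  mi
}

# Independent interaction-gain oracle on a 3 x 3 x 2 count array: builds
# the three mutual-information terms I(XY;C), I(X;C), I(Y;C) cell by cell.
naive_interaction_gain <- function(counts) {
  n <- sum(counts)
  xy <- rep(seq_len(9), times = 2)          # joint genotype label per cell
  x <- rep(rep(1:3, times = 3), times = 2)
  y <- rep(rep(1:3, each = 3), times = 2)
  cl <- rep(1:2, each = 9)
  w <- as.vector(counts)
  expand <- function(lbl) rep(lbl, w)
  v_xy <- expand(xy); v_x <- expand(x); v_y <- expand(y); v_c <- expand(cl)
  naive_mi(v_xy, v_c) - naive_mi(v_x, v_c) - naive_mi(v_y, v_c)
}

# Random 3 x 3 x 2 contingency table with total count at most n_max.
random_pair_table <- function(n_max = 12) {
  n <- sample(seq_len(n_max), 1)
  probs <- stats::runif(18)
  counts <- array(as.vector(stats::rmultinom(1, n, probs / sum(probs))),
                  dim = c(3, 3, 2))
  structure(list(counts = counts, n = n), class = "pair_table")
}
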