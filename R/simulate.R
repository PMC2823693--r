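# Simulation of case-control genotype data with embedded two-locus
# epistasis, the four noise transforms, and the half-SNP permutation that
# imputes known false interactions.

#' Noise configuration
#'
#' The four noise types applied to simulated data sets: missing data (mN),
#' genotyping error (gN), phenocopies (pN) and genetic heterogeneity (hN).
#' All rates are fractions in [0, 1]. \code{noise_preset()} returns the named
#' settings used throughout: \code{"none"} (all zero), a single active noise
#' type at its default rate, or \code{"AN"} (all four at once). Default
#' rates follow the simulation protocol this generator emulates: 5\%
#' missingness, 5\% genotyping error, 50\% phenocopies, 50\% heterogeneity.
#'
#' @param missing_rate probability that any genotype entry is set missing.
#' @param genotyping_error_rate probability that a non-missing entry is
#'   replaced by one of the two other genotype values.
#' @param phenocopy_rate fraction of cases whose disease is made
#'   non-genetic (interacting-pair genotypes resampled from the control
#'   distribution).
#' @param heterogeneity fraction of cases whose disease is attributed to a
#'   secondary epistatic pair instead of the primary one.
#' @return a \code{noise_config} list.
#' @export
noise_config <- function(missing_rate = 0, genotyping_error_rate = 0,
                         phenocopy_rate = 0, heterogeneity = 0) {
  check_rate(missing_rate, "missing_rate")
  check_rate(genotyping_error_rate, "genotyping_error_rate")
  check_rate(phenocopy_rate, "phenocopy_rate")
  check_rate(heterogeneity, "heterogeneity")
  structure(list(missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 phenocopy_rate = phenocopy_rate,
                 heterogeneity = heterogeneity),
            class = "noise_config")
}

#' @rdname noise_config
#' @param name one of \code{"none"}, \code{"mN"}, \code{"gN"}, \code{"pN"},
#'   \code{"hN"}, \code{"AN"}.
#' @export
noise_preset <- function(name = c("none", "mN", "gN", "pN", "hN", "AN")) {
  name <- match.arg(name)
  switch(name,
         none = noise_config(),
         mN = noise_config(missing_rate = 0.05),
         gN = noise_config(genotyping_error_rate = 0.05),
         pN = noise_config(phenocopy_rate = 0.5),
         hN = noise_config(heterogeneity = 0.5),
         AN = noise_config(missing_rate = 0.05, genotyping_error_rate = 0.05,
                           phenocopy_rate = 0.5, heterogeneity = 0.5))
}

#' Simulation presets
#'
#' \code{syn1}: 100 SNPs with 24 embedded interacting pairs (four per
#' epistasis model); \code{syn2}: 500 SNPs with 60 pairs (ten per model).
#' Both comprise 200 cases and 200 controls. \code{custom} lets every field
#' be chosen freely.
#'
#' @param name preset name, \code{"syn1"}, \code{"syn2"} or \code{"custom"}.
#' @param n_snps number of SNP columns (custom only).
#' @param pairs_per_model embedded interacting pairs per epistasis model
#'   (custom only).
#' @param n_cases,n_controls exact class totals.
#' @param noise a \code{noise_config}.
#' @param maf_range range the background SNPs' minor allele frequencies are
#'   drawn from, uniformly per SNP.
#' @param seed RNG seed for [simulate_dataset()]; \code{NULL} uses the
#'   ambient RNG stream.
#' @return a \code{sim_preset} list.
#' @export
sim_preset <- function(name = c("syn1", "syn2", "custom"),
                       n_snps = NULL, pairs_per_model = NULL,
                       n_cases = 200L, n_controls = 200L,
                       noise = noise_config(),
                       maf_range = c(0.05, 0.5),
                       seed = NULL) {
  name <- match.arg(name)
  if (name == "syn1") { n_snps <- 100L; pairs_per_model <- 4L }
  if (name == "syn2") { n_snps <- 500L; pairs_per_model <- 10L }
  if (is.null(n_snps) || is.null(pairs_per_model)) {
    stop_config("custom presets require n_snps and pairs_per_model")
  }
  n_snps <- as.integer(n_snps)
  pairs_per_model <- as.integer(pairs_per_model)
  n_cases <- as.integer(n_cases)
  n_controls <- as.integer(n_controls)
  if (n_cases < 1L || n_controls < 1L) {
    stop_config("n_cases and n_controls must be positive")
  }
  if (n_snps < 2L * 6L * pairs_per_model) {
    stop_config("n_snps must be at least 2 * 6 * pairs_per_model")
  }
  if (!inherits(noise, "noise_config")) stop_config("noise must be a noise_config")
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  structure(list(name = name, n_snps = n_snps,
                 pairs_per_model = pairs_per_model,
                 n_cases = n_cases, n_controls = n_controls,
                 noise = noise, maf_range = maf_range, seed = seed),
            class = "sim_preset")
}

# Case- and control-conditional distributions over the 9 two-locus genotype
# cells of a penetrance model: the HWE prior times penetrance (cases) or
# times one minus penetrance (controls), normalised. These are exactly the
# limiting distributions of rejection-sampling whole individuals into the
# case and control bins, computed in closed form.
pair_cell_dists <- function(model) {
  prior <- outer(hwe_probs(model$p), hwe_probs(model$q))
  case <- prior * model$table
  control <- prior * (1 - model$table)
  list(case = as.vector(case) / sum(case),
       control = as.vector(control) / sum(control))
}

# Sample two-locus genotypes for the given phenotype vector under a model.
# Returns an n x 2 integer matrix (genotype at locus A, at locus B).
sample_pair_genotypes <- function(model, phenotype) {
  d <- pair_cell_dists(model)
  n <- length(phenotype)
  cell <- integer(n)
  is_case <- phenotype == 1L
  if (any(is_case)) {
    cell[is_case] <- sample.int(9L, sum(is_case), replace = TRUE,
                                prob = d$case)
  }
  if (any(!is_case)) {
    cell[!is_case] <- sample.int(9L, sum(!is_case), replace = TRUE,
                                 prob = d$control)
  }
  # cells are column-major over the 3x3 table: row = genotype at A
  cbind((cell - 1L) %% 3L, (cell - 1L) %/% 3L)
}

#' Simulate a case-control data set with embedded epistatic pairs
#'
#' Generates a data set with exactly \code{preset$n_cases} cases and
#' \code{preset$n_controls} controls. Each epistasis model (1..6)
#' contributes \code{pairs_per_model} interacting SNP pairs; the pair
#' columns occupy the lowest SNP indices in model order (pair k uses columns
#' 2k-1 and 2k), followed by the background SNPs. Genotypes at an embedded
#' pair are drawn from the model's case-/control-conditional two-locus
#' distribution (Hardy-Weinberg prior weighted by penetrance), so every
#' embedded pair carries its model's full association with the phenotype;
#' each SNP belongs to at most one pair. Background SNPs are drawn under
#' Hardy-Weinberg proportions, independently of the phenotype, with minor
#' allele frequencies uniform over \code{preset$maf_range}.
#'
#' Noise is then applied in the fixed order heterogeneity, phenocopies,
#' genotyping error, missing data (biological corruption before measurement
#' corruption), all rates taken from \code{preset$noise}. A single RNG
#' stream seeded from \code{preset$seed} drives the whole generation.
#'
#' @param preset a [sim_preset()].
#' @return a [genotype_dataset()] whose truth manifest lists the embedded
#'   pairs and their models.
#' @examples
#' d <- simulate_dataset(sim_preset("syn1", seed = 1))
#' nrow(d$truth$pairs)  # 24
#' @export
simulate_dataset <- function(preset) {
  if (!inherits(preset, "sim_preset")) stop_config("preset must be a sim_preset")
  with_seed(preset$seed, {
    n <- preset$n_cases + preset$n_controls
    m <- preset$n_snps
    phenotype <- c(rep(1L, preset$n_cases), rep(0L, preset$n_controls))
    g <- matrix(NA_integer_, n, m)

    ppm <- preset$pairs_per_model
    n_pairs <- 6L * ppm
    pairs <- cbind(seq(1L, 2L * n_pairs, by = 2L),
                   seq(2L, 2L * n_pairs, by = 2L))
    model_ids <- rep(1:6, each = ppm)
    for (k in seq_len(n_pairs)) {
      gp <- sample_pair_genotypes(epistasis_model(model_ids[k]), phenotype)
      g[, pairs[k, 1]] <- gp[, 1]
      g[, pairs[k, 2]] <- gp[, 2]
    }

    bg <- setdiff(seq_len(m), seq_len(2L * n_pairs))
    if (length(bg)) {
      maf <- stats::runif(length(bg), preset$maf_range[1], preset$maf_range[2])
      for (i in seq_along(bg)) {
        g[, bg[i]] <- sample(0:2, n, replace = TRUE,
                             prob = hwe_probs(1 - maf[i]))
      }
    }

    data <- genotype_dataset(g, phenotype,
                             truth = truth_manifest(pairs, model_ids))
    nz <- preset$noise
    if (nz$heterogeneity > 0) {
      data <- add_heterogeneity(data, nz$heterogeneity)
    }
    if (nz$phenocopy_rate > 0) {
      data <- add_phenocopies(data, nz$phenocopy_rate)
    }
    if (nz$genotyping_error_rate > 0) {
      data <- add_genotyping_error(data, nz$genotyping_error_rate)
    }
    if (nz$missing_rate > 0) {
      data <- add_missing(data, nz$missing_rate)
    }
    data
  })
}

# Resample the genotypes of `rows` at the truth pairs listed in `which_pairs`
# from the chosen conditional distribution ("case" or "control").
resample_pair_rows <- function(data, rows, which_pairs, from) {
  if (!length(rows) || !length(which_pairs)) return(data)
  for (k in which_pairs) {
    d <- pair_cell_dists(epistasis_model(data$truth$model[k]))
    cell <- sample.int(9L, length(rows), replace = TRUE, prob = d[[from]])
    data$genotypes[rows, data$truth$pairs[k, 1]] <- (cell - 1L) %% 3L
    data$genotypes[rows, data$truth$pairs[k, 2]] <- (cell - 1L) %/% 3L
  }
  data
}

#' Noise transforms for simulated data sets
#'
#' \code{add_missing} sets each genotype entry to missing independently with
#' probability \code{rate}. \code{add_genotyping_error} replaces each
#' non-missing entry, independently with probability \code{rate}, by one of
#' the two other genotype values chosen uniformly. \code{add_phenocopies}
#' picks \code{floor(rate * n_cases)} cases uniformly and resamples their
#' genotypes at every embedded interacting pair from the control
#' (no-disease) distribution, so their disease is no longer explained by the
#' modelled interactions. \code{add_heterogeneity} splits each model's
#' embedded pairs into a primary and a secondary half and attributes the
#' disease of \code{floor(fraction * n_cases)} uniformly chosen cases to the
#' secondary pairs: those cases get control-distribution genotypes at the
#' primary pairs and case-conditional genotypes at the secondary pairs,
#' while the remaining cases get control-distribution genotypes at the
#' secondary pairs. Phenotype, class totals and the truth manifest are never
#' changed; heterogeneity with a selection that rounds to zero cases is the
#' identity.
#'
#' @param data a \code{genotype_dataset}.
#' @param rate,fraction fraction in [0, 1].
#' @param seed optional seed; \code{NULL} draws from the ambient RNG stream.
#' @return the transformed \code{genotype_dataset}.
#' @name noise_transforms
NULL

#' @rdname noise_transforms
#' @export
add_missing <- function(data, rate, seed = NULL) {
  check_rate(rate)
  stopifnot(inherits(data, "genotype_dataset"))
  with_seed(seed, {
    if (rate > 0) {
      mask <- stats::runif(length(data$genotypes)) < rate
      data$genotypes[mask] <- NA_integer_
    }
    data
  })
}

#' @rdname noise_transforms
#' @export
add_genotyping_error <- function(data, rate, seed = NULL) {
  check_rate(rate)
  stopifnot(inherits(data, "genotype_dataset"))
  with_seed(seed, {
    if (rate > 0) {
      g <- data$genotypes
      hit <- which(!is.na(g) & stats::runif(length(g)) < rate)
      if (length(hit)) {
        shift <- sample(1:2, length(hit), replace = TRUE)
        g[hit] <- (g[hit] + shift) %% 3L
      }
      data$genotypes <- g
    }
    data
  })
}

#' @rdname noise_transforms
#' @export
add_phenocopies <- function(data, rate, seed = NULL) {
  check_rate(rate)
  stopifnot(inherits(data, "genotype_dataset"))
  with_seed(seed, {
    cases <- case_idx(data)
    k <- floor(rate * length(cases))
    if (k > 0 && nrow(data$truth$pairs)) {
      chosen <- sample(cases, k)
      data <- resample_pair_rows(data, chosen,
                                 seq_len(nrow(data$truth$pairs)), "control")
    }
    data
  })
}

#' @rdname noise_transforms
#' @export
add_heterogeneity <- function(data, fraction, seed = NULL) {
  check_rate(fraction, "fraction")
  stopifnot(inherits(data, "genotype_dataset"))
  model_ids <- data$truth$model
  if (any(table(factor(model_ids, levels = unique(model_ids))) < 2)) {
    stop_config("heterogeneity requires at least 2 embedded pairs per model")
  }
  with_seed(seed, {
    cases <- case_idx(data)
    k <- floor(fraction * length(cases))
    if (k > 0) {
      # second half of each model's pairs acts as the secondary mechanism
      secondary <- unlist(lapply(unique(model_ids), function(mid) {
        idx <- which(model_ids == mid)
        idx[seq.int(floor(length(idx) / 2) + 1L, length(idx))]
      }))
      primary <- setdiff(seq_along(model_ids), secondary)
      chosen <- sample(cases, k)
      rest <- setdiff(cases, chosen)
      data <- resample_pair_rows(data, chosen, primary, "control")
      data <- resample_pair_rows(data, chosen, secondary, "case")
      data <- resample_pair_rows(data, rest, secondary, "control")
    }
    data
  })
}

#' Destroy interactions for half of the SNPs by permutation
#'
#' Picks \code{floor(n_snps / 2)} SNP columns uniformly at random and
#' permutes each across the samples, independently per column. A permuted
#' column keeps its multiset of values but loses any association with the
#' phenotype or with other SNPs, so pairs involving a permuted SNP are known
#' false positives. The permuted columns are recorded in
#' \code{truth$permuted}; any embedded interacting pair that involves a
#' permuted SNP is dropped from the manifest's true pairs (its interaction
#' no longer exists).
#'
#' @param data a \code{genotype_dataset} with at least 2 SNPs.
#' @param seed optional seed.
#' @return the permuted \code{genotype_dataset}.
#' @export
permute_half_snps <- function(data, seed = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (n_snps(data) < 2L) stop_input("need at least 2 SNPs to permute half")
  with_seed(seed, {
    m <- n_snps(data)
    n <- n_samples(data)
    cols <- sort(sample.int(m, floor(m / 2)))
    for (cc in cols) {
      data$genotypes[, cc] <- data$genotypes[sample.int(n), cc]
    }
    keep <- !(data$truth$pairs[, 1] %in% cols |
                data$truth$pairs[, 2] %in% cols)
    data$truth <- truth_manifest(data$truth$pairs[keep, , drop = FALSE],
                                 data$truth$model[keep],
                                 permuted = cols)
    data
  })
}
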