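test_that("syn1 and syn2 presets embed the documented interaction counts", {
  d1 <- simulate_dataset(sim_preset("syn1", seed = 11))
  expect_equal(nrow(d1$truth$pairs), 24)
  expect_equal(ncol(d1$genotypes), 100)
  expect_equal(sum(d1$phenotype == 1), 200)
  expect_equal(sum(d1$phenotype == 0), 200)
  expect_equal(as.vector(table(d1$truth$model)), rep(4, 6))

  d2 <- simulate_dataset(sim_preset("syn2", seed = 11))
  expect_equal(nrow(d2$truth$pairs), 60)
  expect_equal(ncol(d2$genotypes), 500)
  expect_equal(as.vector(table(d2$truth$model)), rep(10, 6))

  # each SNP in at most one pair; pair columns occupy the lowest indices
  expect_equal(sort(as.vector(d1$truth$pairs)), 1:48)
  # noise-free: no missing entries, all values in 0..2
  expect_false(anyNA(d1$genotypes))
  expect_true(all(d1$genotypes %in% 0:2))
})

test_that("simulation is reproducible from the seed and varies across seeds", {
  a <- simulate_dataset(sim_preset("syn1", seed = 5))
  b <- simulate_dataset(sim_preset("syn1", seed = 5))
  c_ <- simulate_dataset(sim_preset("syn1", seed = 6))
  expect_identical(a, b)
  expect_false(identical(a$genotypes, c_$genotypes))
})

test_that("preset invariants are enforced", {
  expect_error(sim_preset("custom", n_snps = 10, pairs_per_model = 1),
               class = "epipair_config_error")
  expect_error(sim_preset("custom", n_snps = 20, pairs_per_model = 1,
                          n_cases = 0), class = "epipair_config_error")
  expect_error(noise_config(missing_rate = 1.2),
               class = "epipair_config_error")
})

test_that("missing-data noise hits the configured fraction of entries", {
  d <- simulate_dataset(small_preset(seed = 2))
  expect_identical(add_missing(d, 0, seed = 1), d)
  all_na <- add_missing(d, 1, seed = 1)
  expect_true(all(is.na(all_na$genotypes)))

  d4 <- simulate_dataset(sim_preset("syn1", seed = 3))
  miss <- add_missing(d4, 0.05, seed = 4)
  n_missing <- sum(is.na(miss$genotypes))
  interval <- stats::qbinom(c(0.005, 0.995), 400 * 100, 0.05)
  expect_gte(n_missing, interval[1])
  expect_lte(n_missing, interval[2])
  expect_identical(miss$phenotype, d4$phenotype)
  expect_identical(miss$truth, d4$truth)
})

test_that("genotyping error replaces entries at the configured rate", {
  d <- simulate_dataset(sim_preset("syn1", seed = 7))
  expect_identical(add_genotyping_error(d, 0, seed = 1), d)
  flipped <- add_genotyping_error(d, 1, seed = 1)
  expect_true(all(flipped$genotypes != d$genotypes))
  expect_true(all(flipped$genotypes %in% 0:2))

  some <- add_genotyping_error(d, 0.05, seed = 2)
  frac <- mean(some$genotypes != d$genotypes)
  interval <- stats::qbinom(c(0.005, 0.995), 400 * 100, 0.05) / (400 * 100)
  expect_gte(frac, interval[1])
  expect_lte(frac, interval[2])
})

test_that("phenocopies alter exactly the selected cases at pair loci only", {
  d <- simulate_dataset(sim_preset("syn1", seed = 9))
  expect_identical(add_phenocopies(d, 0, seed = 1), d)
  pc <- add_phenocopies(d, 0.5, seed = 1)
  changed_rows <- which(rowSums(pc$genotypes != d$genotypes) > 0)
  # only cases may change, at most floor(0.5 * 200) of them, and with 48
  # resampled loci per selected case virtually every selected case changes
  expect_true(all(d$phenotype[changed_rows] == 1))
  expect_equal(length(changed_rows), floor(0.5 * 200))
  pair_cols <- as.vector(d$truth$pairs)
  changed_cols <- which(colSums(pc$genotypes != d$genotypes) > 0)
  expect_true(all(changed_cols %in% pair_cols))
  expect_identical(pc$truth, d$truth)
})

test_that("phenocopy rate 1 removes the true pairs' signal entirely", {
  set.seed(401)
  diffs <- replicate(50, {
    d <- simulate_dataset(small_preset(n_snps = 30,
                                       noise = noise_config(phenocopy_rate = 1)))
    s <- score_pairs(d, "igain")
    lab <- label_pairs(d$truth, s)
    mean(s$score[lab]) - mean(s$score[!lab])
  })
  # mean interaction gain of true pairs statistically indistinguishable
  # from background pairs
  expect_gt(stats::t.test(diffs)$p.value, 0.001)
})

test_that("heterogeneity reassigns the selected fraction of cases", {
  d <- simulate_dataset(sim_preset("syn1", seed = 13))
  expect_identical(add_heterogeneity(d, 0, seed = 1), d)
  het <- add_heterogeneity(d, 0.5, seed = 1)
  changed_rows <- which(rowSums(het$genotypes != d$genotypes) > 0)
  expect_true(all(d$phenotype[changed_rows] == 1))
  # every case is touched: selected cases are resampled at primary pairs,
  # unselected cases at secondary pairs
  expect_true(all(colSums(het$genotypes != d$genotypes) == 0 |
                    seq_len(100) %in% as.vector(d$truth$pairs)))
  expect_identical(het$truth, d$truth)
  # single pair per model cannot express heterogeneity
  one <- simulate_dataset(small_preset(seed = 3))
  expect_error(add_heterogeneity(one, 0.5), class = "epipair_config_error")
})

test_that("heterogeneity 1 leaves primary pairs with no case signal", {
  set.seed(402)
  diffs <- replicate(30, {
    d <- simulate_dataset(sim_preset("custom", n_snps = 26,
                                     pairs_per_model = 2,
                                     n_cases = 100, n_controls = 100,
                                     noise = noise_config(heterogeneity = 1)))
    s <- score_pairs(d, "igain")
    model_ids <- d$truth$model
    primary <- unlist(lapply(unique(model_ids), function(m) {
      which(model_ids == m)[1]
    }))
    key <- paste(s$i, s$j)
    pkey <- paste(d$truth$pairs[primary, 1], d$truth$pairs[primary, 2])
    lab <- label_pairs(d$truth, s)
    mean(s$score[key %in% pkey]) - mean(s$score[!lab])
  })
  expect_gt(stats::t.test(diffs)$p.value, 0.001)
})

test_that("background SNP pairs are exchangeable with the phenotype", {
  set.seed(403)
  diffs <- replicate(100, {
    d <- simulate_dataset(small_preset(n_snps = 20, n_cases = 50,
                                       n_controls = 50))
    s <- score_pairs(d, "igain")
    bg <- s$i > 12 & s$j > 12        # pairs of two background SNPs
    perm <- d
    perm$phenotype <- sample(perm$phenotype)
    sp <- score_pairs(perm, "igain")
    bgp <- sp$i > 12 & sp$j > 12
    mean(s$score[bg]) - mean(sp$score[bgp])
  })
  expect_gt(stats::t.test(diffs)$p.value, 0.001)
})

test_that("pairwise signal of true pairs dominates single-locus association", {
  set.seed(404)
  ok <- replicate(20, {
    d <- simulate_dataset(small_preset(n_snps = 16))
    s <- score_pairs(d, "igain")
    lab <- label_pairs(d$truth, s)
    single_mi <- vapply(seq_len(16), function(j) {
      naive_mi(d$genotypes[, j], d$phenotype)
    }, numeric(1))
    mean(s$score[lab]) > stats::median(single_mi)
  })
  expect_true(all(ok))
})

test_that("permuting half the SNPs preserves value multisets and truth hygiene", {
  d <- simulate_dataset(sim_preset("syn1", seed = 21))
  p <- permute_half_snps(d, seed = 22)
  expect_length(p$truth$permuted, 50)
  for (cc in p$truth$permuted) {
    expect_equal(sort(p$genotypes[, cc]), sort(d$genotypes[, cc]))
  }
  untouched <- setdiff(seq_len(100), p$truth$permuted)
  expect_identical(p$genotypes[, untouched], d$genotypes[, untouched])
  # permuted SNPs never remain in the true-pair list
  expect_false(any(as.vector(p$truth$pairs) %in% p$truth$permuted))
  # a constant column is unchanged by permutation
  cd <- genotype_dataset(matrix(1L, 10, 2), rep(0:1, 5))
  pc <- permute_half_snps(cd, seed = 1)
  expect_identical(pc$genotypes, cd$genotypes)
  expect_error(permute_half_snps(genotype_dataset(matrix(0L, 4, 1),
                                                  rep(0:1, 2))),
               class = "epipair_input_error")
})

test_that("TSV, ped/map and truth JSON round-trips preserve the data", {
  d <- add_missing(simulate_dataset(small_preset(seed = 31)), 0.1, seed = 32)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(d, tsv)
  back <- read_genotypes(tsv)
  expect_identical(back$genotypes, d$genotypes)
  expect_identical(back$phenotype, d$phenotype)
  expect_identical(back$snp_ids, d$snp_ids)

  tj <- withr::local_tempfile(fileext = ".json")
  write_truth(d$truth, d$snp_ids, tj)
  tr <- read_truth(tj, d$snp_ids)
  expect_identical(tr, d$truth)

  prefix <- withr::local_tempfile()
  write_ped_map(d, prefix)
  ped <- readLines(paste0(prefix, ".ped"))
  map <- readLines(paste0(prefix, ".map"))
  expect_length(ped, nrow(d$genotypes))
  expect_length(map, ncol(d$genotypes))
  first <- strsplit(ped[1], " ")[[1]]
  expect_length(first, 6 + 2 * ncol(d$genotypes))
  expect_equal(first[6], as.character(d$phenotype[1] + 1))
})
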