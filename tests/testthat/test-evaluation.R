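# Helper: wrap an explicit ranking/label sequence into the classes the
# curve code expects.
ranked_labels <- function(labels, n_snps = 50L) {
  n <- length(labels)
  sc <- structure(data.frame(i = rep(1L, n), j = seq_len(n) + 1L,
                             snp_i = "x", snp_j = paste0("y", seq_len(n)),
                             score = seq(n, 1)),
                  method = "igain", n_snps = n_snps,
                  class = c("pair_scores", "data.frame"))
  list(scores = sc, labels = labels)
}

test_that("pairs are labelled against the manifest in both modes", {
  d <- simulate_dataset(sim_preset("syn1", seed = 18))
  s <- score_pairs(d, "igain")
  lab <- label_pairs(d$truth, s)
  expect_length(lab, 4950)
  expect_equal(sum(lab), 24)
  expect_false(anyNA(lab))

  p <- permute_half_snps(d, seed = 19)
  sp <- score_pairs(p, "igain")
  labp <- label_pairs(p$truth, sp, mode = "permutation")
  has_perm <- sp$i %in% p$truth$permuted | sp$j %in% p$truth$permuted
  expect_true(all(labp[has_perm] == FALSE))
  key <- paste(p$truth$pairs[, 1], p$truth$pairs[, 2])
  is_true_pair <- paste(sp$i, sp$j) %in% key
  expect_true(all(labp[is_true_pair]))
  # unpermuted non-embedded pairs have unknown status
  expect_true(all(is.na(labp[!has_perm & !is_true_pair])))

  bad <- s
  attr(bad, "n_snps") <- 10L
  expect_error(label_pairs(d$truth, bad), class = "epipair_input_error")
})

test_that("the documented toy ranking yields cumulative FP [0,1,1,2,3,3]", {
  rl <- ranked_labels(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  cu <- fp_curve(rl$scores, rl$labels)
  expect_equal(cu$fp, c(0, 1, 1, 2, 3, 3))
  expect_equal(cu$n_true, 3)
  expect_equal(cu$n_pairs, 6)
})

test_that("perfect and worst-case rankings attain the envelopes", {
  best <- ranked_labels(c(rep(TRUE, 4), rep(FALSE, 6)))
  cb <- fp_curve(best$scores, best$labels)
  expect_equal(cb$fp, pmax(0, seq_len(10) - 4))
  worst <- ranked_labels(c(rep(FALSE, 6), rep(TRUE, 4)))
  cw <- fp_curve(worst$scores, worst$labels)
  expect_equal(cw$fp, pmin(seq_len(10), 6))
})

test_that("every produced curve satisfies the FP-curve invariants", {
  set.seed(201)
  for (i in 1:20) {
    labels <- sample(c(TRUE, FALSE), 40, replace = TRUE,
                     prob = c(0.2, 0.8))
    rl <- ranked_labels(labels)
    cu <- fp_curve(rl$scores, rl$labels)
    expect_true(all(diff(cu$fp) >= 0))                       # monotone
    expect_true(all(cu$fp >= pmax(0, cu$k - cu$n_true)))     # >= best
    expect_true(all(cu$fp <= pmin(cu$k, cu$n_pairs - cu$n_true)))
    expect_equal(cu$fp[length(cu$fp)], cu$n_pairs - cu$n_true)
    # conservation: false + true selections = k
    tp <- cumsum(labels)
    expect_equal(cu$fp + tp, as.numeric(cu$k))
  }
})

test_that("NA-labelled pairs are excluded from the curve universe", {
  rl <- ranked_labels(c(TRUE, NA, FALSE, NA, FALSE, TRUE))
  cu <- fp_curve(rl$scores, rl$labels)
  expect_equal(cu$n_pairs, 4)
  expect_equal(cu$fp, c(0, 1, 2, 2))
})

test_that("curve averaging is a pointwise mean over a shared grid", {
  rl <- ranked_labels(c(TRUE, FALSE, TRUE, FALSE))
  cu <- fp_curve(rl$scores, rl$labels)
  expect_equal(average_curves(list(cu, cu))$fp, cu$fp)

  rl2 <- ranked_labels(c(FALSE, TRUE, FALSE, TRUE))
  cu2 <- fp_curve(rl2$scores, rl2$labels)
  avg <- average_curves(list(cu, cu2))
  expect_equal(avg$fp, (cu$fp + cu2$fp) / 2)
  expect_true(all(avg$fp >= pmin(cu$fp, cu2$fp)))
  expect_true(all(avg$fp <= pmax(cu$fp, cu2$fp)))

  rl3 <- ranked_labels(c(TRUE, FALSE))
  expect_error(average_curves(list(cu, fp_curve(rl3$scores, rl3$labels))),
               class = "epipair_input_error")
})

test_that("a one-replicate direct experiment equals the manual pipeline", {
  preset <- small_preset()
  ex <- run_experiment(preset, methods = "igain", strategies = "direct",
                       n_reps = 1, seed = 31)
  manual <- withr::with_seed((31 * 1000 + 1) %% 2147483647, {
    d <- simulate_dataset(preset)
    s <- score_pairs(d, "igain")
    fp_curve(s, label_pairs(d$truth, s))
  })
  expect_equal(ex$curves$igain$direct, manual)
})

test_that("strategy names parse and unknown ones are rejected", {
  expect_error(run_experiment(small_preset(), strategies = "rg_three",
                              n_reps = 1, seed = 1),
               class = "epipair_config_error")
  ex <- run_experiment(small_preset(), methods = "igain",
                       strategies = c("rg2", "bootstrap2"),
                       n_reps = 2, seed = 5)
  expect_named(ex$curves$igain, c("rg2", "bootstrap2"))
})

test_that("bootstrap aggregation does not trail replication groups", {
  ex <- run_experiment(sim_preset("syn1"), methods = c("igain", "hfcc"),
                       strategies = c("rg3", "bootstrap3"),
                       n_reps = 20, seed = 23)
  for (method in c("igain", "hfcc")) {
    boot <- ex$curves[[method]]$bootstrap3
    rg3 <- ex$curves[[method]]$rg3
    for (k in c(24, 100, 1000)) {
      expect_lte(boot$fp[match(k, boot$k)], rg3$fp[match(k, rg3$k)])
    }
  }
})

test_that("performance plots are written without log-domain errors", {
  rl <- ranked_labels(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  cu <- fp_curve(rl$scores, rl$labels)     # zero-FP prefix at small k
  path <- withr::local_tempfile(fileext = ".png")
  expect_no_error(plot_performance(list(direct = cu), file = path))
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
})

test_that("experiments and their curve tables are reproducible and writable", {
  preset <- small_preset()
  ex1 <- run_experiment(preset, methods = "igain",
                        strategies = c("direct", "rg2"),
                        n_reps = 2, seed = 77)
  ex2 <- run_experiment(preset, methods = "igain",
                        strategies = c("direct", "rg2"),
                        n_reps = 2, seed = 77)
  expect_equal(ex1$curves, ex2$curves)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fp_curves(ex1, path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_named(df, c("k", "fp_igain_direct", "fp_igain_rg2", "best", "worst"))
  expect_equal(nrow(df), count_pairs(20))
})
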