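# Top-k false-positive evaluation: turn a ranked pair list plus ground
# truth into a false-positive-vs-k curve with theoretical best/worst
# envelopes, average curves over replicates, and drive whole experiments.

#' Label ranked pairs against the ground truth
#'
#' In \code{simulation} mode a pair is a true interaction iff it was
#' embedded (listed in \code{truth$pairs}); every other pair is false. In
#' \code{permutation} mode any pair containing a permuted SNP is false,
#' embedded pairs are true, and pairs of two unpermuted SNPs are of unknown
#' status (\code{NA}) and excluded from false-positive counting — in real
#' permuted data nothing is known about them. \code{"auto"} selects
#' permutation mode iff the manifest records permuted SNPs.
#'
#' @param truth a \code{truth_manifest}.
#' @param scores a \code{pair_scores} ranking.
#' @param mode \code{"auto"}, \code{"simulation"} or \code{"permutation"}.
#' @return logical vector aligned with the rows of \code{scores}: TRUE =
#'   true interaction, FALSE = false positive when selected, NA = excluded.
#' @export
label_pairs <- function(truth, scores, mode = c("auto", "simulation",
                                                "permutation")) {
  stopifnot(inherits(truth, "truth_manifest"),
            inherits(scores, "pair_scores"))
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (length(truth$permuted)) "permutation" else "simulation"
  }
  m <- attr(scores, "n_snps")
  validate_truth(truth, m)
  if (any(scores$i < 1 | scores$j > m)) {
    stop_input("scores reference SNP indices outside the truth universe")
  }
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  true_keys <- if (nrow(truth$pairs)) {
    key(truth$pairs[, 1], truth$pairs[, 2])
  } else character()
  lab <- key(scores$i, scores$j) %in% true_keys
  if (mode == "permutation") {
    has_perm <- scores$i %in% truth$permuted | scores$j %in% truth$permuted
    lab[!lab & !has_perm] <- NA
    lab[has_perm] <- FALSE
  }
  lab
}

#' False-positive curve of a ranking
#'
#' For each cutoff k, counts the false pairs among the k best-scored pairs.
#' Pairs with \code{NA} labels are removed from the ranking first (their
#' status is unknown), so the curve lives on the labelled pair universe.
#' Envelopes: \code{best(k) = max(0, k - n_true)} (all true pairs ranked
#' first) and \code{worst(k) = min(k, n_false)} (all false pairs first).
#' The k grid is every integer up to the number of pairs when that is at
#' most 10^4, otherwise a log-spaced grid of at most 512 points.
#'
#' @param scores a \code{pair_scores}, ranked (as produced by the scan).
#' @param labels logical vector from [label_pairs()], same length as
#'   \code{nrow(scores)}.
#' @return object of class \code{fp_curve}: list with \code{k}, \code{fp},
#'   \code{best}, \code{worst}, \code{n_true}, \code{n_pairs}.
#' @export
fp_curve <- function(scores, labels) {
  stopifnot(inherits(scores, "pair_scores"))
  if (length(labels) != nrow(scores)) {
    stop_input("labels must have one entry per scored pair")
  }
  labels <- labels[!is.na(labels)]
  n_pairs <- length(labels)
  if (!n_pairs) stop_input("no labelled pairs to evaluate")
  n_true <- sum(labels)
  k <- k_grid(n_pairs)
  fp <- cumsum(!labels)[k]
  structure(list(k = k, fp = as.numeric(fp),
                 best = pmax(0, k - n_true),
                 worst = pmin(k, n_pairs - n_true),
                 n_true = n_true, n_pairs = n_pairs),
            class = "fp_curve")
}

k_grid <- function(n_pairs) {
  if (n_pairs <= 1e4) return(seq_len(n_pairs))
  unique(round(exp(seq(log(1), log(n_pairs), length.out = 512))))
}

#' @export
print.fp_curve <- function(x, ...) {
  cat(sprintf("fp_curve: %d pairs (%d true); FP at k = %s: %s\n",
              x$n_pairs, x$n_true,
              paste(show_k <- intersect(c(10, 24, 100, 1000), x$k),
                    collapse = "/"),
              paste(format(x$fp[match(show_k, x$k)], digits = 3),
                    collapse = "/")))
  invisible(x)
}

#' Average false-positive curves over replicates
#'
#' Pointwise arithmetic mean of the \code{fp} vectors; all curves must share
#' the same k grid and number of true pairs.
#'
#' @param curves list of \code{fp_curve}s.
#' @return an \code{fp_curve} with real-valued \code{fp}.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE,
                                            "fp_curve")))
  ref <- curves[[1]]
  for (cu in curves[-1]) {
    if (!identical(cu$k, ref$k) || cu$n_true != ref$n_true ||
        cu$n_pairs != ref$n_pairs) {
      stop_input("curves to average must share the k grid and truth counts")
    }
  }
  fp <- rowMeans(vapply(curves, function(cu) cu$fp,
                        numeric(length(ref$k))))
  out <- ref
  out$fp <- fp
  out
}

# Parse strategy names of the form "direct", "rg2", "rg3", "rgN",
# "bootstrap" (r = 3) or "bootstrapN" into (strategy, r).
parse_strategy <- function(name) {
  if (name == "direct") {
    list(strategy = "direct", r = 1L)
  } else if (grepl("^rg[0-9]+$", name)) {
    list(strategy = "replication_groups",
         r = as.integer(sub("^rg", "", name)))
  } else if (grepl("^bootstrap[0-9]*$", name)) {
    r <- sub("^bootstrap", "", name)
    list(strategy = "bootstrap", r = if (nzchar(r)) as.integer(r) else 3L)
  } else {
    stop_config("unknown strategy name: ", name,
                " (expected direct, rgN or bootstrapN)")
  }
}

#' Run a simulate-score-aggregate-evaluate experiment
#'
#' For each replicate: simulate a data set from \code{preset} (with a
#' replicate-specific seed derived from \code{seed}), optionally permute
#' half of the SNPs (\code{mode = "permutation"}), then for every
#' aggregation strategy and every scoring method compute the aggregated
#' ranking and its false-positive curve. Returns the curves averaged over
#' replicates, per method and strategy. Fully reproducible from
#' \code{seed}; each subset's genotype cross-tabulation is shared between
#' the scoring methods.
#'
#' @param preset a [sim_preset()]; its own \code{seed} field is ignored in
#'   favour of the replicate seeds derived here.
#' @param methods scoring methods, subset of \code{c("igain", "hfcc")}.
#' @param strategies strategy names: \code{"direct"}, \code{"rgN"} (N
#'   replication groups), \code{"bootstrapN"} (N resamples, default 3).
#' @param n_reps number of replicates to average over.
#' @param seed base RNG seed.
#' @param mode \code{"simulation"} (every non-embedded pair is false) or
#'   \code{"permutation"} (half the SNPs permuted after simulation; only
#'   pairs involving permuted SNPs count as false).
#' @return object of class \code{epi_experiment}: list with
#'   \code{curves[[method]][[strategy]]} (averaged [fp_curve()]s) and the
#'   run metadata.
#' @examples
#' \donttest{
#' ex <- run_experiment(sim_preset("syn1"), methods = "igain",
#'                      strategies = c("direct", "rg3"),
#'                      n_reps = 3, seed = 1)
#' ex
#' }
#' @export
run_experiment <- function(preset,
                           methods = c("igain", "hfcc"),
                           strategies = c("direct", "rg2", "rg3"),
                           n_reps = 100L, seed = 1L,
                           mode = c("simulation", "permutation")) {
  stopifnot(inherits(preset, "sim_preset"))
  methods <- match.arg(methods, several.ok = TRUE)
  mode <- match.arg(mode)
  if (n_reps < 1L) stop_config("n_reps must be at least 1")
  specs <- lapply(strategies, parse_strategy)
  names(specs) <- strategies
  preset$seed <- NULL

  curves <- lapply(methods, function(m) {
    stats::setNames(lapply(strategies, function(s) list()), strategies)
  })
  names(curves) <- methods

  for (rep in seq_len(n_reps)) {
    rep_seed <- (as.numeric(seed) * 1000 + rep) %% 2147483647
    rep_curves <- with_seed(rep_seed, {
      data <- simulate_dataset(preset)
      if (mode == "permutation") data <- permute_half_snps(data)
      out <- list()
      for (s in strategies) {
        plan <- subset_plan(data, specs[[s]]$strategy, specs[[s]]$r)
        mats <- aggregate_matrices(data, plan, methods)
        for (meth in methods) {
          ranked <- rank_pairs(mats[[meth]], data$snp_ids, meth)
          labels <- label_pairs(data$truth, ranked, mode = mode)
          out[[meth]][[s]] <- fp_curve(ranked, labels)
        }
      }
      out
    })
    for (meth in methods) for (s in strategies) {
      curves[[meth]][[s]][[rep]] <- rep_curves[[meth]][[s]]
    }
  }

  avg <- lapply(methods, function(meth) {
    stats::setNames(lapply(strategies, function(s) {
      average_curves(curves[[meth]][[s]])
    }), strategies)
  })
  names(avg) <- methods
  structure(list(curves = avg, preset = preset, methods = methods,
                 strategies = strategies, n_reps = n_reps, seed = seed,
                 mode = mode),
            class = "epi_experiment")
}

#' Mean false-positive counts at selected cutoffs
#'
#' @param experiment an \code{epi_experiment}.
#' @param k cutoffs to report.
#' @return data frame with columns \code{method}, \code{strategy},
#'   \code{k}, \code{fp}.
#' @export
fp_at <- function(experiment, k = c(10, 24, 100, 1000)) {
  stopifnot(inherits(experiment, "epi_experiment"))
  rows <- list()
  for (meth in experiment$methods) {
    for (s in experiment$strategies) {
      cu <- experiment$curves[[meth]][[s]]
      kk <- k[k <= max(cu$k)]
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, strategy = s, k = kk,
                   fp = cu$fp[match(kk, cu$k)])
    }
  }
  do.call(rbind, rows)
}

#' @export
print.epi_experiment <- function(x, ...) {
  cat(sprintf("epi_experiment: preset %s (%d SNPs), %s mode, %d replicate(s)\n",
              x$preset$name, x$preset$n_snps, x$mode, x$n_reps))
  cat("mean false positives among the top k pairs:\n")
  tab <- fp_at(x)
  tab$fp <- round(tab$fp, 2)
  print(utils::head(stats::reshape(tab, direction = "wide",
                                   idvar = c("method", "strategy"),
                                   timevar = "k"), 20), row.names = FALSE)
  invisible(x)
}

#' Write averaged curves as TSV
#'
#' Columns: \code{k}, one \code{fp_<method>_<strategy>} column per curve,
#' \code{best}, \code{worst}.
#'
#' @param experiment an \code{epi_experiment}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_fp_curves <- function(experiment, path) {
  stopifnot(inherits(experiment, "epi_experiment"))
  first <- experiment$curves[[1]][[1]]
  df <- data.frame(k = first$k)
  for (meth in experiment$methods) {
    for (s in experiment$strategies) {
      df[[paste0("fp_", meth, "_", s)]] <- experiment$curves[[meth]][[s]]$fp
    }
  }
  df$best <- first$best
  df$worst <- first$worst
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot false-positive performance curves
#'
#' Log-log plot of mean false-positive count against the number of selected
#' top-ranked pairs, one curve per strategy, with the theoretical best and
#' worst envelopes in light gray. Zero counts are clipped to a small floor
#' so the log scale is well defined (the axes are logarithmic to emphasise
#' small candidate sets).
#'
#' @param curves named list of \code{fp_curve}s (one per strategy), or an
#'   \code{epi_experiment} via the plot method.
#' @param file optional path; when given the plot is written there as PNG.
#' @param main plot title.
#' @return \code{file} (or \code{NULL}), invisibly.
#' @export
plot_performance <- function(curves, file = NULL, main = "") {
  stopifnot(length(curves) >= 1)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  ref <- curves[[1]]
  floor_v <- 0.5
  clip <- function(v) pmax(v, floor_v)
  graphics::plot(ref$k, clip(ref$worst), type = "n", log = "xy",
                 xlab = "number of best-scored pairs selected (k)",
                 ylab = "false positives among top k", main = main,
                 ylim = c(floor_v, max(ref$worst)))
  graphics::lines(ref$k, clip(ref$best), col = "gray80", lwd = 2)
  graphics::lines(ref$k, clip(ref$worst), col = "gray80", lwd = 2)
  cols <- grDevices::hcl.colors(max(3, length(curves)), "Dark 3")
  lty <- c(1, 2, 3, 4, 5, 6)
  for (ii in seq_along(curves)) {
    graphics::lines(curves[[ii]]$k, clip(curves[[ii]]$fp),
                    col = cols[ii], lwd = 2,
                    lty = lty[(ii - 1) %% 6 + 1])
  }
  graphics::legend("topleft",
                   legend = c(names(curves), "best/worst envelope"),
                   col = c(cols[seq_along(curves)], "gray80"),
                   lty = c(lty[(seq_along(curves) - 1) %% 6 + 1], 1),
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(file)
}

#' @export
plot.epi_experiment <- function(x, method = x$methods[1], file = NULL, ...) {
  plot_performance(x$curves[[method]], file = file,
                   main = sprintf("%s, %s scoring (%d replicates)",
                                  x$preset$name, method, x$n_reps))
}
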