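# Aggregation strategies: direct (whole data set), replication groups
# (stratified disjoint split, min over subsets), bootstrap (stratified
# resamples, min over subsets).

#' Build a sample-subset plan
#'
#' \describe{
#'   \item{direct}{one subset containing every sample.}
#'   \item{replication_groups}{the samples are split into \code{r} disjoint
#'     subsets of approximately equal sizes and class distributions: each
#'     phenotype class's indices are shuffled and dealt round-robin to the
#'     \code{r} subsets, with the dealing position carried over between
#'     classes so that both per-class and total subset sizes differ by at
#'     most one.}
#'   \item{bootstrap}{\code{r} subsets, each a with-replacement resample of
#'     size \code{n_samples}, drawn within phenotype class so every subset
#'     keeps the exact case/control totals.}
#' }
#'
#' @param data a \code{genotype_dataset}.
#' @param strategy \code{"direct"}, \code{"replication_groups"} or
#'   \code{"bootstrap"}.
#' @param r number of subsets (forced to 1 for direct; must not exceed the
#'   smaller phenotype class for replication groups).
#' @param seed RNG seed; same seed, same plan.
#' @return object of class \code{subset_plan}: list with \code{strategy},
#'   \code{r}, \code{seed} and \code{subsets} (sample-index vectors).
#' @export
subset_plan <- function(data,
                        strategy = c("direct", "replication_groups",
                                     "bootstrap"),
                        r = 1L, seed = NULL) {
  stopifnot(inherits(data, "genotype_dataset"))
  strategy <- match.arg(strategy)
  r <- as.integer(r)
  if (r < 1L) stop_config("r must be at least 1")
  n <- n_samples(data)
  classes <- list(control_idx(data), case_idx(data))
  subsets <- switch(strategy,
    direct = {
      r <- 1L
      list(seq_len(n))
    },
    replication_groups = {
      if (r > min(lengths(classes))) {
        stop_config("r must not exceed the smaller phenotype class")
      }
      with_seed(seed, {
        groups <- vector("list", r)
        start <- 0L
        for (cls in classes) {
          dealt <- sample(cls)
          grp <- ((seq_along(dealt) - 1L + start) %% r) + 1L
          for (g in seq_len(r)) {
            groups[[g]] <- c(groups[[g]], dealt[grp == g])
          }
          start <- (start + length(dealt)) %% r
        }
        lapply(groups, sort)
      })
    },
    bootstrap = {
      with_seed(seed, {
        lapply(seq_len(r), function(b) {
          sort(unlist(lapply(classes, function(cls) {
            sample(cls, length(cls), replace = TRUE)
          })))
        })
      })
    })
  structure(list(strategy = strategy, r = r, seed = seed, subsets = subsets),
            class = "subset_plan")
}

#' @export
print.subset_plan <- function(x, ...) {
  cat(sprintf("subset_plan: %s, r = %d, subset sizes: %s\n",
              x$strategy, x$r, paste(lengths(x$subsets), collapse = ", ")))
  invisible(x)
}

#' Serialise / load a subset plan as JSON
#'
#' Stores the strategy, r, seed and the explicit sample indices of every
#' subset, sufficient to replay an aggregation exactly.
#'
#' @param plan a \code{subset_plan}.
#' @param path file path.
#' @return \code{write_plan}: \code{path} invisibly; \code{read_plan}: a
#'   \code{subset_plan}.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "subset_plan"))
  jsonlite::write_json(list(strategy = plan$strategy, r = plan$r,
                            seed = plan$seed, subsets = plan$subsets),
                       path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(strategy = obj$strategy, r = as.integer(obj$r),
                 seed = obj$seed,
                 subsets = lapply(obj$subsets,
                                  function(s) as.integer(unlist(s)))),
            class = "subset_plan")
}

# Per-subset score matrices for one or more methods, min-aggregated.
# Returns a named list of m x m matrices, one per method. Shared by
# aggregate_scores() and the experiment driver so each subset's genotype
# cross-tabulation is computed once however many methods are requested.
aggregate_matrices <- function(data, plan, methods) {
  agg <- NULL
  for (idx in plan$subsets) {
    sub <- subset_samples(data, idx)
    if (length(unique(sub$phenotype)) < 2L) {
      stop_config("a subset contains a single phenotype class; ",
                  "scores are undefined on it")
    }
    counts <- pair_counts(sub$genotypes, sub$phenotype)
    mats <- lapply(methods, function(meth) score_matrix(counts, meth))
    names(mats) <- methods
    agg <- if (is.null(agg)) mats else Map(pmin, agg, mats)
  }
  agg
}

#' Aggregate pair scores over a subset plan
#'
#' Scores every SNP pair on every subset of the plan and returns, per pair,
#' the minimum score across subsets (for a direct plan this is exactly the
#' whole-data score). A pair selected by thresholding the aggregated score
#' is therefore one whose score exceeds the threshold in every subset
#' simultaneously.
#'
#' @param data a \code{genotype_dataset}.
#' @param plan a [subset_plan()].
#' @param method \code{"igain"} or \code{"hfcc"}.
#' @return a \code{pair_scores} ranking (see [score_pairs()]).
#' @export
aggregate_scores <- function(data, plan, method = c("igain", "hfcc")) {
  stopifnot(inherits(data, "genotype_dataset"),
            inherits(plan, "subset_plan"))
  method <- match.arg(method)
  mat <- aggregate_matrices(data, plan, method)[[method]]
  rank_pairs(mat, data$snp_ids, method)
}

#' Select pairs exceeding a threshold
#'
#' Returns the pairs whose aggregated score is strictly greater than
#' \code{threshold}. With min-aggregated scores this is the set of pairs
#' scoring above the threshold in every subset.
#'
#' @param scores a \code{pair_scores}.
#' @param threshold numeric cutoff T.
#' @return the selected rows of \code{scores} (still ranked).
#' @export
threshold_select <- function(scores, threshold) {
  stopifnot(inherits(scores, "pair_scores"))
  keep <- !is.na(scores$score) & scores$score > threshold
  scores[keep, , drop = FALSE]
}
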