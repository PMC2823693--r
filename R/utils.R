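# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL runs under the ambient RNG stream (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# x * log2(x) with the 0 log 0 = 0 convention, vectorised.
xlog2x <- function(x) {
  out <- x * log2(x)
  out[x == 0] <- 0
  out
}

#' Number of unordered SNP pairs
#'
#' Convenience wrapper around \code{choose(n, 2)}: the number of candidate
#' interaction hypotheses an exhaustive pairwise scan of \code{n} SNPs must
#' score (about 5e11 for a million-probe array).
#'
#' @param n_snps number of SNPs.
#' @return number of unordered pairs, \code{n_snps * (n_snps - 1) / 2}.
#' @examples
#' count_pairs(100)  # 4950
#' @export
count_pairs <- function(n_snps) {
  stopifnot(is.numeric(n_snps), n_snps >= 0)
  choose(n_snps, 2)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("epipair_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("epipair_input_error", "error")))
}

check_rate <- function(rate, what = "rate") {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop_config(what, " must be a single value in [0, 1]")
  }
  invisible(rate)
}
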