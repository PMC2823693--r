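# Pairwise SNP interaction scores.
#
# Two scores are implemented on the 3 x 3 x 2 (genotype X, genotype Y,
# phenotype) contingency table of a SNP pair:
#
#   * interaction gain, I(XY;C) - I(X;C) - I(Y;C) in bits, with plug-in
#     probability estimates, base-2 logs and the 0 log 0 = 0 convention —
#     the information gained by considering the two SNPs jointly over
#     considering them separately; negative values indicate redundancy;
#
#   * an HFCC-like score: each of the nine single-high-risk-cell disease
#     models collapses the 9 genotype cells into high-risk vs low-risk; the
#     Pearson chi-square of the resulting 2 x 2 (risk x phenotype) table is
#     kept when the high-risk cell is case-enriched and clamped to 0
#     otherwise; the score is the maximum over the nine models (best-fitting
#     model). This mirrors the described best-disease-model mechanism; it is
#     not a bit-exact reimplementation of the HFCC binary, whose fit
#     statistic is not public.
#
# Missing genotypes are handled pairwise-complete: a sample contributes to a
# pair's table only if it is non-missing at both SNPs.

#' Two-SNP contingency table
#'
#' Tabulates the joint distribution of genotypes at SNPs \code{i} and
#' \code{j} against the phenotype, over the samples with non-missing
#' genotypes at both SNPs.
#'
#' @param data a \code{genotype_dataset}.
#' @param i,j distinct SNP column indices.
#' @return object of class \code{pair_table}: list with \code{counts}
#'   (3 x 3 x 2 array indexed by genotype at X, genotype at Y, phenotype
#'   control/case) and \code{n} (total tabulated samples).
#' @export
pair_contingency <- function(data, i, j) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (i == j) stop_input("i and j must be distinct SNP indices")
  if (i < 1 || j < 1 || i > n_snps(data) || j > n_snps(data)) {
    stop_input("SNP index out of range")
  }
  x <- data$genotypes[, i]
  y <- data$genotypes[, j]
  ok <- !is.na(x) & !is.na(y)
  counts <- array(0L, dim = c(3, 3, 2),
                  dimnames = list(X = 0:2, Y = 0:2,
                                  C = c("control", "case")))
  if (any(ok)) {
    tab <- table(factor(x[ok], levels = 0:2),
                 factor(y[ok], levels = 0:2),
                 factor(data$phenotype[ok], levels = 0:1))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, n = sum(ok)), class = "pair_table")
}

# Plug-in entropy in bits of a vector/array of counts summing to n.
count_entropy <- function(counts, n) {
  if (n == 0) return(0)
  log2(n) - sum(xlog2x(as.numeric(counts))) / n
}

#' Interaction gain of a two-SNP contingency table
#'
#' \code{I(XY;C) - I(X;C) - I(Y;C)} in bits, where \code{XY} is the 9-valued
#' joint genotype variable and \code{C} the phenotype, using maximum-
#' likelihood (plug-in) probability estimates and base-2 logarithms.
#' Symmetric in X and Y; positive when the pair is synergistic, negative
#' when the two SNPs are redundant. Bounded by 1 bit in absolute value for a
#' binary phenotype.
#'
#' @param t a \code{pair_table} from [pair_contingency()].
#' @return interaction gain in bits.
#' @examples
#' # phenotype = XOR of two binary-valued SNPs: 1 full bit of pure synergy
#' g <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
#' d <- genotype_dataset(g, c(0, 1, 1, 0))
#' interaction_gain(pair_contingency(d, 1, 2))
#' @export
interaction_gain <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  if (t$n == 0) stop_input("interaction gain is undefined on an empty table")
  cnt <- t$counts
  n <- t$n
  h_xyc <- count_entropy(cnt, n)
  h_xy <- count_entropy(apply(cnt, c(1, 2), sum), n)
  h_xc <- count_entropy(apply(cnt, c(1, 3), sum), n)
  h_yc <- count_entropy(apply(cnt, c(2, 3), sum), n)
  h_x <- count_entropy(apply(cnt, 1, sum), n)
  h_y <- count_entropy(apply(cnt, 2, sum), n)
  h_c <- count_entropy(apply(cnt, 3, sum), n)
  i_xy_c <- h_xy + h_c - h_xyc
  i_x_c <- h_x + h_c - h_xc
  i_y_c <- h_y + h_c - h_yc
  i_xy_c - i_x_c - i_y_c
}

#' HFCC-like best-disease-model score of a two-SNP contingency table
#'
#' For each supplied single-high-risk-cell disease model, collapses the nine
#' genotype cells into high-risk vs low-risk, computes the Pearson
#' chi-square statistic of the 2 x 2 risk-by-phenotype table, keeps it when
#' the high-risk cell is enriched in cases and clamps it to 0 otherwise, and
#' returns the maximum over models. Zero on phenotype-independent tables;
#' equals \code{n} under perfect case/control separation by one cell. The
#' statistic is not normalised by sample size, so values grow with n.
#'
#' @param t a \code{pair_table}.
#' @param models list of \code{risk_model}s, by default the nine from
#'   [risk_partition_models()].
#' @return the best-model chi-square statistic (non-negative).
#' @export
hfcc_score <- function(t, models = risk_partition_models()) {
  stopifnot(inherits(t, "pair_table"))
  if (t$n == 0) stop_input("score is undefined on an empty table")
  if (!length(models)) stop_config("at least one disease model is required")
  case_tot <- sum(t$counts[, , 2])
  ctrl_tot <- sum(t$counts[, , 1])
  n <- t$n
  best <- 0
  for (m in models) {
    a <- t$counts[m$high_risk[1] + 1L, m$high_risk[2] + 1L, 2]  # hi-risk case
    b <- t$counts[m$high_risk[1] + 1L, m$high_risk[2] + 1L, 1]  # hi-risk ctrl
    c_ <- case_tot - a
    d <- ctrl_tot - b
    num <- a * d - b * c_
    if (num <= 0) next  # high-risk cell not case-enriched
    den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
    if (den == 0) next  # degenerate collapse: empty marginal contributes 0
    best <- max(best, n * num^2 / den)
  }
  best
}

# ---- vectorised all-pairs scan ---------------------------------------------

# Per-class genotype-indicator cross products: counts[[c]][[g]][[h]] is the
# m x m matrix whose (i, j) entry counts samples of phenotype class c with
# genotype g at SNP i and h at SNP j (pairwise-complete by construction:
# missing entries are 0 in every indicator).
pair_counts <- function(genotypes, phenotype) {
  lapply(0:1, function(cl) {
    rows <- phenotype == cl
    ind <- lapply(0:2, function(g) {
      x <- genotypes[rows, , drop = FALSE] == g
      x[is.na(x)] <- FALSE
      storage.mode(x) <- "double"
      x
    })
    lapply(1:3, function(g) lapply(1:3, function(h) {
      crossprod(ind[[g]], ind[[h]])
    }))
  })
}

# Elementwise entropy matrix for a list of m x m count matrices with totals
# `n` (m x m): H = log2(n) - sum(xlog2x(counts)) / n; 0 where n = 0.
entropy_mat <- function(count_list, n) {
  s <- 0
  for (cm in count_list) s <- s + xlog2x(cm)
  h <- log2(n) - s / n
  h[n == 0] <- 0
  h
}

# m x m matrix of interaction gains over all pairs (only the upper triangle
# is meaningful); entries with an empty pairwise-complete table are NA.
igain_matrix <- function(counts) {
  cells <- list()
  for (cl in 1:2) for (g in 1:3) for (h in 1:3) {
    cells[[length(cells) + 1L]] <- counts[[cl]][[g]][[h]]
  }
  n <- Reduce(`+`, cells)
  joint <- lapply(1:3, function(g) lapply(1:3, function(h) {
    counts[[1]][[g]][[h]] + counts[[2]][[g]][[h]]
  }))
  xc <- unlist(lapply(1:2, function(cl) lapply(1:3, function(g) {
    Reduce(`+`, counts[[cl]][[g]])
  })), recursive = FALSE)
  yc <- unlist(lapply(1:2, function(cl) lapply(1:3, function(h) {
    Reduce(`+`, lapply(1:3, function(g) counts[[cl]][[g]][[h]]))
  })), recursive = FALSE)
  x_m <- lapply(1:3, function(g) xc[[g]] + xc[[3 + g]])
  y_m <- lapply(1:3, function(h) yc[[h]] + yc[[3 + h]])
  c_m <- lapply(1:2, function(cl) {
    s <- 0
    for (g in 1:3) for (h in 1:3) s <- s + counts[[cl]][[g]][[h]]
    s
  })
  h_xyc <- entropy_mat(cells, n)
  h_xy <- entropy_mat(unlist(joint, recursive = FALSE), n)
  h_xc <- entropy_mat(xc, n)
  h_yc <- entropy_mat(yc, n)
  h_x <- entropy_mat(x_m, n)
  h_y <- entropy_mat(y_m, n)
  h_c <- entropy_mat(c_m, n)
  ig <- (h_xy + h_c - h_xyc) - (h_x + h_c - h_xc) - (h_y + h_c - h_yc)
  ig[n == 0] <- NA_real_
  ig
}

# m x m matrix of HFCC-like scores over all pairs.
hfcc_matrix <- function(counts) {
  case_tot <- 0
  ctrl_tot <- 0
  for (g in 1:3) for (h in 1:3) {
    case_tot <- case_tot + counts[[2]][[g]][[h]]
    ctrl_tot <- ctrl_tot + counts[[1]][[g]][[h]]
  }
  n <- case_tot + ctrl_tot
  best <- matrix(0, nrow(n), ncol(n))
  for (g in 1:3) for (h in 1:3) {
    a <- counts[[2]][[g]][[h]]
    b <- counts[[1]][[g]][[h]]
    c_ <- case_tot - a
    d <- ctrl_tot - b
    num <- a * d - b * c_
    den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
    chi <- ifelse(num > 0 & den > 0, n * num^2 / den, 0)
    best <- pmax(best, chi)
  }
  best[n == 0] <- NA_real_
  best
}

score_matrix <- function(counts, method) {
  switch(method,
         igain = igain_matrix(counts),
         hfcc = hfcc_matrix(counts),
         stop_config("unknown scoring method: ", method))
}

# Turn an m x m score matrix into a ranked pair_scores data frame:
# descending score, ties broken lexicographically by (i, j); NA scores
# (empty pairwise-complete tables) sort last.
rank_pairs <- function(scores_mat, snp_ids, method) {
  m <- nrow(scores_mat)
  ut <- which(upper.tri(scores_mat), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2],
                   score = scores_mat[ut])
  ord <- order(-df$score, df$i, df$j, na.last = TRUE)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$snp_i <- snp_ids[df$i]
  df$snp_j <- snp_ids[df$j]
  structure(df[, c("i", "j", "snp_i", "snp_j", "score")],
            method = method, n_snps = m,
            class = c("pair_scores", "data.frame"))
}

#' Score every SNP pair of a data set
#'
#' Computes the chosen interaction score for all \code{choose(n_snps, 2)}
#' unordered SNP pairs. Missing genotypes are handled pairwise-complete.
#' The result is sorted by descending score, ties broken lexicographically
#' by SNP index pair, so the ranking is deterministic.
#'
#' @param data a \code{genotype_dataset}.
#' @param method \code{"igain"} (interaction gain, bits) or \code{"hfcc"}
#'   (HFCC-like best-disease-model chi-square).
#' @return object of class \code{pair_scores}: a data frame with columns
#'   \code{i}, \code{j}, \code{snp_i}, \code{snp_j}, \code{score}, plus
#'   attributes \code{method} and \code{n_snps}.
#' @examples
#' d <- simulate_dataset(sim_preset("custom", n_snps = 20,
#'                                  pairs_per_model = 1, seed = 1))
#' head(score_pairs(d, "igain"))
#' @export
score_pairs <- function(data, method = c("igain", "hfcc")) {
  stopifnot(inherits(data, "genotype_dataset"))
  method <- match.arg(method)
  if (n_snps(data) < 2L) stop_input("need at least 2 SNPs to score pairs")
  counts <- pair_counts(data$genotypes, data$phenotype)
  rank_pairs(score_matrix(counts, method), data$snp_ids, method)
}

#' @export
print.pair_scores <- function(x, n = 10L, ...) {
  cat(sprintf("pair_scores: %d pairs of %d SNPs, method = %s\n",
              nrow(x), attr(x, "n_snps"), attr(x, "method")))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more pairs\n", nrow(x) - n))
  invisible(x)
}

#' Write a ranked pair list as TSV
#'
#' Columns \code{snp_i}, \code{snp_j}, \code{score}, \code{method}, in
#' ranking order (descending score, lexicographic tie-break).
#'
#' @param scores a \code{pair_scores}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_pair_scores <- function(scores, path) {
  stopifnot(inherits(scores, "pair_scores"))
  df <- data.frame(snp_i = scores$snp_i, snp_j = scores$snp_j,
                   score = scores$score,
                   method = attr(scores, "method"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
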