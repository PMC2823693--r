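# Two-locus disease models.
#
# Genotype encoding, fixed package-wide: 0 = homozygous major (AA),
# 1 = heterozygous (Aa), 2 = homozygous minor (aa). A two-locus genotype
# cell is the index pair (gA, gB); 3x3 tables are stored with rows AA/Aa/aa
# (locus A) and columns BB/Bb/bb (locus B).

GENO_LABELS_A <- c("AA", "Aa", "aa")
GENO_LABELS_B <- c("BB", "Bb", "bb")

# Penetrance tables of the six simulation models. All six are *pure*
# epistasis models: the HWE-weighted penetrance is constant within every
# row and every column of the table, so neither locus carries a marginal
# association with the disease and the whole signal lives in the two-locus
# combination. (This is the defining property of the simulation protocol
# these models emulate; without it, SNPs from two different embedded pairs
# would associate with each other through their shared marginal effects
# and flood the evaluation with spurious cross-pairs.)
#
#   model 1: classic XOR table at p = q = 0.5 - penetrance 0.10 when
#            exactly one locus is heterozygous (AABb, AaBB, Aabb, aaBb),
#            0 elsewhere; prevalence 0.05;
#   model 2: classic "ZZ" table at p = q = 0.5 - 0.10 on the AAbb / aaBB
#            corners, 0.05 on AaBb; prevalence 0.025;
#   models 3-6: pure tables at minor allele frequencies 0.25 and 0.1 built
#            by the rank-one construction below, alternating the "edges
#            high / centre zero" and "corners+centre high / edges zero"
#            shapes; prevalence 0.10 each.
.xor_table <- function(f) {
  t <- matrix(0, 3, 3, dimnames = list(GENO_LABELS_A, GENO_LABELS_B))
  t["AA", "Bb"] <- f
  t["Aa", "BB"] <- f
  t["Aa", "bb"] <- f
  t["aa", "Bb"] <- f
  t
}

.zz_table <- function(f_corner, f_center) {
  t <- matrix(0, 3, 3, dimnames = list(GENO_LABELS_A, GENO_LABELS_B))
  t["AA", "bb"] <- f_corner
  t["aa", "BB"] <- f_corner
  t["Aa", "Bb"] <- f_center
  t
}

# Pure-epistasis table at equal allele frequencies p (major) for both loci:
# f(i, j) = K + d * g[i] * g[j], with g = (1, t, 1) chosen orthogonal to
# the HWE genotype probabilities (sum_i a_i g_i = 0). Any such table has
# constant HWE-weighted row and column penetrance K, i.e. zero marginal
# effect at either locus and prevalence exactly K. `d` is set so that one
# cell class hits penetrance 0:
#   shape "corners": heterozygous-homozygous cells are 0 (disease needs
#                    both loci homozygous, or both heterozygous);
#   shape "edges":   the doubly-heterozygous centre is 0 (disease needs
#                    exactly one heterozygous locus) - an XOR-like table.
.pure_table <- function(p, K, shape = c("corners", "edges")) {
  shape <- match.arg(shape)
  a <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  t_ <- -(a[1] + a[3]) / a[2]
  g <- c(1, t_, 1)
  d <- switch(shape,
              corners = -K / t_,          # zeroes the hom-het edges
              edges = -K / t_^2)          # zeroes the het-het centre
  tab <- K + d * outer(g, g)
  tab[abs(tab) < 1e-12] <- 0
  dimnames(tab) <- list(GENO_LABELS_A, GENO_LABELS_B)
  stopifnot(all(tab >= 0), all(tab <= 1))
  tab
}

.EPI_MODELS <- list(
  list(id = 1L, table = .xor_table(0.10),      p = 0.50, q = 0.50),
  list(id = 2L, table = .zz_table(0.10, 0.05), p = 0.50, q = 0.50),
  list(id = 3L, table = .pure_table(0.75, 0.10, "edges"),   p = 0.75, q = 0.75),
  list(id = 4L, table = .pure_table(0.75, 0.10, "corners"), p = 0.75, q = 0.75),
  list(id = 5L, table = .pure_table(0.90, 0.10, "edges"),   p = 0.90, q = 0.90),
  list(id = 6L, table = .pure_table(0.90, 0.10, "corners"), p = 0.90, q = 0.90)
)

#' Two-locus epistasis penetrance models
#'
#' Returns one of the six two-locus penetrance models used by the simulator.
#' A penetrance model gives, for each of the nine genotype combinations of
#' two biallelic SNPs, the probability that a carrier expresses the disease.
#' All six models are "pure" epistasis models: neither locus carries a
#' marginal full-penetrance effect, the signal lives in the combination.
#'
#' Model 1 assigns penetrance 0.10 to genotypes AABb, AaBB, Aabb and aaBb
#' and 0 to all others, with allele frequencies p = q = 0.5; its population
#' prevalence under Hardy-Weinberg proportions is 0.05.
#'
#' @param id integer model identifier, 1 to 6.
#' @return An object of class \code{penetrance_model}: a list with elements
#'   \code{id}, \code{table} (3x3 penetrance matrix, rows AA/Aa/aa for locus
#'   A, columns BB/Bb/bb for locus B), \code{p} and \code{q} (frequencies of
#'   the A and B alleles).
#' @seealso [model_prevalence()], [risk_partition_models()]
#' @examples
#' m <- epistasis_model(1)
#' m$table["AA", "Bb"]   # 0.10
#' model_prevalence(m)   # 0.05
#' @export
epistasis_model <- function(id) {
  if (!is.numeric(id) || length(id) != 1L || is.na(id) ||
      id != as.integer(id) || id < 1 || id > 6) {
    stop_config("unknown epistasis model id: must be an integer in 1..6")
  }
  m <- .EPI_MODELS[[as.integer(id)]]
  structure(m, class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("Two-locus penetrance model %d (p = %.2f, q = %.2f)\n",
              x$id, x$p, x$q))
  print(x$table)
  cat(sprintf("Population prevalence under HWE: %.4f\n",
              model_prevalence(x)))
  invisible(x)
}

# Hardy-Weinberg genotype probabilities for allele frequency p of the major
# allele: (p^2, 2p(1-p), (1-p)^2) over genotypes (0, 1, 2).
hwe_probs <- function(p) {
  stopifnot(p > 0, p < 1)
  c(p^2, 2 * p * (1 - p), (1 - p)^2)
}

#' Population disease prevalence of a penetrance model
#'
#' Sum over the nine two-locus genotype cells of penetrance times the
#' Hardy-Weinberg probability of the cell, i.e. the marginal disease
#' probability the simulator's sampler operates at.
#'
#' @param model a \code{penetrance_model}.
#' @return prevalence in (0, 1).
#' @export
model_prevalence <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  sum(outer(hwe_probs(model$p), hwe_probs(model$q)) * model$table)
}

#' Single-high-risk-cell disease models
#'
#' The nine simple two-SNP disease models used by the HFCC-like score: each
#' model designates exactly one of the nine two-locus genotype combinations
#' as high-risk, and together the nine models cover all combinations.
#' Enumeration is row-major over (genotype at A, genotype at B).
#'
#' @return list of 9 objects of class \code{risk_model}, each a list with
#'   \code{id} and \code{high_risk} (a cell as \code{c(gA, gB)} in 0..2).
#' @seealso [hfcc_score()]
#' @export
risk_partition_models <- function() {
  cells <- expand.grid(gB = 0:2, gA = 0:2)[, c("gA", "gB")]  # row-major in gA
  lapply(seq_len(nrow(cells)), function(i) {
    structure(list(id = i,
                   high_risk = c(cells$gA[i], cells$gB[i])),
              class = "risk_model")
  })
}

#' Write penetrance tables as a plain-text dump
#'
#' One 3x3 block per model, for documentation and eyeballing.
#'
#' @param path output file path.
#' @param ids model ids to dump (default all six).
#' @return \code{path}, invisibly.
#' @export
write_model_tables <- function(path, ids = 1:6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    m <- epistasis_model(id)
    writeLines(sprintf("# model %d  p=%.2f q=%.2f", m$id, m$p, m$q), con)
    utils::write.table(format(m$table, digits = 4), con, quote = FALSE,
                       col.names = NA, sep = "\t")
    writeLines("", con)
  }
  invisible(path)
}
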