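# Case-control genotype data sets and their plain-text serialisations.

#' Construct a case-control genotype data set
#'
#' The package's central data container: a samples x SNPs genotype matrix
#' (entries 0/1/2, \code{NA} for missing), a binary phenotype, SNP
#' identifiers, and a ground-truth manifest recording which SNP pairs were
#' embedded as true interactions and which SNP columns were permuted.
#'
#' @param genotypes integer matrix, samples x SNPs, entries in
#'   \{0, 1, 2, NA\}.
#' @param phenotype vector of 0 (control) / 1 (case), length \code{nrow(genotypes)}.
#' @param snp_ids character identifiers for the SNP columns; defaults to
#'   \code{snp1..snpM}.
#' @param sample_ids character identifiers for the rows.
#' @param truth a \code{truth_manifest}, see [truth_manifest()].
#' @return object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(genotypes, phenotype,
                             snp_ids = NULL, sample_ids = NULL,
                             truth = truth_manifest()) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- NULL
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes)) {
    stop_input("phenotype length must equal the genotype row count")
  }
  if (!all(phenotype %in% c(0L, 1L))) {
    stop_input("phenotype entries must be 0 (control) or 1 (case)")
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop_input("non-missing genotype entries must be in {0, 1, 2}")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(genotypes)))
  stopifnot(length(snp_ids) == ncol(genotypes),
            length(sample_ids) == nrow(genotypes))
  validate_truth(truth, ncol(genotypes))
  structure(list(genotypes = genotypes,
                 phenotype = phenotype,
                 snp_ids = as.character(snp_ids),
                 sample_ids = as.character(sample_ids),
                 truth = truth),
            class = "genotype_dataset")
}

#' Ground-truth manifest of a simulated or permuted data set
#'
#' Records the embedded true interactions (as unordered SNP-index pairs with
#' the epistasis model that generated each) and the SNP columns whose values
#' were permuted to destroy any association. A SNP may appear in at most one
#' interacting pair, and permuted SNPs never appear in an interacting pair.
#'
#' @param pairs two-column integer matrix of SNP indices, one row per
#'   embedded pair (unordered; stored with first index < second).
#' @param model integer vector, epistasis model id per pair.
#' @param permuted integer vector of permuted SNP column indices.
#' @return object of class \code{truth_manifest}.
#' @export
truth_manifest <- function(pairs = matrix(integer(), 0, 2),
                           model = integer(), permuted = integer()) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    pairs <- t(apply(pairs, 1, sort))
    pairs <- matrix(as.integer(pairs), ncol = 2)
  }
  tm <- structure(list(pairs = pairs,
                       model = as.integer(model),
                       permuted = sort(as.integer(permuted))),
                  class = "truth_manifest")
  validate_truth(tm)
  tm
}

validate_truth <- function(truth, n_snps = NULL) {
  stopifnot(inherits(truth, "truth_manifest"))
  p <- truth$pairs
  if (nrow(p) != length(truth$model)) {
    stop_input("truth manifest: one model id is required per pair")
  }
  idx <- as.vector(p)
  if (anyDuplicated(idx)) {
    stop_input("truth manifest: a SNP may belong to at most one pair")
  }
  if (length(intersect(idx, truth$permuted))) {
    stop_input("truth manifest: interacting and permuted SNPs must be disjoint")
  }
  if (!is.null(n_snps) && length(c(idx, truth$permuted)) &&
      max(c(idx, truth$permuted)) > n_snps) {
    stop_input("truth manifest references SNP indices beyond the data set")
  }
  invisible(truth)
}

n_samples <- function(data) nrow(data$genotypes)
n_snps <- function(data) ncol(data$genotypes)
case_idx <- function(data) which(data$phenotype == 1L)
control_idx <- function(data) which(data$phenotype == 0L)

# Row-subset a data set (truth refers to SNP columns, so it is unchanged).
subset_samples <- function(data, idx) {
  genotype_dataset(data$genotypes[idx, , drop = FALSE],
                   data$phenotype[idx],
                   snp_ids = data$snp_ids,
                   sample_ids = data$sample_ids[idx],
                   truth = data$truth)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls) x %d SNPs\n",
              n_samples(x), sum(x$phenotype == 1L), sum(x$phenotype == 0L),
              n_snps(x)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  cat(sprintf("  truth: %d embedded interacting pair(s), %d permuted SNP(s)\n",
              nrow(x$truth$pairs), length(x$truth$permuted)))
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  print(object)
  if (nrow(object$truth$pairs)) {
    cat("  embedded pairs (model: snpA-snpB):\n")
    for (i in seq_len(nrow(object$truth$pairs))) {
      cat(sprintf("    m%d: %s-%s\n", object$truth$model[i],
                  object$snp_ids[object$truth$pairs[i, 1]],
                  object$snp_ids[object$truth$pairs[i, 2]]))
    }
  }
  invisible(object)
}

# ---- plain-text I/O ---------------------------------------------------------

#' Write / read a genotype data set as TSV
#'
#' Format: header row with \code{sample_id}, \code{phenotype} and the SNP
#' ids; one row per sample; phenotype coded 0 = control, 1 = case; genotypes
#' 0/1/2 with missing values written as \code{NA}.
#'
#' @param data a \code{genotype_dataset}.
#' @param path file path.
#' @return \code{write_genotypes}: \code{path}, invisibly.
#' @export
write_genotypes <- function(data, path) {
  stopifnot(inherits(data, "genotype_dataset"))
  df <- data.frame(sample_id = data$sample_ids,
                   phenotype = data$phenotype,
                   data$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:2)] <- data$snp_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param truth optional \code{truth_manifest} to attach on read (e.g. from
#'   [read_truth()]).
#' @return \code{read_genotypes}: a \code{genotype_dataset}.
#' @export
read_genotypes <- function(path, truth = truth_manifest()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("sample_id", "phenotype"))) {
    stop_input("genotype TSV must start with sample_id and phenotype columns")
  }
  genotype_dataset(as.matrix(df[, -(1:2), drop = FALSE]),
                   df$phenotype,
                   snp_ids = names(df)[-(1:2)],
                   sample_ids = df$sample_id,
                   truth = truth)
}

#' Write a data set in minimal PLINK ped/map text format
#'
#' Biallelic coding with alleles \code{A}/\code{a} per SNP: genotype 0 is
#' written \code{A A}, 1 is \code{A a}, 2 is \code{a a}, missing is
#' \code{0 0}. Phenotype uses PLINK's 1 = control, 2 = case. The map file
#' places all SNPs on chromosome 1 at consecutive positions.
#'
#' @param data a \code{genotype_dataset}.
#' @param prefix output prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @return the two file paths, invisibly.
#' @export
write_ped_map <- function(data, prefix) {
  stopifnot(inherits(data, "genotype_dataset"))
  g <- data$genotypes
  allele_strings <- c("A A", "A a", "a a")
  gs <- matrix("0 0", nrow(g), ncol(g))
  for (v in 0:2) gs[!is.na(g) & g == v] <- allele_strings[v + 1]
  ped <- cbind(data$sample_ids, data$sample_ids, "0", "0", "0",
               as.character(data$phenotype + 1L), gs)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(ped, ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(chr = 1L, id = data$snp_ids, cm = 0,
                    bp = seq_len(n_snps(data)))
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Write / read a truth manifest as JSON
#'
#' Pairs are stored by SNP id together with the epistasis model per pair,
#' plus the list of permuted SNP ids.
#'
#' @param truth a \code{truth_manifest}.
#' @param snp_ids SNP id vector of the data set the manifest refers to.
#' @param path file path.
#' @return \code{write_truth}: \code{path} invisibly; \code{read_truth}: a
#'   \code{truth_manifest} (indices resolved against \code{snp_ids}).
#' @export
write_truth <- function(truth, snp_ids, path) {
  validate_truth(truth, length(snp_ids))
  obj <- list(
    interacting_pairs = if (nrow(truth$pairs)) {
      lapply(seq_len(nrow(truth$pairs)), function(i) {
        list(snp_a = snp_ids[truth$pairs[i, 1]],
             snp_b = snp_ids[truth$pairs[i, 2]],
             model = truth$model[i])
      })
    } else list(),
    permuted_snps = as.list(snp_ids[truth$permuted])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path, snp_ids) {
  obj <- jsonlite::read_json(path)
  pairs <- matrix(integer(), 0, 2)
  model <- integer()
  for (p in obj$interacting_pairs) {
    ia <- match(p$snp_a, snp_ids)
    ib <- match(p$snp_b, snp_ids)
    if (is.na(ia) || is.na(ib)) stop_input("truth JSON references unknown SNP id")
    pairs <- rbind(pairs, c(ia, ib))
    model <- c(model, as.integer(p$model))
  }
  permuted <- match(unlist(obj$permuted_snps), snp_ids)
  if (anyNA(permuted)) stop_input("truth JSON references unknown SNP id")
  truth_manifest(pairs, model, as.integer(permuted))
}
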