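#' Cohort genotype container
#'
#' A `genotype_matrix` bundles a samples-by-SNPs dosage matrix with the SNP
#' map and per-sample metadata. Genotypes are coded as the count of
#' `allele_b` (0, 1, 2); missing calls are `NA` (never a numeric sentinel).
#'
#' @param calls integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}. Row names are ignored (sample ids come from `samples`).
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`. Positions are 1-based base-pair coordinates and must be
#'   strictly increasing within each chromosome.
#' @param samples data.frame with column `sample_id` and optional columns
#'   `population`, `platform`, `group`, `sex`. Missing optional columns are
#'   filled with `NA`.
#'
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `snps`, `samples`.
#' @examples
#' g <- genotype_matrix(
#'   calls = matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2, byrow = TRUE),
#'   snps = data.frame(snp_id = c("s1", "s2", "s3"), chrom = "1",
#'                     pos = c(100L, 200L, 300L),
#'                     allele_a = "A", allele_b = "G"),
#'   samples = data.frame(sample_id = c("i1", "i2"), population = "P1")
#' )
#' call_rate(g)
#' @export
genotype_matrix <- function(calls, snps, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("population", "platform", "group", "sex")) {
    if (is.null(samples[[col]])) {
      samples[[col]] <- rep(NA_character_, nrow(samples))
    }
  }
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(req %in% names(snps))) {
    stop("snps must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(calls) != nrow(samples)) {
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  }
  if (ncol(calls) != nrow(snps)) {
    stop("calls has ", ncol(calls), " columns but snps has ", nrow(snps))
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  if (nrow(snps) > 1) {
    for (ch in unique(snps$chrom)) {
      p <- snps$pos[snps$chrom == ch]
      if (length(p) > 1 && any(diff(p) <= 0)) {
        stop("positions not strictly increasing on chromosome ", ch)
      }
    }
  }
  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = " "), "\n")
  pops <- table(x$samples$population, useNA = "ifany")
  cat("  populations:",
      paste(names(pops), pops, sep = "=", collapse = " "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname genotype_matrix
#' @export
n_snps <- function(g) ncol(g$calls)

#' Per-SNP call rate
#'
#' Fraction of non-missing genotypes per SNP, optionally restricted to a
#' subset of samples.
#'
#' @param g a [genotype_matrix()].
#' @param samples optional logical/integer/character index of samples.
#' @return Numeric vector, one call rate per SNP, named by snp_id.
#' @export
call_rate <- function(g, samples = NULL) {
  m <- g$calls
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  1 - colSums(is.na(m)) / nrow(m)   # exactly 1 - missing/samples
}

#' Per-SNP allele frequency of allele_b
#'
#' @param g a [genotype_matrix()].
#' @param samples optional sample subset.
#' @return Frequency of `allele_b` among called alleles per SNP (`NaN` where
#'   no calls).
#' @export
allele_freq <- function(g, samples = NULL) {
  m <- g$calls
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  colMeans(m, na.rm = TRUE) / 2
}

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param samples,snps logical/integer/character indices (character values
#'   match `sample_id` / `snp_id`); `NULL` keeps everything.
#' @return A new `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(g)) else samples
  if (is.character(si)) si <- match(si, g$samples$sample_id)
  vi <- if (is.null(snps)) seq_len(n_snps(g)) else snps
  if (is.character(vi)) vi <- match(vi, g$snps$snp_id)
  genotype_matrix(g$calls[si, vi, drop = FALSE],
                  g$snps[vi, , drop = FALSE],
                  g$samples[si, , drop = FALSE])
}
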