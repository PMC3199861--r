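#' Rare-SNP criterion
#'
#' A SNP is "rare" when the exact (Clopper-Pearson) confidence interval for
#' its minor-allele frequency lies entirely below `maf_bound`.
#'
#' @param maf_bound MAF bound, default 0.01.
#' @param confidence CI level, default 0.95.
#' @return list of class `rare_criterion`.
#' @export
rare_criterion <- function(maf_bound = 0.01, confidence = 0.95) {
  stopifnot(maf_bound > 0, maf_bound < 0.5, confidence > 0, confidence < 1)
  structure(list(maf_bound = maf_bound, confidence = confidence),
            class = "rare_criterion")
}

#' Maximum minor-allele count still classified as rare
#'
#' Largest count k such that the Clopper-Pearson upper confidence bound for
#' k of `n_chromosomes` observed alleles is below the MAF bound. At 2 x 977
#' chromosomes this is 10 ("rare" means fewer than 11 minor alleles); at
#' 2 x 532 it is 4.
#'
#' @param n_chromosomes number of observed alleles (2 x called genotypes).
#' @param crit a [rare_criterion()].
#' @return Integer threshold, or `NA` if even a count of zero is not rare
#'   (upper bound for k = 0 is `1 - ((1-conf)/2)^(1/n)`).
#' @export
rare_count_threshold <- function(n_chromosomes, crit = rare_criterion()) {
  stopifnot(n_chromosomes >= 2)
  upper <- function(k) {
    stats::qbeta(1 - (1 - crit$confidence) / 2, k + 1, n_chromosomes - k)
  }
  if (upper(0) >= crit$maf_bound) return(NA_integer_)
  k <- 0L
  while (k + 1L <= n_chromosomes / 2 && upper(k + 1L) < crit$maf_bound) {
    k <- k + 1L
  }
  k
}

#' Classify SNPs as rare by the exact-CI criterion
#'
#' A SNP is rare iff its observed minor-allele count among called genotypes
#' is at most [rare_count_threshold()] evaluated at the realized number of
#' called chromosomes at that SNP (so missingness lowers the bar
#' SNP-by-SNP).
#'
#' @param g a [genotype_matrix()].
#' @param crit a [rare_criterion()].
#' @param samples optional sample subset (cohort restriction).
#' @return data.frame with `snp_id`, `mac` (minor-allele count),
#'   `n_chromosomes`, `rare` (logical).
#' @export
classify_rare <- function(g, crit = rare_criterion(), samples = NULL) {
  m <- g$calls
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  n_called <- colSums(!is.na(m))
  nb <- colSums(m, na.rm = TRUE)
  nchr <- 2 * n_called
  mac <- pmin(nb, nchr - nb)
  thr_lookup <- vapply(sort(unique(nchr[nchr >= 2])), function(nc) {
    c(nc, rare_count_threshold(nc, crit))
  }, numeric(2))
  thr <- rep(NA_integer_, length(nchr))
  if (length(thr_lookup)) {
    thr <- thr_lookup[2, match(nchr, thr_lookup[1, ])]
  }
  data.frame(snp_id = g$snps$snp_id, mac = mac, n_chromosomes = nchr,
             rare = !is.na(thr) & mac <= thr, stringsAsFactors = FALSE)
}

#' Compare rare-SNP odds between two cohorts
#'
#' Fisher's exact two-sided test on the 2x2 (rare / non-rare) x (cohort A /
#' cohort B) table, with the sample odds ratio. The exact p is computed by
#' direct hypergeometric summation (minimum-likelihood two-sided
#' definition), which handles genome-scale tables.
#'
#' @param count_a,count_b rare-SNP counts in the two cohorts.
#' @param total_snps number of SNPs assessed in each cohort.
#' @return list with `or` and `p`.
#' @export
compare_rare_odds <- function(count_a, total_snps, count_b) {
  stopifnot(count_a <= total_snps, count_b <= total_snps)
  a <- count_a; b <- total_snps - count_a
  c_ <- count_b; d <- total_snps - count_b
  p <- exact_test_2x2(a, b, c_, d)
  or <- if (c_ == 0) Inf else (a / b) / (c_ / d)
  list(or = or, p = p)
}
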