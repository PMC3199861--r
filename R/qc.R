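#' SNP quality-control thresholds
#'
#' @param min_call_rate combined-cohort call-rate threshold (strict `<`
#'   fails), default 0.95.
#' @param hwe_p stratified Hardy-Weinberg p-value threshold, default 1e-6.
#' @param platform_p between-platform allele-frequency p threshold, default
#'   1e-7.
#' @param pca_call_rate stricter call-rate threshold used for PCA input,
#'   default 0.99.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, hwe_p = 1e-6,
                          platform_p = 1e-7, pca_call_rate = 0.99) {
  vals <- c(min_call_rate, hwe_p, platform_p, pca_call_rate)
  stopifnot(all(vals > 0), all(vals <= 1))
  structure(list(min_call_rate = min_call_rate, hwe_p = hwe_p,
                 platform_p = platform_p, pca_call_rate = pca_call_rate),
            class = "qc_thresholds")
}

#' Combined-cohort call-rate filter
#'
#' A SNP fails iff its call rate over all samples combined is strictly below
#' `min_call_rate` (a SNP with exactly the threshold rate passes).
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return Character vector of failing snp_ids.
#' @export
call_rate_filter <- function(g, thresholds = qc_thresholds()) {
  cr <- call_rate(g)
  g$snps$snp_id[cr < thresholds$min_call_rate]
}

# Levene exact-null moments for the heterozygote count given the allele
# count: E[H] = nA*nB/(2N-1), E[H(H-1)] = nA(nA-1)nB(nB-1)/((2N-1)(2N-3))
levene_moments <- function(nA, nB) {
  tot <- nA + nB
  eh <- nA * nB / (tot - 1)
  ehh <- ifelse(tot >= 4, nA * (nA - 1) * nB * (nB - 1) / ((tot - 1) * (tot - 3)), 0)
  list(mean = eh, var = pmax(ehh + eh - eh^2, 0))
}

#' Stratified Hardy-Weinberg test
#'
#' Per stratum, the signed heterozygote deficit (observed het count minus
#' its exact-null expectation given the stratum allele counts) is computed
#' together with its exact-null variance; deficits are summed over strata and
#' referred to a normal: Z = sum(d_s) / sqrt(sum(Var_s)), two-sided p.
#' Pooling-robust: strata in HWE at different allele frequencies do not
#' produce a Wahlund rejection. With a single stratum this is the classic
#' one-population HWE score test.
#'
#' @param g a [genotype_matrix()].
#' @param strata vector of stratum labels per sample (default: population).
#' @return data.frame with `snp_id`, `z`, `p`, and `flag` (`"monomorphic"`
#'   where no stratum is polymorphic, in which case p = 1).
#' @export
stratified_hwe_test <- function(g, strata = g$samples$population) {
  stopifnot(length(strata) == n_samples(g))
  m <- n_snps(g)
  d_sum <- numeric(m)
  v_sum <- numeric(m)
  for (s in unique(strata)) {
    rows <- which(strata == s)
    sub <- g$calls[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    nB <- colSums(sub, na.rm = TRUE)          # allele_b count
    nA <- 2 * n_called - nB
    o_het <- colSums(sub == 1L, na.rm = TRUE)
    mom <- levene_moments(nA, nB)
    ok <- n_called >= 2 & nA > 0 & nB > 0
    d_sum[ok] <- d_sum[ok] + (o_het[ok] - mom$mean[ok])
    v_sum[ok] <- v_sum[ok] + mom$var[ok]
  }
  z <- ifelse(v_sum > 0, d_sum / sqrt(v_sum), 0)
  p <- ifelse(v_sum > 0, 2 * stats::pnorm(-abs(z)), 1)
  data.frame(snp_id = g$snps$snp_id, z = z, p = p,
             flag = ifelse(v_sum > 0, "", "monomorphic"),
             stringsAsFactors = FALSE)
}

#' Between-platform allele-frequency test
#'
#' Two-sided test on the 2x2 allele-count table between two genotyping
#' platforms within one population; Fisher's exact test where any expected
#' cell count is below 5, chi-square (no continuity correction) otherwise.
#' SNPs typed on one platform only get `NA` and are logged in the
#' `skipped` attribute.
#'
#' @param g a [genotype_matrix()].
#' @param within population label to restrict to (`NULL` = all samples).
#' @return data.frame with `snp_id`, `p`; monomorphic-on-both tables give
#'   p = 1.
#' @export
platform_frequency_test <- function(g, within = NULL) {
  rows <- seq_len(n_samples(g))
  if (!is.null(within)) rows <- which(g$samples$population == within)
  plat <- g$samples$platform[rows]
  labs <- unique(plat[!is.na(plat)])
  if (length(labs) < 2) stop("need two platform labels within the population")
  labs <- labs[1:2]
  counts <- lapply(labs, function(pl) {
    sub <- g$calls[rows[plat == pl], , drop = FALSE]
    nc <- colSums(!is.na(sub))
    nb <- colSums(sub, na.rm = TRUE)
    cbind(b = nb, a = 2 * nc - nb)
  })
  m <- n_snps(g)
  p <- rep(NA_real_, m)
  t1 <- counts[[1]]
  t2 <- counts[[2]]
  tot1 <- rowSums(t1)
  tot2 <- rowSums(t2)
  skipped <- tot1 == 0 | tot2 == 0
  colb <- t1[, "b"] + t2[, "b"]
  cola <- t1[, "a"] + t2[, "a"]
  tot <- tot1 + tot2
  mono <- !skipped & (colb == 0 | cola == 0)
  p[mono] <- 1                            # monomorphic on both platforms
  todo <- !skipped & !mono
  # vectorized Pearson chi-square on the 2x2 allele-count table
  min_exp <- pmin(tot1 * colb, tot1 * cola, tot2 * colb, tot2 * cola) / tot
  chi <- (t1[, "b"] * t2[, "a"] - t1[, "a"] * t2[, "b"])^2 * tot /
    (tot1 * tot2 * colb * cola)
  use_chi <- todo & min_exp >= 5
  p[use_chi] <- stats::pchisq(chi[use_chi], 1, lower.tail = FALSE)
  for (j in which(todo & min_exp < 5)) {
    p[j] <- exact_test_2x2(t1[j, "b"], t1[j, "a"], t2[j, "b"], t2[j, "a"])
  }
  res <- data.frame(snp_id = g$snps$snp_id, p = p, stringsAsFactors = FALSE)
  attr(res, "skipped") <- g$snps$snp_id[skipped]
  res
}

# two-sided exact p for a 2x2 table by direct hypergeometric summation
# (minimum-likelihood definition, as stats::fisher.test); works for margins
# far beyond fisher.test's workspace limits
exact_test_2x2 <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) return(1)
  x <- max(0, k - m2):min(k, m1)
  dv <- stats::dhyper(x, m1, m2, k)
  sum(dv[dv <= stats::dhyper(a, m1, m2, k) * (1 + 1e-7)])
}

#' Apply all SNP QC filters
#'
#' Removes the union of the call-rate, stratified-HWE, and platform
#' frequency failure sets, with per-criterion and union accounting (a SNP
#' violating several criteria is only removed once).
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param platform_within population label for the platform test; `NULL`
#'   skips the platform test (e.g. single-platform cohorts).
#' @return `list(genotypes =, report =)` where the report holds `n_input`,
#'   the three failure id sets, `n_removed_union`, `n_retained`.
#' @export
apply_qc <- function(g, thresholds = qc_thresholds(), platform_within = NULL) {
  fail_cr <- call_rate_filter(g, thresholds)
  hwe <- stratified_hwe_test(g)
  fail_hwe <- hwe$snp_id[hwe$p < thresholds$hwe_p]
  fail_plat <- character(0)
  if (!is.null(platform_within)) {
    pt <- platform_frequency_test(g, within = platform_within)
    fail_plat <- pt$snp_id[!is.na(pt$p) & pt$p < thresholds$platform_p]
  }
  union_set <- union(union(fail_cr, fail_hwe), fail_plat)
  if (length(union_set) == n_snps(g)) stop("QC removed every SNP")
  keep <- !(g$snps$snp_id %in% union_set)
  report <- list(n_input = n_snps(g),
                 removed_call_rate = fail_cr,
                 removed_hwe = fail_hwe,
                 removed_platform = fail_plat,
                 n_removed_union = length(union_set),
                 n_retained = sum(keep))
  list(genotypes = subset_genotypes(g, snps = which(keep)), report = report)
}
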