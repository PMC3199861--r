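#' Pairwise relatedness estimation
#'
#' Allele-frequency-standardised genomic relatedness: for a pair (i, j),
#' r_ij is the mean over SNPs called in both individuals of
#' `(x_i - 2p)(x_j - 2p) / (2p(1-p))`, with p the in-sample frequency of the
#' counted allele. Only SNPs with MAF >= `min_maf` contribute. Expectation
#' is 0.5 for parent-offspring pairs, 0.25 for second degree, 0 for
#' unrelated pairs; the diagonal estimates 1 + F.
#'
#' By default frequencies are computed within each population separately
#' (standardisation then reflects the individual's own population); set
#' `by_population = FALSE` to use pooled frequencies.
#'
#' @param g a [genotype_matrix()] with >= 2 samples and >= 100 polymorphic
#'   SNPs.
#' @param min_maf minimum minor-allele frequency for a SNP to contribute
#'   (default 0.01).
#' @param by_population standardise within population labels (default TRUE
#'   when labels are present).
#' @return Symmetric matrix of class `relatedness_matrix` with sample ids as
#'   dimnames.
#' @export
estimate_relatedness <- function(g, min_maf = 0.01,
                                 by_population = !all(is.na(g$samples$population))) {
  if (n_samples(g) < 2) stop("need at least two samples")
  pops <- if (by_population) g$samples$population else rep("all", n_samples(g))
  Z <- matrix(0, n_samples(g), n_snps(g))
  keep <- rep(FALSE, n_snps(g))
  for (pp in unique(pops)) {
    rows <- which(pops == pp)
    p <- allele_freq(g, rows)
    ok <- !is.na(p) & pmin(p, 1 - p) >= min_maf
    keep <- keep | ok
    x <- g$calls[rows, , drop = FALSE]
    zz <- sweep(x, 2, 2 * p, "-")
    zz <- sweep(zz, 2, sqrt(2 * p * (1 - p)), "/")
    zz[, !ok] <- NA
    Z[rows, ] <- zz
  }
  if (sum(keep) < 100) stop("fewer than 100 polymorphic SNPs with MAF >= ",
                            min_maf)
  M <- !is.na(Z)
  Z[!M] <- 0
  num <- tcrossprod(Z)
  den <- tcrossprod(M * 1)
  R <- num / den
  R[den == 0] <- NA
  dimnames(R) <- list(g$samples$sample_id, g$samples$sample_id)
  class(R) <- c("relatedness_matrix", class(R))
  R
}

#' Greedy unrelated-subset selection
#'
#' Step-by-step removal of the individual with the highest number of
#' relationships above the cutoff, until no pair with relatedness > cutoff
#' remains (strict inequality: a pair at exactly the cutoff is unrelated).
#' Ties are broken by the higher maximum pairwise estimate, then by
#' lexicographic sample id.
#'
#' @param R a relatedness matrix (as from [estimate_relatedness()]).
#' @param cutoff relatedness threshold, default 0.2.
#' @return Character vector of retained sample ids.
#' @export
select_unrelated <- function(R, cutoff = 0.2) {
  ids <- rownames(R)
  A <- !is.na(R) & R > cutoff
  diag(A) <- FALSE
  alive <- rep(TRUE, nrow(A))
  repeat {
    deg <- rowSums(A[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      mx <- vapply(cand, function(i) max(R[i, alive & A[i, ]]), 0)
      cand <- cand[mx == max(mx)]
      if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
    }
    alive[cand[1]] <- FALSE
    A[cand[1], ] <- FALSE
    A[, cand[1]] <- FALSE
  }
  ids[alive]
}

#' Distribution of pairwise relatedness estimates
#'
#' Counts of unordered pairs whose estimate strictly exceeds each lower
#' bound, per population.
#'
#' @param R a relatedness matrix.
#' @param lower_bounds thresholds, default `c(0.1, 0.2, 0.4, 0.6)`.
#' @return data.frame with `lower_bound`, `n_pairs`, `total_pairs`.
#' @export
pair_distribution <- function(R, lower_bounds = c(0.1, 0.2, 0.4, 0.6)) {
  v <- R[upper.tri(R)]
  n <- nrow(R)
  data.frame(lower_bound = lower_bounds,
             n_pairs = vapply(lower_bounds,
                              function(b) sum(v > b, na.rm = TRUE), 0L),
             total_pairs = n * (n - 1) / 2)
}

#' Odds ratio for encountering a related pair
#'
#' Sample odds ratio between two cohorts for the event "pair exceeds the
#' relatedness bound", with a Woolf (log-OR normal) confidence interval.
#' With zero related pairs in the reference cohort the OR is unbounded
#' (`Inf`) and only the lower confidence limit is reported. For small
#' tables the conditional-MLE OR from [stats::fisher.test()] is also
#' reported (`NA` where the table is too large for it).
#'
#' @param count_a,total_a related-pair count and total pairs, cohort A.
#' @param count_b,total_b same for the reference cohort B.
#' @param conf confidence level, default 0.95.
#' @return list with `or`, `ci` (length 2), `or_cmle`.
#' @export
related_pair_odds_ratio <- function(count_a, total_a, count_b, total_b,
                                    conf = 0.95) {
  stopifnot(count_a >= 0, count_b >= 0, total_a > count_a, total_b > count_b)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  a <- count_a; b <- total_a - count_a
  c_ <- count_b; d <- total_b - count_b
  if (count_b == 0) {
    # unbounded OR: one-sided interval from the 0.5-corrected log OR
    lse <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / 0.5 + 1 / (d + 0.5))
    lo <- exp(log(((a + 0.5) / (b + 0.5)) / (0.5 / (d + 0.5))) - z * lse)
    return(list(or = Inf, ci = c(lo, Inf), or_cmle = NA_real_))
  }
  or <- (a / b) / (c_ / d)
  lse <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * z * lse)
  or_cmle <- tryCatch(
    unname(stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                     byrow = TRUE))$estimate),
    error = function(e) NA_real_)
  list(or = or, ci = ci, or_cmle = or_cmle)
}
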