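# Weir & Cockerham (1984) per-SNP variance components from per-population
# sufficient statistics: sample sizes n_i, allele-b frequencies p_i, and
# heterozygote frequencies h_i (complete-case per SNP). Inputs are matrices
# with one row per SNP and one column per population.
wc_components <- function(n, p, h) {
  r <- ncol(n)
  nbar <- rowMeans(n)
  nsum <- rowSums(n)
  pbar <- rowSums(n * p) / nsum
  hbar <- rowSums(n * h) / nsum
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  nc <- (nsum - rowSums(n^2) / nsum) / (r - 1)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

# single-population within/between-individual components (the r = 1 limit):
# b among individuals within the population, c within individuals
wc_components_within <- function(n, p, h) {
  b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h)
  list(b = b, c = h / 2)
}

# per-SNP sufficient statistics for one set of rows
snp_suffstats <- function(calls, rows) {
  sub <- calls[rows, , drop = FALSE]
  n <- colSums(!is.na(sub))
  nb <- colSums(sub, na.rm = TRUE)
  het <- colSums(sub == 1L, na.rm = TRUE)
  list(n = n, nb = nb, het = het)
}

fis_from_suffstats <- function(n, nb, het) {
  ok <- n >= 2
  p <- nb[ok] / (2 * n[ok])
  comp <- wc_components_within(n[ok], p, het[ok] / n[ok])
  poly <- p > 0 & p < 1
  denom <- sum(comp$b[poly] + comp$c[poly])
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  1 - sum(comp$c[poly]) / denom
}

fst_from_suffstats <- function(n1, nb1, het1, n2, nb2, het2) {
  ok <- n1 >= 2 & n2 >= 2
  n <- cbind(n1[ok], n2[ok])
  p <- cbind(nb1[ok] / (2 * n1[ok]), nb2[ok] / (2 * n2[ok]))
  h <- cbind(het1[ok] / n1[ok], het2[ok] / n2[ok])
  comp <- wc_components(n, p, h)
  # SNPs monomorphic for the same allele in both samples contribute zero to
  # numerator and denominator; only non-finite components are dropped
  informative <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c)
  num <- sum(comp$a[informative])
  den <- sum((comp$a + comp$b + comp$c)[informative])
  if (den == 0) return(NA_real_)
  num / den
}

#' Within-population inbreeding coefficient F_IS
#'
#' Weir-Cockerham unbiased per-SNP components combined over SNPs as a ratio
#' of sums (weighted average): `F_IS = 1 - sum(c) / sum(b + c)`, where b is
#' the among-individual and c the within-individual component. The standard
#' error is the delete-one-individual jackknife, recomputed incrementally
#' from cached per-SNP sufficient statistics.
#'
#' Negative values indicate heterozygote excess; the estimate is -1 when
#' every individual is heterozygous at every SNP.
#'
#' @param g a [genotype_matrix()].
#' @param population population label (default: the only one present).
#' @return list of class `fstat_result`: `statistic`, `estimate`, `se`,
#'   `n_snps`, `n_individuals`.
#' @export
fis <- function(g, population = NULL) {
  rows <- fstat_rows(g, population)
  if (length(rows) < 2) stop("need at least two individuals")
  st <- snp_suffstats(g$calls, rows)
  if (!any(st$nb > 0 & st$nb < 2 * st$n)) stop("no polymorphic SNPs")
  est <- fis_from_suffstats(st$n, st$nb, st$het)
  # delete-one jackknife: subtract individual i's contribution per SNP
  theta_i <- vapply(rows, function(i) {
    x <- g$calls[i, ]
    called <- !is.na(x)
    fis_from_suffstats(st$n - called, st$nb - ifelse(called, x, 0L),
                       st$het - (called & x == 1L))
  }, 0)
  structure(list(statistic = "F_IS", estimate = est,
                 se = jackknife_se_from_values(theta_i),
                 n_snps = sum(st$n >= 2), n_individuals = length(rows)),
            class = "fstat_result")
}

#' Between-population co-ancestry coefficient F_ST
#'
#' Weir-Cockerham theta for a pair of populations: per-SNP variance
#' components a (among populations), b (among individuals within
#' populations), c (within individuals), combined over SNPs as
#' `sum(a) / sum(a + b + c)`. The standard error is the
#' delete-one-individual jackknife (each left-out individual is removed from
#' its own population only).
#'
#' @param g a [genotype_matrix()].
#' @param pop_a,pop_b the two population labels.
#' @return list of class `fstat_result`.
#' @export
fst <- function(g, pop_a, pop_b) {
  rows_a <- which(g$samples$population == pop_a)
  rows_b <- which(g$samples$population == pop_b)
  if (length(rows_a) < 2 || length(rows_b) < 2) {
    stop("each population needs at least two individuals")
  }
  sa <- snp_suffstats(g$calls, rows_a)
  sb <- snp_suffstats(g$calls, rows_b)
  est <- fst_from_suffstats(sa$n, sa$nb, sa$het, sb$n, sb$nb, sb$het)
  jack_one <- function(i, own) {
    x <- g$calls[i, ]
    called <- !is.na(x)
    dn <- ifelse(called, 1L, 0L)
    dnb <- ifelse(called, x, 0L)
    dh <- called & x == 1L
    if (own == "a") {
      fst_from_suffstats(sa$n - dn, sa$nb - dnb, sa$het - dh,
                         sb$n, sb$nb, sb$het)
    } else {
      fst_from_suffstats(sa$n, sa$nb, sa$het,
                         sb$n - dn, sb$nb - dnb, sb$het - dh)
    }
  }
  theta_i <- c(vapply(rows_a, jack_one, 0, own = "a"),
               vapply(rows_b, jack_one, 0, own = "b"))
  structure(list(statistic = "F_ST", estimate = est,
                 se = jackknife_se_from_values(theta_i),
                 n_snps = sum(sa$n >= 2 & sb$n >= 2),
                 n_individuals = length(rows_a) + length(rows_b)),
            class = "fstat_result")
}

fstat_rows <- function(g, population) {
  if (is.null(population)) {
    pops <- unique(g$samples$population)
    if (length(pops) > 1) stop("several populations present; name one")
    seq_len(n_samples(g))
  } else {
    which(g$samples$population == population)
  }
}

jackknife_se_from_values <- function(theta_i) {
  theta_i <- theta_i[is.finite(theta_i)]
  n <- length(theta_i)
  if (n < 3) return(NA_real_)
  sqrt((n - 1) / n * sum((theta_i - mean(theta_i))^2))
}

#' Delete-one-individual jackknife standard error
#'
#' Recomputes a statistic on every leave-one-out subset of individuals and
#' returns `sqrt((n-1)/n * sum((theta_(i) - theta_bar)^2))`. Subsets on
#' which the statistic is undefined (NA/NaN) are skipped with a warning and
#' n adjusted.
#'
#' @param statistic function taking a [genotype_matrix()] and returning a
#'   scalar.
#' @param g a [genotype_matrix()] with at least three samples.
#' @param ... passed on to `statistic`.
#' @return Standard error (scalar).
#' @export
jackknife_se <- function(statistic, g, ...) {
  n <- n_samples(g)
  if (n < 3) stop("need at least three individuals")
  theta_i <- vapply(seq_len(n), function(i) {
    statistic(subset_genotypes(g, samples = setdiff(seq_len(n), i)), ...)
  }, 0)
  if (any(!is.finite(theta_i))) {
    warning(sum(!is.finite(theta_i)), " leave-one-out subsets skipped")
  }
  jackknife_se_from_values(theta_i)
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g (jackknife SE %.3g; %d SNPs, %d individuals)\n",
              x$statistic, x$estimate, x$se, x$n_snps, x$n_individuals))
  invisible(x)
}
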