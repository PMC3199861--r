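# two-locus haplotype-frequency EM from unphased genotypes. g1, g2 are
# dosage vectors (0/1/2, NA allowed); complete-case individuals only.
# Returns frequencies (pAB, pAb, paB, pab) where "A"/"B" denote allele_b at
# the two loci (dosage-counted alleles).
haplotype_em <- function(g1, g2, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  x <- g1[ok]
  y <- g2[ok]
  n <- length(x)
  if (n == 0) return(NULL)
  # genotype-pair counts; only the double heterozygote is phase-ambiguous
  tab <- matrix(tabulate(3L * x + y + 1L, nbins = 9L), 3, 3, byrow = TRUE)
  n_dh <- tab[2, 2]
  # known haplotype counts from unambiguous genotypes
  base_AB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  base_Ab <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  base_aB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  base_ab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  pAB <- (base_AB + n_dh / 2) / (2 * n)
  pAb <- (base_Ab + n_dh / 2) / (2 * n)
  paB <- (base_aB + n_dh / 2) / (2 * n)
  pab <- (base_ab + n_dh / 2) / (2 * n)
  converged <- n_dh == 0
  iter <- 0
  while (!converged && iter < max_iter) {
    iter <- iter + 1
    cis <- pAB * pab
    trans <- pAb * paB
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new_AB <- (base_AB + n_dh * w) / (2 * n)
    new_ab <- (base_ab + n_dh * w) / (2 * n)
    new_Ab <- (base_Ab + n_dh * (1 - w)) / (2 * n)
    new_aB <- (base_aB + n_dh * (1 - w)) / (2 * n)
    converged <- max(abs(c(new_AB - pAB, new_Ab - pAb,
                           new_aB - paB, new_ab - pab))) < tol
    pAB <- new_AB; pAb <- new_Ab; paB <- new_aB; pab <- new_ab
  }
  list(freqs = c(AB = pAB, Ab = pAb, aB = paB, ab = pab),
       n = n, converged = converged || n_dh == 0)
}

#' Pairwise LD measures for one SNP pair
#'
#' Haplotype frequencies are estimated by a two-locus EM over unphased
#' genotypes (complete-case individuals); from them D, the correlation r,
#' |D'|, the haplotype odds ratio lambda, and the allele-frequency-free
#' measure eta1 (via [eta1_from_odds_ratio()]) are derived.
#'
#' @param g1,g2 dosage vectors of the two SNPs over the same individuals.
#' @param min_n minimum complete-case individuals (default 20).
#' @return list with `r`, `abs_dprime`, `lambda`, `eta1`, `n`,
#'   `em_converged`; `NULL` for monomorphic input.
#' @export
estimate_pair_ld <- function(g1, g2, min_n = 20) {
  em <- haplotype_em(g1, g2)
  if (is.null(em) || em$n < min_n) {
    stop("need at least ", min_n, " individuals with both calls")
  }
  fr <- em$freqs
  pA <- fr["AB"] + fr["Ab"]
  pB <- fr["AB"] + fr["aB"]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NULL)
  D <- fr["AB"] - pA * pB
  r <- D / sqrt(pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  lambda <- (fr["AB"] * fr["ab"]) / (fr["Ab"] * fr["aB"])
  list(r = unname(r), abs_dprime = unname(min(dprime, 1)),
       lambda = unname(lambda),
       eta1 = eta1_from_odds_ratio(unname(lambda)),
       n = em$n, em_converged = em$converged)
}

# cached Monte Carlo quantile table of |log lambda| under haplotype
# frequencies uniform on the 3-simplex (Dirichlet(1,1,1,1) null)
eta1_cache <- new.env(parent = emptyenv())

eta1_table <- function(n_mc = 1e6, seed = 20110728) {
  key <- paste0("t", n_mc, "_", seed)
  if (!is.null(eta1_cache[[key]])) return(eta1_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w <- matrix(stats::rgamma(4 * n_mc, 1), ncol = 4)
  abs_log_lam <- abs(log(w[, 1]) + log(w[, 4]) - log(w[, 2]) - log(w[, 3]))
  probs <- seq(0, 1, length.out = 4097)[-4097]
  tab <- list(q = stats::quantile(abs_log_lam, probs, names = FALSE),
              p = probs)
  eta1_cache[[key]] <- tab
  tab
}

#' Allele-frequency-free LD measure eta1
#'
#' eta1 is a monotone transform of the haplotype odds ratio lambda, in
#' [-1, 1]. Its absolute value is the probability that a haplotype
#' frequency vector drawn uniformly on the 3-simplex shows less extreme LD
#' (smaller |log odds ratio|) than the observed lambda; its sign is the
#' sign of log(lambda). lambda = 1 gives 0; lambda of 0 or infinity gives
#' -1 or 1. Computed by interpolating a cached fixed-seed Monte Carlo
#' quantile table of |log lambda| under the uniform null.
#'
#' @param lambda odds ratio(s) in [0, Inf]; vectorised.
#' @param n_mc Monte Carlo size of the quantile table (default 1e6).
#' @return eta1 value(s) in [-1, 1].
#' @export
eta1_from_odds_ratio <- function(lambda, n_mc = 1e6) {
  if (any(lambda < 0, na.rm = TRUE)) stop("lambda must be non-negative")
  tab <- eta1_table(n_mc)
  ll <- log(lambda)
  mag <- stats::approx(tab$q, tab$p, xout = abs(ll), rule = 2)$y
  out <- sign(ll) * mag
  out[is.infinite(ll)] <- sign(ll[is.infinite(ll)])
  out[lambda == 1] <- 0
  out
}

#' Binned LD decay profile along a chromosome
#'
#' Computes the chosen LD measure for intra-chromosome SNP pairs up to
#' `max_distance_bp`, averages it in half-open distance bins of `bin_kb`,
#' and smooths the bin means over bin midpoints with a LOWESS estimator
#' (span 0.3, one robustness iteration by default).
#'
#' @param g a [genotype_matrix()].
#' @param chromosome chromosome label.
#' @param measure one of `"eta1"`, `"abs_eta1"`, `"r"`, `"abs_r"`,
#'   `"abs_dprime"`.
#' @param bin_kb bin width in kb (default 5).
#' @param max_distance_bp maximum pair distance (default 1e6).
#' @param samples optional sample subset.
#' @param lowess_f LOWESS span (default 0.3).
#' @param lowess_iter robustness iterations (default 1).
#' @param min_maf SNPs below this MAF are excluded (default 0.01).
#' @return list with `pairs` (data.frame of per-pair records), `bins`
#'   (bin_start_bp, midpoint_bp, mean, n_pairs), `smoothed` (midpoint_bp,
#'   value).
#' @export
ld_decay_profile <- function(g, chromosome,
                             measure = c("eta1", "abs_eta1", "r", "abs_r",
                                         "abs_dprime"),
                             bin_kb = 5, max_distance_bp = 1e6,
                             samples = NULL, lowess_f = 0.3, lowess_iter = 1,
                             min_maf = 0.01) {
  measure <- match.arg(measure)
  idx <- which(g$snps$chrom == chromosome)
  if (length(idx) < 2) stop("need at least two SNPs on chromosome ",
                            chromosome)
  calls <- g$calls[if (is.null(samples)) seq_len(n_samples(g)) else samples,
                   idx, drop = FALSE]
  pos <- g$snps$pos[idx]
  p <- colMeans(calls, na.rm = TRUE) / 2
  poly <- !is.na(p) & pmin(p, 1 - p) >= min_maf
  # enumerate in-range pairs first, then fill flat vectors (cheap), and
  # evaluate eta1 once, vectorised over the collected lambdas
  pi_ <- integer(0)
  pj_ <- integer(0)
  for (i in seq_along(idx)) {
    if (!poly[i]) next
    jmax <- findInterval(pos[i] + max_distance_bp, pos)
    if (jmax <= i) next
    js <- (i + 1L):jmax
    js <- js[poly[js]]
    pi_ <- c(pi_, rep.int(i, length(js)))
    pj_ <- c(pj_, js)
  }
  np <- length(pi_)
  rv <- dv <- lv <- rep(NA_real_, np)
  keep <- rep(FALSE, np)
  for (k in seq_len(np)) {
    ld <- tryCatch(estimate_pair_ld(calls[, pi_[k]], calls[, pj_[k]]),
                   error = function(e) NULL)
    if (is.null(ld)) next
    keep[k] <- TRUE
    rv[k] <- ld$r
    dv[k] <- ld$abs_dprime
    lv[k] <- ld$lambda
  }
  pairs <- data.frame(
    snp_i = g$snps$snp_id[idx[pi_[keep]]],
    snp_j = g$snps$snp_id[idx[pj_[keep]]],
    distance_bp = pos[pj_[keep]] - pos[pi_[keep]],
    r = rv[keep], abs_dprime = dv[keep], lambda = lv[keep],
    eta1 = if (any(keep)) eta1_from_odds_ratio(lv[keep]) else numeric(0),
    stringsAsFactors = FALSE)
  val <- switch(measure, eta1 = pairs$eta1, abs_eta1 = abs(pairs$eta1),
                r = pairs$r, abs_r = abs(pairs$r),
                abs_dprime = pairs$abs_dprime)
  bin_bp <- bin_kb * 1000
  bin_id <- floor(pairs$distance_bp / bin_bp)      # half-open [k*w, (k+1)*w)
  bins <- data.frame()
  smoothed <- data.frame(midpoint_bp = numeric(), value = numeric())
  if (nrow(pairs) > 0) {
    agg <- tapply(val, bin_id, mean)
    ks <- as.numeric(names(agg))
    bins <- data.frame(bin_start_bp = ks * bin_bp,
                       midpoint_bp = (ks + 0.5) * bin_bp,
                       mean = as.numeric(agg),
                       n_pairs = as.integer(table(bin_id)))
    if (nrow(bins) >= 2) {
      lw <- stats::lowess(bins$midpoint_bp, bins$mean, f = lowess_f,
                          iter = lowess_iter)
      smoothed <- data.frame(midpoint_bp = lw$x, value = lw$y)
    } else {
      smoothed <- data.frame(midpoint_bp = bins$midpoint_bp,
                             value = bins$mean)
    }
  }
  list(pairs = pairs, bins = bins, smoothed = smoothed, measure = measure)
}
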