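#' Power-model specification
#'
#' The phenotype model is `y = beta1 * s1 + g + e` with `beta1 = 1` (no
#' loss of generality once effects are expressed as explained variance):
#' the causal SNP s1 explains `v_s` of the total phenotype variance, the
#' polygenic effect `g ~ N(0, sigma_g^2 G)` explains `h2 - v_s`, and the
#' residual the remainder. Testing is done on the best proxy SNP s2, never
#' on s1 itself.
#'
#' @param v_s explained variance of the causal SNP (proportion).
#' @param h2 heritability, `v_s <= h2 <= 1`; `h2 = v_s` is the minimal
#'   (no-polygenic-effect) case.
#' @param alpha_grid p-value thresholds (default `c(1e-5, 1e-7)`).
#' @param n_reps phenotype draws per SNP in simulation mode (default 1000).
#' @param proxy_window_bp proxy search window around the causal SNP
#'   (default 2 Mb).
#' @return list of class `power_spec`.
#' @export
power_spec <- function(v_s = 0.02, h2 = v_s, alpha_grid = c(1e-5, 1e-7),
                       n_reps = 1000, proxy_window_bp = 2e6) {
  if (h2 < v_s) stop("h2 must be at least v_s")
  stopifnot(v_s >= 0, h2 <= 1, all(alpha_grid > 0 & alpha_grid < 1),
            n_reps >= 1)
  structure(list(v_s = v_s, h2 = h2, alpha_grid = alpha_grid,
                 n_reps = n_reps, proxy_window_bp = proxy_window_bp),
            class = "power_spec")
}

#' Best proxy SNP for a causal SNP
#'
#' The SNP (other than the causal one) with maximal |r| to the causal SNP
#' within `window_bp` on the same chromosome, r being the dosage
#' correlation; ties go to the smaller distance, then the smaller snp_id.
#'
#' @param g a [genotype_matrix()].
#' @param causal_snp snp_id of the causal SNP.
#' @param window_bp half-window (default 2 Mb).
#' @return list with `proxy` (snp_id or `NA` if no SNP lies in the
#'   window), `max_r`, `distance_bp`.
#' @export
best_proxy <- function(g, causal_snp, window_bp = 2e6) {
  k <- match(causal_snp, g$snps$snp_id)
  if (is.na(k)) stop("unknown snp_id: ", causal_snp)
  same <- which(g$snps$chrom == g$snps$chrom[k])
  dist <- abs(g$snps$pos[same] - g$snps$pos[k])
  cand <- same[dist <= window_bp & same != k]
  if (length(cand) == 0) {
    return(list(proxy = NA_character_, max_r = NA_real_,
                distance_bp = NA_real_))
  }
  s1 <- g$calls[, k]
  rs <- suppressWarnings(
    stats::cor(s1, g$calls[, cand, drop = FALSE],
               use = "pairwise.complete.obs"))
  rs <- as.numeric(rs)
  rs[is.na(rs)] <- 0
  dd <- abs(g$snps$pos[cand] - g$snps$pos[k])
  ord <- order(-abs(rs), dd, g$snps$snp_id[cand])
  b <- ord[1]
  list(proxy = g$snps$snp_id[cand[b]], max_r = rs[b], distance_bp = dd[b])
}

#' Analytic power of proxy-SNP testing (uncorrelated phenotypes)
#'
#' Under `y = s1 + e`, `e ~ N(0, sigma^2)` with
#' `sigma^2 = Var(s1) (1 - v_s) / v_s` (so s1 explains `v_s` of the
#' phenotype variance), the least-squares slope of y on the proxy s2 is
#' normal with mean `sum((s2 - mean(s2)) s1) / sum((s2 - mean(s2))^2)` and
#' variance `sigma^2 / sum((s2 - mean(s2))^2)`, conditional on genotypes.
#' Power of the two-sided normal test at level alpha is
#' `pnorm(-z + |ncp|) + pnorm(-z - |ncp|)` with `ncp = mean / sd` and
#' `z = qnorm(1 - alpha/2)`.
#'
#' @param s1,s2 causal and proxy dosage vectors (complete cases used).
#' @param v_s explained variance of s1, in (0, 1); 0 returns alpha.
#' @param alpha significance level(s).
#' @return Power per alpha.
#' @export
analytic_power <- function(s1, s2, v_s, alpha) {
  ok <- !is.na(s1) & !is.na(s2)
  s1 <- s1[ok]; s2 <- s2[ok]
  if (stats::var(s2) == 0) stop("proxy genotype is constant")
  if (v_s <= 0) return(rep_len(alpha * 0 + alpha, length(alpha)))
  if (v_s >= 1) return(rep_len(1, length(alpha)))
  s2c <- s2 - mean(s2)
  ss2 <- sum(s2c^2)
  mu <- sum(s2c * s1) / ss2
  sigma2 <- stats::var(s1) * (1 - v_s) / v_s
  ncp <- abs(mu) / sqrt(sigma2 / ss2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-z + ncp) + stats::pnorm(-z - ncp)
}

# variance components from (v_s, h2): beta1 = 1 fixes Var(s1) = v_s * T
# where T is the total phenotype variance, so T = Var(s1)/v_s; the
# polygenic share is scaled by the mean diagonal of G
power_variance_components <- function(s1, G, spec) {
  vs1 <- stats::var(s1)
  if (vs1 == 0) stop("causal genotype is constant")
  total <- vs1 / spec$v_s
  vg <- spec$h2 - spec$v_s
  sigma_g2 <- vg * total / mean(diag(G))
  sigma_e2 <- (1 - spec$h2) * total
  list(total = total, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)
}

# symmetric PSD square root of sigma_g2*G + sigma_e2*I via eigen; negative
# eigenvalues (non-PSD relatedness estimates) are clipped at zero
phenotype_cov_root <- function(G, sigma_g2, sigma_e2, eigen_G = NULL) {
  if (sigma_g2 == 0) return(list(root = NULL, sd_iid = sqrt(sigma_e2)))
  eg <- if (is.null(eigen_G)) eigen(G, symmetric = TRUE) else eigen_G
  ev <- pmax(eg$values, 0)
  if (any(eg$values < -1e-8)) {
    message("relatedness matrix not PSD; ",
            sum(eg$values < -1e-8), " negative eigenvalues clipped")
  }
  root <- eg$vectors %*% (sqrt(sigma_g2 * ev + sigma_e2) * t(eg$vectors))
  list(root = root, sd_iid = NULL)
}

#' Simulated power of proxy-SNP testing under the relatedness mixed model
#'
#' Draws `n_reps` phenotypes from `y = s1 + g + e`, `g ~ N(0, sigma_g^2 G)`,
#' `e ~ N(0, sigma_e^2 I)`, with variance components derived from
#' `(v_s, h2)` (total variance `Var(s1)/v_s`; polygenic variance scaled by
#' the mean diagonal of G). Each draw is analysed by the naive model
#' `y = beta2 s2 + e2`: an OLS fit whose two-sided Wald p-value uses the
#' residual-estimated sigma, exactly as an uncorrected association scan
#' would. Power is the rejection fraction per alpha.
#'
#' @param s1,s2 causal and proxy dosage vectors.
#' @param G relatedness matrix over the same individuals (used as the
#'   polygenic covariance; clipped to PSD if needed).
#' @param spec a [power_spec()].
#' @param seed RNG seed for the draws.
#' @param eigen_G optional precomputed `eigen(G, symmetric = TRUE)` (reused
#'   across SNPs; ignored when missing genotypes force a subset).
#' @return list with `power` (named by alpha), `beta_hat` (the `n_reps`
#'   estimates), `analytic_var` (conditional variance of the estimator
#'   under the uncorrelated model with the same total residual variance).
#' @export
simulate_power_mixed <- function(s1, s2, G, spec, seed = 1L,
                                 eigen_G = NULL) {
  ok <- !is.na(s1) & !is.na(s2)
  if (!all(ok)) eigen_G <- NULL       # cached decomposition no longer fits
  s1 <- s1[ok]; s2 <- s2[ok]
  G <- G[ok, ok, drop = FALSE]
  n <- length(s1)
  vc <- power_variance_components(s1, G, spec)
  set.seed(seed)
  cr <- phenotype_cov_root(G, vc$sigma_g2, vc$sigma_e2, eigen_G)
  E <- matrix(stats::rnorm(n * spec$n_reps), n, spec$n_reps)
  noise <- if (is.null(cr$root)) cr$sd_iid * E else cr$root %*% E
  Y <- s1 + noise
  s2c <- s2 - mean(s2)
  ss2 <- sum(s2c^2)
  if (ss2 == 0) stop("proxy genotype is constant")
  beta_hat <- as.numeric(crossprod(s2c, Y)) / ss2
  # naive residual variance estimate per draw (intercept + slope model)
  Yc <- Y - matrix(colMeans(Y), n, spec$n_reps, byrow = TRUE)
  rss <- colSums(Yc^2) - beta_hat^2 * ss2
  se_hat <- sqrt(rss / (n - 2) / ss2)
  zstat <- beta_hat / se_hat
  pvals <- 2 * stats::pnorm(-abs(zstat))
  power <- vapply(spec$alpha_grid, function(a) mean(pvals < a), 0)
  names(power) <- format(spec$alpha_grid, scientific = TRUE)
  # residual variance an uncorrelated analysis would see, in expectation
  uncorr_var <- (vc$sigma_g2 * mean(diag(G)) + vc$sigma_e2) / ss2
  list(power = power, beta_hat = beta_hat, analytic_var = uncorr_var)
}

#' Variance inflation of the naive estimator under relatedness
#'
#' Ratio of the empirical variance of the OLS slope over `n_reps` mixed-
#' model draws to the analytic conditional variance the uncorrelated model
#' predicts. Equals 1 for identity G or `h2 = v_s`; exceeds 1 under family
#' structure with high heritability, which is what mis-calibrates naive
#' association tests in family-enriched samples.
#'
#' @inheritParams simulate_power_mixed
#' @return list with `ratio`, `mc_se` (Monte-Carlo SE of the ratio),
#'   `empirical_var`, `analytic_var`.
#' @export
variance_inflation <- function(s1, s2, G, spec, seed = 1L) {
  sim <- simulate_power_mixed(s1, s2, G, spec, seed = seed)
  emp <- stats::var(sim$beta_hat)
  ratio <- emp / sim$analytic_var
  # SE of a variance estimate under approximate normality of beta_hat
  mc_se <- ratio * sqrt(2 / (spec$n_reps - 1))
  list(ratio = ratio, mc_se = mc_se, empirical_var = emp,
       analytic_var = sim$analytic_var)
}

#' Distribution of proxy-testing power along a chromosome
#'
#' Treats every SNP of the chromosome as causal in turn, finds its best
#' proxy within the window, computes power (analytic, or simulated under
#' the mixed model), and reports the quartiles per (v_s, alpha), in
#' percent.
#'
#' @param g a [genotype_matrix()].
#' @param chromosome chromosome label.
#' @param spec a [power_spec()]; in mixed mode its `h2` applies.
#' @param mode `"analytic"` or `"mixed"`.
#' @param G relatedness matrix (mixed mode only).
#' @param samples optional sample subset.
#' @param seed base seed for mixed-mode draws (one derived seed per SNP).
#' @return list with `quartiles` (data.frame: alpha, q1, median, q3 in
#'   percent), `per_snp` (power per causal SNP and alpha),
#'   `n_no_proxy` (SNPs without any in-window proxy, excluded).
#' @export
power_distribution <- function(g, chromosome, spec,
                               mode = c("analytic", "mixed"), G = NULL,
                               samples = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "mixed" && is.null(G)) stop("mixed mode needs G")
  idx <- which(g$snps$chrom == chromosome)
  rows <- if (is.null(samples)) seq_len(n_samples(g)) else samples
  if (is.character(rows)) rows <- match(rows, g$samples$sample_id)
  calls <- g$calls[rows, idx, drop = FALSE]
  pos <- g$snps$pos[idx]
  eg <- NULL
  if (mode == "mixed") {
    G <- G[rows, rows, drop = FALSE]
    if (spec$h2 > spec$v_s) eg <- eigen(G, symmetric = TRUE)
  }
  nA <- length(spec$alpha_grid)
  pw <- matrix(NA_real_, length(idx), nA)
  n_no_proxy <- 0L
  for (k in seq_along(idx)) {
    s1 <- calls[, k]
    if (is.na(stats::var(s1, na.rm = TRUE)) ||
        stats::var(s1, na.rm = TRUE) == 0) next
    cand <- which(abs(pos - pos[k]) <= spec$proxy_window_bp)
    cand <- setdiff(cand, k)
    if (length(cand) == 0) {
      n_no_proxy <- n_no_proxy + 1L
      next
    }
    rs <- suppressWarnings(as.numeric(
      stats::cor(s1, calls[, cand, drop = FALSE],
                 use = "pairwise.complete.obs")))
    rs[is.na(rs)] <- 0
    dd <- abs(pos[cand] - pos[k])
    b <- order(-abs(rs), dd)[1]
    s2 <- calls[, cand[b]]
    if (stats::var(s2, na.rm = TRUE) == 0) {
      n_no_proxy <- n_no_proxy + 1L
      next
    }
    if (mode == "analytic") {
      pw[k, ] <- analytic_power(s1, s2, spec$v_s, spec$alpha_grid)
    } else {
      sim <- simulate_power_mixed(s1, s2, G, spec, seed = seed + k,
                                  eigen_G = eg)
      pw[k, ] <- sim$power
    }
  }
  done <- rowSums(!is.na(pw)) > 0
  qs <- lapply(seq_len(nA), function(a) {
    q <- stats::quantile(pw[done, a], c(0.25, 0.5, 0.75)) * 100
    data.frame(alpha = spec$alpha_grid[a], q1 = q[1], median = q[2],
               q3 = q[3], row.names = NULL)
  })
  list(quartiles = do.call(rbind, qs),
       per_snp = data.frame(snp_id = g$snps$snp_id[idx], pw),
       n_no_proxy = n_no_proxy)
}
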