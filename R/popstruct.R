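#' PCA configuration
#'
#' @param n_per_group individuals drawn per group for the balanced subsample
#'   (default 50).
#' @param n_outlier_iterations maximum outlier-removal iterations (5).
#' @param ld_regress_snps number of preceding SNPs each SNP is residualised
#'   on (2; 0 disables the LD correction).
#' @param n_components components retained and screened for outliers (10).
#' @param outlier_sigma outlier threshold in within-component SDs (6).
#' @param pca_call_rate minimum SNP call rate for PCA input (0.99).
#' @param relatedness_cutoff pairs above this count as relationships when
#'   picking the most unrelated individuals (0.2).
#' @return list of class `pca_config`.
#' @export
pca_config <- function(n_per_group = 50, n_outlier_iterations = 5,
                       ld_regress_snps = 2, n_components = 10,
                       outlier_sigma = 6, pca_call_rate = 0.99,
                       relatedness_cutoff = 0.2) {
  stopifnot(n_per_group > 0, n_outlier_iterations >= 0, ld_regress_snps >= 0,
            n_components > 0, outlier_sigma > 0)
  structure(list(n_per_group = n_per_group,
                 n_outlier_iterations = n_outlier_iterations,
                 ld_regress_snps = ld_regress_snps,
                 n_components = n_components, outlier_sigma = outlier_sigma,
                 pca_call_rate = pca_call_rate,
                 relatedness_cutoff = relatedness_cutoff),
            class = "pca_config")
}

#' Balanced most-unrelated subsample
#'
#' For each group, greedily grows a selection of `n_per_group` individuals
#' minimising, at each step, the number (then the maximum) of
#' above-cutoff relationships to the already-selected individuals; ties are
#' broken by sample id. Equal group sizes remove the sample-size bias of
#' PCA on unbalanced cohorts.
#'
#' @param g a [genotype_matrix()].
#' @param groups vector of group labels per sample (NA = not eligible).
#' @param R relatedness matrix over the samples of `g`.
#' @param cfg a [pca_config()].
#' @return Character vector of selected sample ids.
#' @export
balanced_subsample <- function(g, groups, R, cfg = pca_config()) {
  stopifnot(length(groups) == n_samples(g))
  ids <- g$samples$sample_id
  R <- unclass(R)
  diag(R) <- -Inf                     # self-pairs never count
  sel <- character(0)
  for (grp in unique(groups[!is.na(groups)])) {
    members <- which(groups == grp)
    if (length(members) < cfg$n_per_group) {
      stop("group ", grp, " has ", length(members), " members; need ",
           cfg$n_per_group)
    }
    members <- members[order(ids[members])]
    chosen <- integer(0)
    for (step in seq_len(cfg$n_per_group)) {
      rest <- setdiff(members, chosen)
      ref <- if (length(chosen) == 0) members else chosen
      sub <- R[rest, ref, drop = FALSE]
      nrel <- rowSums(sub > cfg$relatedness_cutoff, na.rm = TRUE)
      mrel <- apply(sub, 1, max, na.rm = TRUE)
      best <- order(nrel, mrel, ids[rest])[1]
      chosen <- c(chosen, rest[best])
    }
    sel <- c(sel, ids[chosen])
  }
  sel
}

#' PCA with LD correction and iterative outlier removal
#'
#' Genotypes are mean-centred and scaled by `sqrt(p(1-p))`; each SNP column
#' is then residualised on the `ld_regress_snps` preceding SNPs of the same
#' chromosome; the eigendecomposition of the individual-by-individual
#' covariance gives the scores. Individuals scoring more than
#' `outlier_sigma` SDs from the mean on any of the leading components are
#' removed and the decomposition recomputed, up to `n_outlier_iterations`
#' times or until no outlier remains. Allele frequencies are recomputed
#' from the retained individuals after each removal. Components are
#' oriented so that the largest-magnitude score is positive.
#'
#' @param g a [genotype_matrix()]; SNPs failing `pca_call_rate` are dropped.
#' @param cfg a [pca_config()].
#' @return list of class `pca_result`: `scores` (retained individuals x
#'   components), `eigenvalues`, `removed_outliers` (ids per iteration),
#'   `n_snps_used`.
#' @export
pca_with_outlier_removal <- function(g, cfg = pca_config()) {
  keep_snp <- call_rate(g) >= cfg$pca_call_rate
  if (sum(keep_snp) < 2) stop("fewer than two SNPs pass the PCA call rate")
  g <- subset_genotypes(g, snps = which(keep_snp))
  alive <- rep(TRUE, n_samples(g))
  removed <- list()
  res <- NULL
  for (it in seq_len(cfg$n_outlier_iterations + 1L)) {
    if (sum(alive) < 10) stop("fewer than 10 individuals left in PCA")
    res <- pca_once(g, which(alive), cfg)
    if (it > cfg$n_outlier_iterations) break
    sds <- apply(res$scores, 2, stats::sd)
    ctr <- colMeans(res$scores)
    out <- rowSums(abs(sweep(sweep(res$scores, 2, ctr), 2,
                             pmax(sds, 1e-12), "/")) >
                     cfg$outlier_sigma) > 0
    if (!any(out)) break
    removed[[length(removed) + 1L]] <- rownames(res$scores)[out]
    alive[match(rownames(res$scores)[out], g$samples$sample_id)] <- FALSE
  }
  structure(list(scores = res$scores, eigenvalues = res$eigenvalues,
                 removed_outliers = removed, n_snps_used = n_snps(g)),
            class = "pca_result")
}

pca_once <- function(g, rows, cfg) {
  x <- g$calls[rows, , drop = FALSE]
  p <- colMeans(x, na.rm = TRUE) / 2
  ok <- !is.na(p) & p > 0 & p < 1
  x <- x[, ok, drop = FALSE]
  p <- p[ok]
  chrom <- g$snps$chrom[ok]
  Z <- sweep(x, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(p * (1 - p)), "/")
  L <- cfg$ld_regress_snps
  if (L > 0) {
    Zr <- Z
    for (j in seq_len(ncol(Z))) {
      prev <- j - seq_len(L)
      prev <- prev[prev >= 1 & chrom[pmax(prev, 1)] == chrom[j]]
      if (length(prev)) {
        fit <- stats::lm.fit(cbind(1, Z[, prev, drop = FALSE]), Z[, j])
        Zr[, j] <- fit$residuals
      }
    }
    Z <- Zr
  }
  ncomp <- min(cfg$n_components, nrow(Z) - 1L)
  cov <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(cov, symmetric = TRUE)
  scores <- eig$vectors[, seq_len(ncomp), drop = FALSE]
  # orient each component so its largest-magnitude score is positive
  for (k in seq_len(ncomp)) {
    if (scores[which.max(abs(scores[, k])), k] < 0) {
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- g$samples$sample_id[rows]
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  list(scores = scores, eigenvalues = eig$values[seq_len(ncomp)])
}
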