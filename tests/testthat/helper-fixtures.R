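# shared fixture builders; everything is generated in code at test time

toy_genotypes <- function(calls, pos = NULL, chrom = "1",
                          population = "pop", platform = NA_character_) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(
    calls,
    data.frame(snp_id = sprintf("s%04d", seq_len(m)), chrom = chrom,
               pos = pos, allele_a = "A", allele_b = "G",
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("i%03d", seq_len(n)),
               population = rep_len(population, n),
               platform = rep_len(platform, n), stringsAsFactors = FALSE))
}

# n individuals drawn from HWE at frequencies p (one per SNP)
hwe_genotypes <- function(n, p, ...) {
  m <- length(p)
  toy_genotypes(matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m), ...)
}

# a small simulated two-population cohort, memoised across tests
fixture_env <- new.env()
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- sim_config(seed = 42, n_pop1 = 80, n_pop2 = 80, n_snps = 3000,
                      n_chromosomes = 2, ld_decay_bp = 5000)
    fixture_env$small <- simulate_two_populations(cfg)
  }
  fixture_env$small
}

# relatedness matrix wrapper from a plain symmetric matrix
as_relmat <- function(m, ids = sprintf("i%03d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  m
}

# brute-force ROH oracle: direct enumeration of windows and segments,
# independent of the package implementation
oracle_roh <- function(x, pos, params) {
  m <- length(x)
  if (m < params$window_min_snps) return(NULL)
  w <- params$window_kb * 1000
  hom_w <- valid_w <- logical(m)
  last <- integer(m)
  for (k in seq_len(m)) {
    inw <- which(pos >= pos[k] & pos <= pos[k] + w)
    last[k] <- max(inw)
    valid_w[k] <- length(inw) >= params$window_min_snps
    if (valid_w[k]) {
      xs <- x[inw]
      hom_w[k] <- sum(xs == 1L, na.rm = TRUE) <= params$window_max_het &&
        sum(is.na(xs)) <= params$window_max_missing
    }
  }
  inrun <- logical(m)
  for (j in seq_len(m)) {
    anchors <- which(valid_w & seq_len(m) <= j & last >= j)
    if (length(anchors) == 0) next
    inrun[j] <- mean(hom_w[anchors]) >= params$hit_proportion
  }
  segs <- list()
  j <- 1
  while (j <= m) {
    if (!inrun[j]) { j <- j + 1; next }
    k <- j
    while (k < m && inrun[k + 1]) k <- k + 1
    idx <- j:k
    # split at large gaps
    cur <- idx[1]
    pieces <- list()
    piece <- cur
    for (t in idx[-1]) {
      if (pos[t] - pos[piece[length(piece)]] >= params$gap_split_kb * 1000) {
        pieces[[length(pieces) + 1]] <- piece
        piece <- t
      } else {
        piece <- c(piece, t)
      }
    }
    pieces[[length(pieces) + 1]] <- piece
    for (pc in pieces) {
      len <- pos[pc[length(pc)]] - pos[pc[1]]
      if (len >= params$min_run_kb * 1000 &&
          length(pc) >= params$min_run_snps &&
          len / length(pc) <= params$min_density_kb_per_snp * 1000) {
        segs[[length(segs) + 1]] <- c(pos[pc[1]], pos[pc[length(pc)]],
                                      length(pc))
      }
    }
    j <- k + 1
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

# sib-pair fixture for variance-inflation work: n/2 pairs, each pair shares
# one genotype value drawn under HWE, with a 2x2 relatedness block of 0.5
sib_block_fixture <- function(n = 200, maf = 0.3, seed = 77) {
  set.seed(seed)
  s <- rep(stats::rbinom(n / 2, 2, maf), each = 2)
  G <- kronecker(diag(n / 2), matrix(c(1, 0.5, 0.5, 1), 2))
  list(s = s, G = G)
}
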