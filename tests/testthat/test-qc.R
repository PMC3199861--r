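test_that("call-rate filter uses a strict threshold on the combined cohort", {
  set.seed(1)
  calls <- matrix(1L, 100, 3)
  calls[seq_len(6), 1] <- NA   # 94/100 calls: fails
  calls[seq_len(5), 2] <- NA   # exactly 95/100: passes
  g <- toy_genotypes(calls)
  fails <- call_rate_filter(g, qc_thresholds(min_call_rate = 0.95))
  expect_identical(fails, g$snps$snp_id[1])
  # fully observed matrix: nothing fails
  expect_length(call_rate_filter(toy_genotypes(matrix(0:2, 30, 5))), 0)
})

test_that("Levene exact-null moments match direct enumeration", {
  # enumerate the heterozygote-count distribution given the allele count
  levene_exact <- function(nA, n) {
    hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    logp <- vapply(hs, function(h) {
      nAA <- (nA - h) / 2
      nBB <- n - nAA - h
      lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(nBB) +
        h * log(2) - (lchoose(2 * n, nA))
    }, 0)
    p <- exp(logp)
    p <- p / sum(p)
    c(mean = sum(hs * p), var = sum(hs^2 * p) - sum(hs * p)^2)
  }
  for (case in list(c(3, 10), c(7, 12), c(10, 25), c(1, 8))) {
    ex <- levene_exact(case[1], case[2])
    mom <- isopop:::levene_moments(case[1], 2 * case[2] - case[1])
    expect_equal(mom$mean, unname(ex["mean"]), tolerance = 1e-12)
    expect_equal(mom$var, unname(ex["var"]), tolerance = 1e-10)
  }
})

test_that("stratified HWE test reduces to the classic score test and resists Wahlund", {
  # strata exactly at the null expectation give Z = 0, p = 1
  g <- toy_genotypes(matrix(c(2L, 2L, 1L), 3, 1))  # E[het | nA=1] = 1 = observed
  res <- stratified_hwe_test(g)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  # single stratum agrees with an independently coded one-population score
  # test to machine precision
  set.seed(4)
  g1 <- hwe_genotypes(80, runif(30, 0.1, 0.9))
  res1 <- stratified_hwe_test(g1)
  classic <- apply(g1$calls, 2, function(x) {
    n <- sum(!is.na(x))
    nb <- sum(x, na.rm = TRUE)
    na_ <- 2 * n - nb
    if (nb == 0 || na_ == 0) return(1)
    eh <- na_ * nb / (2 * n - 1)
    ehh <- na_ * (na_ - 1) * nb * (nb - 1) / ((2 * n - 1) * (2 * n - 3))
    v <- ehh + eh - eh^2
    2 * pnorm(-abs((sum(x == 1, na.rm = TRUE) - eh) / sqrt(v)))
  })
  expect_equal(res1$p, unname(classic), tolerance = 1e-12)
  # two strata in HWE at p = 0.1 / 0.9: stratified test accepts while the
  # pooled naive test rejects on the Wahlund heterozygote deficit
  set.seed(9)
  n <- 500
  x <- c(rbinom(n, 2, 0.1), rbinom(n, 2, 0.9))
  strata <- rep(c("a", "b"), each = n)
  gs <- toy_genotypes(matrix(x, ncol = 1), population = strata)
  expect_gt(stratified_hwe_test(gs)$p, 0.05)
  gp <- toy_genotypes(matrix(x, ncol = 1), population = "all")
  expect_lt(stratified_hwe_test(gp)$p, 1e-10)
  # monomorphic SNP: flagged, p = 1
  gm <- toy_genotypes(matrix(0L, 10, 1))
  resm <- stratified_hwe_test(gm)
  expect_identical(resm$flag, "monomorphic")
  expect_equal(resm$p, 1)
})

test_that("platform frequency test handles exact, asymptotic and degenerate tables", {
  # identical allele counts on both platforms: p = 1
  calls <- rbind(matrix(c(0L, 1L, 2L), 30, 3, byrow = TRUE),
                 matrix(c(0L, 1L, 2L), 30, 3, byrow = TRUE))
  g <- toy_genotypes(calls, platform = rep(c("A", "B"), each = 30))
  expect_equal(platform_frequency_test(g)$p, rep(1, 3))
  # 800/200 vs 500/500 alleles: overwhelming difference
  big <- toy_genotypes(
    rbind(matrix(rep(c(rep(2L, 300), rep(1L, 200)), 1), ncol = 1),
          matrix(rep(c(rep(2L, 0), rep(1L, 500)), 1), ncol = 1)),
    platform = rep(c("A", "B"), each = 500))
  expect_lt(platform_frequency_test(big)$p, 1e-7)
  # monomorphic on both platforms: p = 1
  gm <- toy_genotypes(matrix(2L, 40, 1), platform = rep(c("A", "B"), 20))
  expect_equal(platform_frequency_test(gm)$p, 1)
  # SNP typed on one platform only is skipped and logged
  calls2 <- matrix(1L, 40, 2)
  calls2[21:40, 2] <- NA
  g2 <- toy_genotypes(calls2, platform = rep(c("A", "B"), each = 20))
  res2 <- platform_frequency_test(g2)
  expect_true(is.na(res2$p[2]))
  expect_identical(attr(res2, "skipped"), g2$snps$snp_id[2])
  # the hand-rolled exact p matches fisher.test on small tables
  set.seed(7)
  for (k in 1:20) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    expect_equal(isopop:::exact_test_2x2(tab[1, 1], tab[1, 2],
                                         tab[2, 1], tab[2, 2]),
                 fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("QC removes the union of failure sets, never the sum", {
  set.seed(11)
  n <- 400
  calls <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  calls[seq_len(n * 0.1), 1] <- NA            # snp1 fails call rate
  calls[, 2] <- 1L                            # snp2 fails HWE (all het)
  calls[, 3] <- 1L                            # snp3 fails HWE too
  calls[seq_len(n * 0.1), 3] <- NA            # ... and call rate
  g <- toy_genotypes(calls, platform = rep(c("A", "B"), each = n / 2))
  out <- apply_qc(g, qc_thresholds(), platform_within = "pop")
  rep_ <- out$report
  expect_true(all(c("s0002", "s0003") %in% rep_$removed_hwe))
  expect_true(all(c("s0001", "s0003") %in% rep_$removed_call_rate))
  union_n <- length(union(union(rep_$removed_call_rate, rep_$removed_hwe),
                          rep_$removed_platform))
  expect_identical(rep_$n_removed_union, union_n)
  expect_lt(union_n, length(rep_$removed_call_rate) +
              length(rep_$removed_hwe) + 1)
  expect_identical(rep_$n_retained, rep_$n_input - rep_$n_removed_union)
  expect_identical(n_snps(out$genotypes), rep_$n_retained)
})

test_that("platform-shifted SNPs are flagged with high sensitivity and specificity", {
  cfg <- sim_config(seed = 31, n_pop1 = 400, n_pop2 = 100, n_snps = 2000,
                    maf_range = c(0.1, 0.5),
                    platform_shift_snps = list(count = 50, shift = 0.25))
  sim <- simulate_cohorts(cfg)
  art <- sim$truth$artifact_snps
  res <- platform_frequency_test(sim$genotypes, within = "isolate")
  hits <- res$snp_id[!is.na(res$p) & res$p < 1e-7]
  expect_gte(sum(art %in% hits), 45)
  null_flagged <- setdiff(hits, art)
  expect_lte(length(null_flagged), 0.01 * (2000 - 50))
  # and apply_qc removes them
  out <- apply_qc(sim$genotypes, platform_within = "isolate")
  expect_gte(sum(art %in% out$report$removed_platform), 45)
})

test_that("the stratified HWE test keeps its type-I error under control", {
  # null data: expected failure fraction at 1e-6 is at most 1e-5
  set.seed(13)
  g <- hwe_genotypes(200, runif(60000, 0.1, 0.5))
  p <- stratified_hwe_test(g)$p
  n_fail <- sum(p < 1e-6)
  # under the bound, P(X > 4 | n = 6e4, rate 1e-5) < 1e-3
  expect_lte(n_fail, 4)
})
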