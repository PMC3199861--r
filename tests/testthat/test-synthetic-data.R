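test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 3, n_pop1 = 20, n_pop2 = 20, n_snps = 500,
                    family_spec = list(list(type = "trio", count = 2)),
                    missing_rate_by_platform = c(chipA = 0.02, chipB = 0.01))
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth$true_kinship, b$truth$true_kinship)
})

test_that("zero divergence yields F_ST within two SEs of zero", {
  sim <- simulate_two_populations(
    sim_config(seed = 11, n_pop1 = 150, n_pop2 = 150, n_snps = 4000,
               divergence_fst = 0, ld_decay_bp = 2000))
  r <- fst(sim$genotypes, "isolate", "outbred")
  expect_lt(abs(r$estimate), 2 * r$se)
})

test_that("pedigree ground truth matches Mendelian expectations", {
  cfg <- sim_config(seed = 5, n_pop1 = 40, n_pop2 = 5, n_snps = 400,
                    family_spec = list(
                      list(type = "trio", count = 1),
                      list(type = "sib_pair", count = 1),
                      list(type = "cousin_pair", count = 1),
                      list(type = "cousin_mating", count = 1)))
  sim <- simulate_cohorts(cfg)
  K <- sim$truth$true_kinship
  ped <- sim$truth$pedigree
  kids <- ped$id[!is.na(ped$father)]
  # trio child vs its cohort father
  trio_kid <- kids[1]
  expect_equal(K[trio_kid, ped$father[ped$id == trio_kid]], 0.5)
  # sib pair
  sibs <- ped$id[!is.na(ped$father) &
                   ped$father == ped$father[ped$id == kids[2]]]
  sibs <- sibs[grepl("^isolate", ped$father[match(sibs, ped$id)])]
  expect_equal(unname(K[sibs[1], sibs[2]]), 0.5)
  # first cousins: the two offspring of the internal sibling parents
  cz <- kids[grepl("fam", ped$father[match(kids, ped$id)])]
  cousins <- cz[!grepl("_c", ped$father[match(cz, ped$id)])]
  expect_equal(unname(K[cousins[1], cousins[2]]), 0.125)
  # cousin-mating offspring is inbred with F = 1/16
  inbred <- cz[grepl("_c", ped$father[match(cz, ped$id)])]
  expect_equal(unname(diag(K)[inbred]), 1 + 1 / 16)
  # no families: off-diagonal truth is zero
  sim0 <- simulate_two_populations(sim_config(seed = 6, n_pop1 = 10,
                                              n_pop2 = 10, n_snps = 200))
  K0 <- sim0$truth$true_kinship
  expect_true(all(K0[upper.tri(K0)] == 0))
})

test_that("estimated relatedness recovers pedigree expectations", {
  # one parent-offspring pair at genome scale
  cfg <- sim_config(seed = 8, n_pop1 = 100, n_pop2 = 30, n_snps = 6000,
                    n_chromosomes = 3, ld_decay_bp = 2000,
                    family_spec = list(list(type = "trio", count = 1)))
  sim <- simulate_cohorts(cfg)
  ped <- sim$truth$pedigree
  kid <- ped$id[!is.na(ped$father)][1]
  R <- estimate_relatedness(sim$genotypes)
  expect_gt(R[kid, ped$father[ped$id == kid]], 0.45)
  expect_lt(R[kid, ped$father[ped$id == kid]], 0.55)
  # cousin pairs: replicate-pair mean within 0.03 of 0.125 (many
  # chromosomes and a denser genetic map tame Mendelian sampling noise)
  cfg2 <- sim_config(seed = 9, n_pop1 = 300, n_pop2 = 5, n_snps = 9000,
                     n_chromosomes = 6, ld_decay_bp = 2000,
                     recomb_rate_per_bp = 2e-7,
                     family_spec = list(list(type = "cousin_pair",
                                             count = 30)))
  sim2 <- simulate_cohorts(cfg2)
  K <- sim2$truth$true_kinship
  R2 <- estimate_relatedness(sim2$genotypes)
  pairs <- which(K == 0.125 & upper.tri(K), arr.ind = TRUE)
  expect_identical(nrow(pairs), 30L)
  est <- R2[pairs]
  expect_lt(abs(mean(est) - 0.125), 0.03)
})

test_that("infeasible family specifications raise configuration errors", {
  sim <- simulate_two_populations(sim_config(seed = 2, n_pop1 = 5,
                                             n_pop2 = 5, n_snps = 200))
  expect_error(overlay_families(sim$genotypes, sim$truth,
                                list(list(type = "sib_pair", count = 2)),
                                sim_config(seed = 2, n_pop1 = 5, n_pop2 = 5,
                                           n_snps = 200)),
               "available")
  expect_error(overlay_families(sim$genotypes, sim$truth,
                                list(list(type = "uncle", count = 1)),
                                sim_config(seed = 2, n_pop1 = 5, n_pop2 = 5,
                                           n_snps = 200)),
               "unknown family type")
})

test_that("artifact injection matches its configured rates", {
  cfg0 <- sim_config(seed = 13, n_pop1 = 100, n_pop2 = 100, n_snps = 2000)
  sim <- simulate_two_populations(cfg0)
  # all rates zero: output identical
  out0 <- inject_artifacts(sim$genotypes, sim$truth, cfg0)
  expect_identical(out0$genotypes$calls, sim$genotypes$calls)
  # missing rate 0.06 on one platform: that platform's call rate in [0.93, 0.95]
  cfg1 <- sim_config(seed = 13, n_pop1 = 100, n_pop2 = 100, n_snps = 2000,
                     missing_rate_by_platform = c(chipA = 0, chipB = 0.06))
  out1 <- inject_artifacts(sim$genotypes, sim$truth, cfg1)
  rows <- which(out1$genotypes$samples$platform == "chipB")
  cr <- mean(!is.na(out1$genotypes$calls[rows, ]))
  expect_gt(cr, 0.93)
  expect_lt(cr, 0.95)
  # infeasible shift is clipped with a warning
  cfg2 <- sim_config(seed = 13, n_pop1 = 100, n_pop2 = 100, n_snps = 2000,
                     platform_shift_snps = list(count = 5, shift = 0.9))
  expect_warning(inject_artifacts(sim$genotypes, sim$truth, cfg2), "clipped")
})

test_that("simulated LD decays monotonically on the configured scale", {
  cfg <- sim_config(seed = 21, n_pop1 = 250, n_pop2 = 5, n_snps = 1500,
                    n_chromosomes = 1, ld_decay_bp = 50000,
                    snp_spacing_bp = 5000, maf_range = c(0.2, 0.5))
  sim <- simulate_two_populations(cfg)
  H <- sim$truth$haplotypes[seq_len(500), ]  # isolate haplotypes
  pos <- sim$genotypes$snps$pos
  # haplotype allele correlation binned by 5-kb distance
  set.seed(1)
  i <- sample(1500, 4000, replace = TRUE)
  j <- sample(1500, 4000, replace = TRUE)
  keep <- i < j & (pos[j] - pos[i]) < 3e5
  i <- i[keep]; j <- j[keep]
  rr <- vapply(seq_along(i),
               function(k) abs(stats::cor(H[, i[k]], H[, j[k]])), 0)
  d <- pos[j] - pos[i]
  bins <- floor(d / 25000)
  prof <- tapply(rr, bins, mean)
  # decreasing overall, and roughly halves within ~2 decay lengths
  expect_gt(prof["0"], prof["4"])
  expect_gt(prof["0"], 2 * prof["8"])
  expect_lt(prof["4"] / prof["0"], 0.75)
})
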