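test_that("a clean homozygous stretch yields exactly one run", {
  set.seed(2)
  # 150 SNPs spanning ~1.2 Mb with inter-SNP spacing at most 9 kb
  pos <- 1e5 + cumsum(sample(6000:8900, 150, replace = TRUE))
  g <- toy_genotypes(matrix(0L, 1, 150), pos = pos)
  runs <- detect_roh(g)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$start_bp, pos[1])
  expect_identical(runs$end_bp, pos[150])
  expect_identical(runs$n_snps, 150L)
})

test_that("gap splitting and minimum-SNP filtering drop short fragments", {
  # same stretch with a 150-kb inter-SNP gap after SNP 75: two 75-SNP
  # candidates, both below the 100-SNP floor, so nothing is reported
  pos1 <- seq(100000, by = 8000, length.out = 75)
  pos2 <- seq(max(pos1) + 150000, by = 8000, length.out = 75)
  g <- toy_genotypes(matrix(0L, 1, 150), pos = c(pos1, pos2))
  expect_identical(nrow(detect_roh(g)), 0L)
  # 99 homozygous SNPs spanning 600 kb fail the 100-SNP minimum
  g99 <- toy_genotypes(matrix(0L, 1, 99),
                       pos = round(seq(1e5, 7e5, length.out = 99)))
  expect_identical(nrow(detect_roh(g99)), 0L)
})

test_that("the windowed caller agrees with brute-force enumeration", {
  set.seed(33)
  params <- roh_params(window_kb = 1000, window_min_snps = 20,
                       window_max_het = 1, window_max_missing = 3,
                       hit_proportion = 0.05, min_run_kb = 200,
                       min_run_snps = 25, min_density_kb_per_snp = 50,
                       gap_split_kb = 100)
  n_match <- 0
  for (rep_i in 1:100) {
    m <- sample(60:500, 1)
    pos <- sort(sample.int(3e6, m))
    # blocks of homozygosity with scattered hets and missing calls
    x <- rbinom(m, 2, 0.35)
    b0 <- sample.int(m, 1)
    b1 <- min(m, b0 + sample(30:200, 1))
    x[b0:b1] <- sample(c(0L, 2L), b1 - b0 + 1, replace = TRUE)
    x[sample.int(m, round(0.02 * m))] <- 1L
    x[sample.int(m, round(0.02 * m))] <- NA
    g <- toy_genotypes(matrix(x, 1), pos = pos)
    got <- detect_roh(g, params = params)
    want <- oracle_roh(x, pos, params)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
      n_match <- n_match + (nrow(got) == 0L)
    } else {
      expect_identical(nrow(got), nrow(want))
      expect_identical(cbind(got$start_bp, got$end_bp, got$n_snps),
                       unname(cbind(want[, 1], want[, 2], want[, 3])))
      n_match <- n_match + identical(
        cbind(got$start_bp, got$end_bp, as.integer(got$n_snps)),
        unname(cbind(want[, 1], want[, 2], as.integer(want[, 3]))))
    }
  }
  expect_identical(n_match, 100)
})

test_that("chromosomes are processed independently", {
  set.seed(35)
  pos <- sort(sample(seq(1e5, 1.5e6, by = 500), 200))
  x <- c(rep(0L, 150), rbinom(50, 2, 0.5))
  g1 <- toy_genotypes(matrix(x, 1), pos = pos)
  r1 <- detect_roh(g1)
  # appending an unrelated chromosome leaves chromosome-1 runs untouched
  g2 <- genotype_matrix(cbind(matrix(x, 1), matrix(1L, 1, 120)),
                        rbind(g1$snps,
                              data.frame(snp_id = sprintf("t%03d", 1:120),
                                         chrom = "2",
                                         pos = sort(sample.int(2e6, 120)),
                                         allele_a = "A", allele_b = "G")),
                        g1$samples)
  r2 <- detect_roh(g2)
  expect_identical(r1[, -1], r2[r2$chrom == "1", -1])
})

test_that("relaxing the heterozygote allowance never shrinks total run length", {
  set.seed(37)
  for (rep_i in 1:10) {
    m <- 300
    pos <- sort(sample.int(2.5e6, m))
    x <- rbinom(m, 2, 0.3)
    x[100:250] <- sample(c(0L, 2L), 151, replace = TRUE)
    x[sample(100:250, 4)] <- 1L
    g <- toy_genotypes(matrix(x, 1), pos = pos)
    p1 <- roh_params(window_kb = 1000, window_min_snps = 20,
                     min_run_kb = 200, min_run_snps = 25)
    p2 <- p1
    p2$window_max_het <- p1$window_max_het + 1
    tot <- function(p) sum(detect_roh(g, params = p)$length_kb)
    expect_gte(tot(p2), tot(p1))
  }
})

test_that("population ROH summaries aggregate run lengths correctly", {
  rohs <- data.frame(sample_id = c("a", "a", "b"), chrom = "1",
                     start_bp = c(0, 0, 0),
                     end_bp = c(600000, 2000000, 3000000),
                     n_snps = c(120L, 300L, 400L))
  ids <- c("a", "b", "c")
  # one 3-Mb run lands in [2.5, 5) only
  cls <- roh_length_class_summary(rohs, ids, breaks_mb = c(0.5, 2.5, 5, Inf))
  expect_equal(cls$proportion[cls$bin == "[2.5,5)"], 1 / 3)
  expect_equal(cls$proportion[cls$bin == "[5,Inf)"], 0)
  # individual c (no runs) contributes to no bin; a's two runs share a bin
  expect_equal(sum(cls$proportion * length(ids)), 2)
  # mean total length: individual a has 0.6 + 2 Mb; at L = 1 Mb only the 2
  mt <- mean_total_roh_length(rohs[rohs$sample_id == "a", ], "a",
                              min_length_grid_mb = c(0.5, 1))
  expect_equal(mt$mean_total_mb, c(2.6, 2))
  # empty input: identically zero, and the curve never increases
  mt0 <- mean_total_roh_length(rohs[0, ], ids)
  expect_true(all(mt0$mean_total_mb == 0))
  set.seed(39)
  rr <- data.frame(sample_id = sample(letters[1:4], 30, TRUE), chrom = "1",
                   start_bp = 0, end_bp = runif(30, 1e5, 8e6),
                   n_snps = 100L)
  mtr <- mean_total_roh_length(rr, letters[1:4])
  expect_true(all(diff(mtr$mean_total_mb) <= 0))
})

test_that("consanguineous cohorts show the intermediate-length ROH excess", {
  cfg_con <- sim_config(seed = 41, n_pop1 = 100, n_pop2 = 50, n_snps = 20000,
                        n_chromosomes = 2, ld_decay_bp = 5000,
                        snp_spacing_bp = 5000, maf_range = c(0.1, 0.5),
                        recomb_rate_per_bp = 2.5e-8, inbred_fraction = 0.15)
  sim <- simulate_cohorts(cfg_con)
  g <- sim$genotypes
  runs <- detect_roh(g)
  iso <- g$samples$sample_id[g$samples$population == "isolate"]
  out <- g$samples$sample_id[g$samples$population == "outbred"]
  cls_i <- roh_length_class_summary(runs[runs$sample_id %in% iso, ], iso,
                                    breaks_mb = c(0.5, 2.5, 5, Inf))
  cls_o <- roh_length_class_summary(runs[runs$sample_id %in% out, ], out,
                                    breaks_mb = c(0.5, 2.5, 5, Inf))
  expect_gt(cls_i$proportion[cls_i$bin == "[2.5,5)"],
            cls_o$proportion[cls_o$bin == "[2.5,5)"])
})
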