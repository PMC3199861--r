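test_that("best-proxy search maximises |r| with deterministic tie-breaks", {
  set.seed(71)
  base <- rbinom(300, 2, 0.4)
  noisy <- function(x, k) {
    flip <- sample(300, k)
    x[flip] <- rbinom(k, 2, 0.4)
    x
  }
  calls <- cbind(base, noisy(base, 30), base, rbinom(300, 2, 0.3),
                 noisy(base, 30))
  pos <- c(1e6, 1e6 + 1e4, 1e6 + 5e4, 1e6 + 7e4, 1e6 + 1e5)
  g <- toy_genotypes(calls, pos = as.integer(pos))
  # an exact duplicate 50 kb away wins with |r| = 1
  b <- best_proxy(g, "s0001")
  expect_identical(b$proxy, "s0003")
  expect_equal(abs(b$max_r), 1)
  # equal-|r| candidates at 10 kb and 100 kb: nearer one wins
  g2 <- subset_genotypes(g, snps = c(1, 2, 4, 5))
  b2 <- best_proxy(g2, "s0001")
  expect_identical(b2$proxy, "s0002")
  # nothing within the window: flagged
  gfar <- toy_genotypes(cbind(base, rbinom(300, 2, 0.3)),
                        pos = c(1L, 3000000L))
  expect_true(is.na(best_proxy(gfar, "s0001")$proxy))
})

test_that("analytic power collapses to alpha with no signal and matches Monte Carlo", {
  set.seed(73)
  s1 <- rbinom(977, 2, 0.3)
  # no effect: power equals the level exactly
  expect_equal(analytic_power(s1, s1, 0, 1e-5), 1e-5)
  # a proxy with zero sample covariance gives ncp 0, power alpha
  s2 <- c(0L, 2L, 2L, 0L, rep(1L, 96))
  s1o <- c(0L, 0L, 2L, 2L, rep(1L, 96))
  expect_equal(sum((s2 - mean(s2)) * s1o), 0)
  # upper-tail round trip through qnorm/pnorm is exact to ~1e-10 relative
  expect_equal(analytic_power(s1o, s2, 0.02, 1e-5), 1e-5, tolerance = 1e-8)
  # Monte-Carlo oracle: OLS with the normal Wald test, 2e4 phenotype draws
  v_s <- 0.02
  alpha <- 1e-5
  n <- length(s1)
  sigma <- sqrt(var(s1) * (1 - v_s) / v_s)
  set.seed(74)
  n_reps <- 2e4
  hits <- 0L
  s1c <- s1 - mean(s1)
  ss1 <- sum(s1c^2)
  for (chunk in 1:20) {
    Y <- s1 + matrix(rnorm(n * n_reps / 20, 0, sigma), n, n_reps / 20)
    bh <- as.numeric(crossprod(s1c, Y)) / ss1
    Yc <- Y - matrix(colMeans(Y), n, ncol(Y), byrow = TRUE)
    rss <- colSums(Yc^2) - bh^2 * ss1
    z <- bh / sqrt(rss / (n - 2) / ss1)
    hits <- hits + sum(2 * pnorm(-abs(z)) < alpha)
  }
  p_mc <- hits / n_reps
  p_an <- analytic_power(s1, s1, v_s, alpha)
  expect_lt(abs(p_an - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / n_reps))
  # swapping the allele coding of the proxy leaves power unchanged
  expect_equal(analytic_power(s1, 2L - s1 + 0, v_s, c(1e-5, 1e-7)),
               analytic_power(s1, s1, v_s, c(1e-5, 1e-7)))
})

test_that("the mixed-model simulation reduces to the analytic formula", {
  set.seed(75)
  s1 <- rbinom(500, 2, 0.3)
  G <- diag(500)
  # minimal heritability: no polygenic term at all
  sp <- power_spec(v_s = 0.03, h2 = 0.03, alpha_grid = c(1e-5, 1e-7),
                   n_reps = 4000)
  sim <- simulate_power_mixed(s1, s1, G, sp, seed = 76)
  an <- analytic_power(s1, s1, 0.03, sp$alpha_grid)
  for (k in 1:2) {
    se <- sqrt(max(an[k] * (1 - an[k]), 1e-9) / sp$n_reps)
    expect_lt(abs(sim$power[k] - an[k]), 3 * se + 1e-4)
  }
  # identity G with h2 = 0.5: matches the analytic value computed with the
  # pooled residual variance sigma_g^2 + sigma_e^2
  sp2 <- power_spec(v_s = 0.03, h2 = 0.5, alpha_grid = c(1e-4), n_reps = 4000)
  sim2 <- simulate_power_mixed(s1, s1, G, sp2, seed = 77)
  vc <- isopop:::power_variance_components(s1, G, sp2)
  s1c <- s1 - mean(s1)
  ncp <- sum(s1c * s1) / sum(s1c^2) /
    sqrt((vc$sigma_g2 + vc$sigma_e2) / sum(s1c^2))
  z <- qnorm(1 - sp2$alpha_grid / 2)
  an2 <- pnorm(-z + abs(ncp)) + pnorm(-z - abs(ncp))
  expect_lt(abs(sim2$power[1] - an2), 3 * sqrt(an2 * (1 - an2) / sp2$n_reps))
})

test_that("family structure inflates the naive estimator variance as the sandwich predicts", {
  fx <- sib_block_fixture(n = 200)
  s <- fx$s
  G <- fx$G
  # identity G: no inflation
  sp <- power_spec(v_s = 0.02, h2 = 1, n_reps = 3000)
  vi_id <- variance_inflation(s, s, diag(200), sp, seed = 78)
  expect_lt(abs(vi_id$ratio - 1), 3 * vi_id$mc_se)
  # minimal heritability: no inflation either, whatever G
  sp_min <- power_spec(v_s = 0.02, h2 = 0.02, n_reps = 3000)
  vi_min <- variance_inflation(s, s, G, sp_min, seed = 79)
  expect_lt(abs(vi_min$ratio - 1), 3 * vi_min$mc_se)
  # sib blocks sharing genotypes at h2 = 1: closed-form sandwich oracle
  vi <- variance_inflation(s, s, G, sp, seed = 80)
  vc <- isopop:::power_variance_components(s, G, sp)
  sc <- s - mean(s)
  V <- vc$sigma_g2 * G + vc$sigma_e2 * diag(200)
  var_true <- as.numeric(t(sc) %*% V %*% sc) / sum(sc^2)^2
  expected_ratio <- var_true / ((vc$sigma_g2 + vc$sigma_e2) / sum(sc^2))
  expect_gt(vi$ratio, 1.1)
  expect_lt(abs(vi$ratio - expected_ratio), 4 * vi$mc_se)
})

test_that("inflation crosses the power curve: gain in the far tail, loss near the mean", {
  # ncp about 3.2 sits between z(0.05) and z(1e-7): the widened null spread
  # helps at the stringent threshold and hurts at the liberal one
  fx <- sib_block_fixture(n = 200)
  sp <- power_spec(v_s = 0.05, h2 = 1, alpha_grid = c(0.05, 1e-7),
                   n_reps = 6000)
  sim <- simulate_power_mixed(fx$s, fx$s, fx$G, sp, seed = 81)
  an <- analytic_power(fx$s, fx$s, 0.05, sp$alpha_grid)
  expect_lt(sim$power[1], an[1])   # liberal threshold: loss
  expect_gt(sim$power[2], an[2])   # stringent threshold: gain
})

test_that("power distributions respect duplicates, effect size and sample size", {
  set.seed(83)
  base <- rbinom(977, 2, 0.4)
  g <- toy_genotypes(cbind(base, base), pos = c(1000L, 11000L))
  sp <- power_spec(v_s = 0.02, h2 = 0.02, alpha_grid = c(1e-5))
  pd <- power_distribution(g, "1", sp)
  # a two-SNP chromosome of duplicates: all three quartiles coincide
  expect_equal(pd$quartiles$q1, pd$quartiles$q3)
  expect_equal(pd$quartiles$median / 100,
               analytic_power(base, base, 0.02, 1e-5), tolerance = 1e-12)
  # a simulated chromosome: v_s = 0.05 dominates v_s = 0.02 elementwise,
  # and n = 977 dominates n = 532
  cfg <- sim_config(seed = 84, n_pop1 = 977, n_pop2 = 5, n_snps = 300,
                    n_chromosomes = 1, ld_decay_bp = 25000,
                    maf_range = c(0.1, 0.5))
  gs <- simulate_two_populations(cfg)$genotypes
  iso <- which(gs$samples$population == "isolate")
  q02 <- power_distribution(gs, "1", power_spec(v_s = 0.02,
                                                alpha_grid = c(1e-5, 1e-7)),
                            samples = iso)$quartiles
  q05 <- power_distribution(gs, "1", power_spec(v_s = 0.05,
                                                alpha_grid = c(1e-5, 1e-7)),
                            samples = iso)$quartiles
  expect_true(all(as.matrix(q05[, c("q1", "median", "q3")]) >=
                    as.matrix(q02[, c("q1", "median", "q3")])))
  q532 <- power_distribution(gs, "1", power_spec(v_s = 0.02,
                                                 alpha_grid = c(1e-5, 1e-7)),
                             samples = iso[1:532])$quartiles
  expect_true(all(as.matrix(q02[, c("q1", "median", "q3")]) >
                    as.matrix(q532[, c("q1", "median", "q3")])))
})
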