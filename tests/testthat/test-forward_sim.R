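test_that("two-locus total selection coefficient matches the closed form", {
  # haploid-equivalent: neutral A at p = 0.5 hitchhiking with beneficial B
  # (s_b = 0.05) at q = 0.5, D = 0.1: 20 haplotypes = 7 AB, 3 Ab, 3 aB, 7 ab
  s_b <- 0.05
  hap <- rbind(
    matrix(rep(c(1, 1), 7), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), 7), ncol = 2, byrow = TRUE))
  st <- total_selection_coefficients(hap, s = c(0, s_b), ploidy = "haploid")
  p <- 0.5; q <- 0.5; D <- 7 / 20 - p * q
  expect_equal(D, 0.1)
  oracle <- s_b * D / (p * (1 - p) * (1 + s_b * q))
  expect_equal(st[1], oracle, tolerance = 1e-10)
  expect_equal(round(st[1], 6), 0.019512)
  # the selected locus itself: wF = 1+s, wNF = 1 -> s/(1 + s q)
  expect_equal(st[2], s_b / (1 + s_b * q), tolerance = 1e-10)
  # linkage equilibrium (D = 0): neutral locus has s_total = 0
  hap_le <- cbind(rep(c(1, 0), each = 10), rep(c(1, 0), times = 10))
  st_le <- total_selection_coefficients(hap_le, c(0, s_b), ploidy = "haploid")
  expect_equal(st_le[1], 0, tolerance = 1e-12)
})

test_that("diploid s_total uses dosage weighting and matches the C++ simulator", {
  sim <- run_regime(sim_params(N = 40, genome_length = 1e5, r = 1e-6,
                               mu_neutral = 5e-5, U = 2, s_sel = -0.04,
                               burn_in = 150, t_interval = 5, seed = 99),
                    return_state = TRUE)
  r_side <- total_selection_coefficients(sim$genotypes, sim$s_values, h = 0.5)
  expect_equal(unname(r_side), sim$selection$s_total, tolerance = 1e-8)
  expect_gt(sd(sim$selection$s_total), 0)
})

test_that("neutral regime has exactly zero total selection coefficients", {
  sim <- run_regime(sim_params(N = 50, genome_length = 1e5, r = 1e-6,
                               mu_neutral = 1e-4, U = 0, burn_in = 200,
                               t_interval = 5, seed = 3))
  expect_gt(n_loci(sim$table), 0)
  expect_true(all(sim$selection$s_total == 0))
  expect_true(all(sim$selection$neutral))
  expect_equal(sim$mean_fitness, 1)
})

test_that("simulator is deterministic given a seed", {
  p <- sim_params(N = 30, genome_length = 1e5, r = 1e-6, mu_neutral = 1e-4,
                  U = 0.5, s_sel = 0.02, burn_in = 120, t_interval = 5,
                  seed = 2024)
  a <- run_regime(p)
  b <- run_regime(p)
  expect_identical(freqs(a$table), freqs(b$table))
  expect_identical(a$selection$s_total, b$selection$s_total)
  p2 <- p; p2$seed <- 2025
  expect_false(identical(freqs(a$table), freqs(run_regime(p2)$table)))
})

test_that("frequencies are conserved: snapshot loci stay within [0, 1] and move by drift", {
  sim <- run_regime(sim_params(N = 50, genome_length = 1e5, r = 1e-6,
                               mu_neutral = 1e-4, U = 0, burn_in = 200,
                               t_interval = 3, seed = 17))
  f <- freqs(sim$table)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(any(f[, 1] != f[, 2]))
})

test_that("pool-seq noise has the compound-binomial variance", {
  # Var(phat) = p(1-p) (1/2n + 1/d - 1/(2nd)); p = 0.5, n = 100, d = 100
  p <- 0.5; n <- 100; d <- 100
  L <- 1e5
  tab <- freq_table("1", seq_len(L), matrix(p, L, 2),
                    t_labels = c("t0", "t1"), sort = FALSE)
  noisy <- pool_seq_noise(tab, n, d, seed = 31)
  err <- freqs(noisy)[, 1] - p
  v_expect <- p * (1 - p) * (1 / (2 * n) + 1 / d - 1 / (2 * n * d))
  expect_equal(v_expect, 0.0037375)
  v_emp <- mean(err^2)
  se <- sd(err^2) / sqrt(L)
  expect_lt(abs(v_emp - v_expect), 3 * se)
  # depth -> infinity limit: variance -> p(1-p)/2n
  deep <- pool_seq_noise(tab, n, 1e6, seed = 32)
  v_deep <- mean((freqs(deep)[, 1] - p)^2)
  expect_equal(v_deep, p * (1 - p) / (2 * n), tolerance = 0.05)
  # absorbing frequencies are reproduced exactly
  fixed <- freq_table("1", 1:4, cbind(c(0, 1, 0, 1), c(0, 1, 0, 1)),
                      t_labels = c("t0", "t1"), sort = FALSE)
  expect_identical(freqs(pool_seq_noise(fixed, 10, 10, seed = 1)),
                   freqs(fixed))
})

test_that("fast cohort sampler: drift-only compounding and growth-law variances", {
  L <- 6e4; t <- 10; p0 <- 0.5
  # drift only: C_t = 1 - (1 - C1)^t, frequency independent
  C1 <- 1e-3
  tab <- fast_cohort_sampler(L, p0, "none", t_gens = t,
                             drift_C_per_gen = C1, seed = 5)
  C1r <- attr(tab, "drift_C_realized")
  dp <- freqs(tab)[, 2] - freqs(tab)[, 1]
  C_emp <- var(dp) / (p0 * (1 - p0))
  C_th <- 1 - (1 - C1r)^t
  expect_equal(C_emp, C_th, tolerance = 4 * sqrt(2 / L))
  # constant per-locus s: Var(dp) ~ [p(1-p)]^2 t^2 sigma_s^2
  sg <- 0.01
  tabc <- fast_cohort_sampler(L, p0, "constant", sigma_s = sg, t_gens = t,
                              seed = 6)
  expect_equal(var(freqs(tabc)[, 2] - freqs(tabc)[, 1]),
               (p0 * (1 - p0))^2 * t^2 * sg^2, tolerance = 0.05)
  # iid per-generation s: Var(dp) ~ [p(1-p)]^2 t sigma_s^2
  tabi <- fast_cohort_sampler(L, p0, "iid", sigma_s = sg, t_gens = t,
                              seed = 7)
  expect_equal(var(freqs(tabi)[, 2] - freqs(tabi)[, 1]),
               (p0 * (1 - p0))^2 * t * sg^2, tolerance = 0.05)
  # sampler is deterministic given seed and records requested timepoints
  again <- fast_cohort_sampler(L, p0, "iid", sigma_s = sg, t_gens = t,
                               seed = 7)
  expect_identical(freqs(again), freqs(tabi))
  multi <- fast_cohort_sampler(100, 0.6, "none", t_gens = 8,
                               drift_C_per_gen = 1e-3,
                               record_at = c(0, 2, 4, 8), seed = 8)
  expect_identical(t_labels(multi), c("t0", "t2", "t4", "t8"))
})

test_that("simulation truth: sigma2_by_frequency bins and weights correctly", {
  sel <- data.frame(chrom = "1", pos = 1:6000,
                    p = runif(6000, 0.02, 0.98),
                    s_total = rnorm(6000, 0, 0.02))
  sel$s_total[1:3000] <- 0
  out <- sigma2_by_frequency(sel, binning_scheme(0.1, min_loci = 50))
  expect_true(attr(out, "constancy_approximation"))
  def <- !is.na(out$sigma2_sbar)
  expect_true(any(def))
  expect_equal(out$weighted[def],
               out$p_bar[def] * (1 - out$p_bar[def]) * out$sigma2_sbar[def])
  # all-neutral table gives zero variance in every defined bin
  sel0 <- transform(sel, s_total = 0)
  out0 <- sigma2_by_frequency(sel0, binning_scheme(0.1, min_loci = 50))
  expect_true(all(out0$sigma2_sbar[!is.na(out0$sigma2_sbar)] == 0))
})

test_that("structured population: m = 0.5 is panmictic-like, small m creates an intermediate-frequency variance deficit", {
  pan <- run_regime(sim_params(N = 100, genome_length = 5e5, r = 2e-6,
                               mu_neutral = 4e-6, burn_in = 600,
                               t_interval = 10, n_demes = 2, m = 0.5,
                               seed = 11))
  expect_gt(n_loci(pan$table), 50)
  # with m = 0 the demes are fully independent: a mutation present in one
  # deme can never spread to the other, so no locus exceeds frequency 1/2
  # unless it predates the (absent) split; with a fresh population all
  # frequencies stay within one deme's share
  iso <- run_regime(sim_params(N = 100, genome_length = 5e5, r = 2e-6,
                               mu_neutral = 4e-6, burn_in = 600,
                               t_interval = 10, n_demes = 2, m = 0,
                               seed = 12))
  expect_true(all(freqs(iso$table)[, 1] <= 0.5 + 1e-12))
  # differentiated demes (small m): pooled C_t lower at intermediate than at
  # high major-allele frequencies (variance-deficit direction, sign test)
  reps <- lapply(1:8, function(k) {
    run_regime(sim_params(N = 100, genome_length = 5e5, r = 2e-6,
                          mu_neutral = 4e-6, burn_in = 600, t_interval = 10,
                          n_demes = 2, m = 0.002, seed = 300 + k),
               chrom = paste0("rep", k))
  })
  tab <- pool_tables(reps)
  pol <- polarize_major(tab)
  pr <- variance_coefficient(pol, t_gens = 10,
                             scheme = binning_scheme(0.1, min_loci = 80))
  C_mid <- pr$C[pr$bin_lo == 0.5]
  C_high <- pr$C[pr$bin_lo == 0.8]
  expect_lt(C_mid, C_high)
})

test_that("measurement error alone keeps the binomial form: flat C across frequency", {
  # cohorts defined by the true initial frequency; the second timepoint is a
  # pool-seq remeasurement of the same frequencies, so all divergence is
  # sampling error with variance ~ p(1-p)
  set.seed(8)
  L <- 8e4
  p0 <- runif(L, 0.5, 0.99)
  true_tab <- freq_table("1", seq_len(L) * 100, cbind(p0, p0),
                         t_labels = c("t0", "t1"), sort = FALSE)
  noisy <- pool_seq_noise(true_tab, 100, 100, seed = 9)
  tab <- freq_table("1", seq_len(L) * 100,
                    cbind(p0, freqs(noisy)[, 2]),
                    t_labels = c("t0", "t1"), sort = FALSE)
  pr <- variance_coefficient(tab, t_gens = 1,
                             scheme = binning_scheme(0.05, min_loci = 500))
  d <- !is.na(pr$C)
  fitl <- summary(lm(pr$C[d] ~ pr$p_bar[d]))
  expect_gt(fitl$coefficients[2, 4], 0.01)   # slope indistinguishable from 0
  # and the level matches the one-endpoint compound-binomial coefficient
  expect_equal(mean(pr$C[d]), 0.25 * (1 / 200 + 1 / 100 - 1 / 20000) / 0.25,
               tolerance = 0.05)
})
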