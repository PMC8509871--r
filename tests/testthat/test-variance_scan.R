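make_table <- function(f, chrom = "1", spacing = 1000) {
  f <- as.matrix(f)
  freq_table(rep(chrom, nrow(f)), seq_len(nrow(f)) * spacing, f,
             t_labels = paste0("t", seq_len(ncol(f)) - 1), sort = FALSE)
}

fake_profile <- function(C, lo = 0.5 + 0.1 * (seq_along(C) - 1)) {
  structure(data.frame(bin_lo = lo, bin_hi = lo + 0.1, p_bar = lo + 0.05,
                       C = C, n = 200L),
            t_gens = 1, min_loci = 10,
            class = c("variance_profile", "data.frame"))
}

test_that("major-allele polarization flips below-0.5 loci, keeps ties, is idempotent", {
  tab <- make_table(rbind(c(0.3, 0.4), c(0.5, 0.2), c(0.8, 0.9)))
  pol <- polarize_major(tab)
  expect_equal(freqs(pol)[1, ], c(t0 = 0.7, t1 = 0.6))
  expect_equal(freqs(pol)[2, ], c(t0 = 0.5, t1 = 0.2))  # tie keeps orientation
  expect_equal(freqs(pol)[3, ], c(t0 = 0.8, t1 = 0.9))
  expect_equal(attr(pol, "flipped"), c(TRUE, FALSE, FALSE))
  expect_equal(freqs(polarize_major(pol)), freqs(pol))
  # polarizing at the second timepoint uses that column
  pol2 <- polarize_major(tab, ref_timepoint = "t1")
  expect_equal(freqs(pol2)[2, ], c(t0 = 0.5, t1 = 0.8))
})

test_that("frequency binning uses half-open bins and excludes fixation", {
  sch <- binning_scheme(0.025)
  expect_equal(bin_by_frequency(0.5, sch), 1L)        # [0.500, 0.525)
  expect_equal(bin_by_frequency(0.525, sch), 2L)      # edge goes right
  expect_equal(bin_by_frequency(0.5249999, sch), 1L)
  expect_true(is.na(bin_by_frequency(1.0, sch)))      # fixed loci excluded
  expect_equal(bin_by_frequency(0.975, sch), 20L)
  expect_error(bin_by_frequency(0.4, sch), "consistency")
})

test_that("variance coefficient: hand-worked bin, zero variance, denominator n-1", {
  f0 <- rep(0.5, 4)
  f1 <- f0 + c(0.1, -0.1, 0.1, -0.1)
  tab <- make_table(cbind(f0, f1))
  pr <- variance_coefficient(tab, "t0", "t1", t_gens = 10,
                             scheme = binning_scheme(0.05, min_loci = 4))
  i <- which(!is.na(pr$C))
  expect_length(i, 1)
  expect_equal(pr$bin_lo[i], 0.5)
  expect_equal(pr$C[i], (0.04 / 3) / 0.25)   # = 0.05333...
  expect_equal(pr$n[i], 4L)
  # all identical changes -> zero variance
  tab0 <- make_table(cbind(rep(0.6, 5), rep(0.65, 5)))
  pr0 <- variance_coefficient(tab0, t_gens = 5,
                              scheme = binning_scheme(0.05, min_loci = 5))
  expect_equal(pr0$C[!is.na(pr0$C)], 0)
  # no bin reaching min_loci is an error
  expect_error(variance_coefficient(tab, t_gens = 10,
                                    scheme = binning_scheme(0.05, min_loci = 50)),
               "empty profile")
})

test_that("loci with missing timepoints are excluded from binning", {
  f <- cbind(c(0.55, 0.56, 0.57, NA), c(0.6, 0.61, NA, 0.6))
  tab <- make_table(f)
  pr <- variance_coefficient(tab, t_gens = 1,
                             scheme = binning_scheme(0.05, min_loci = 2))
  expect_equal(sum(pr$n), 2)
})

test_that("min-subtraction shifts to zero minimum and is idempotent", {
  pr <- fake_profile(c(0.03, 0.01, 0.02))
  nm <- normalize_min(pr)
  expect_equal(nm$C, c(0.02, 0.00, 0.01))
  expect_equal(normalize_min(nm)$C, nm$C)
  one <- fake_profile(c(NA, 0.05, NA))
  expect_equal(normalize_min(one)$C, c(NA, 0, NA))
})

test_that("excess variance subtracts bins and is shift-invariant", {
  set.seed(2)
  tab <- make_table(cbind(runif(4000, 0.5, 1), runif(4000, 0.5, 1)))
  pr <- variance_coefficient(tab, t_gens = 1, scheme = binning_scheme(0.05))
  e <- excess_variance(pr)
  expect_equal(e$excess, pr$C[1] - pr$C[9])
  expect_equal(excess_variance(pr, c(0.9, 0.95), c(0.9, 0.95))$excess, 0)
  # invariance under min-subtraction and arbitrary constant shifts
  expect_equal(excess_variance(normalize_min(pr))$excess, e$excess)
  shifted <- pr
  shifted$C <- pr$C + 0.123
  expect_equal(excess_variance(shifted)$excess, e$excess)
  # undefined bin errors by name
  thin <- variance_coefficient(tab, t_gens = 1,
                               scheme = binning_scheme(0.05, min_loci = 100))
  thin$C[1] <- NA
  expect_error(excess_variance(thin), "\\[0.5, 0.55\\) is undefined")
})

test_that("sigma2 lower bound: arithmetic, zero, negative flag, 1/t^2 scaling", {
  b <- sigma2_lower_bound(2.5e-3, t_gens = 10, p_bar = 0.5)
  expect_equal(b$sigma2_bound, 1e-4)
  expect_false(b$negative)
  expect_equal(sigma2_lower_bound(0, 1, 0.5)$sigma2_bound, 0)
  bn <- sigma2_lower_bound(-1e-3, 10, 0.5)
  expect_true(bn$negative)
  expect_equal(bn$sigma2_bound, -4e-5)
  expect_error(sigma2_lower_bound(1e-3, 10, 1), "domain error")
  # doubling t at fixed excess quarters the bound
  expect_equal(sigma2_lower_bound(2.5e-3, 20, 0.5)$sigma2_bound,
               sigma2_lower_bound(2.5e-3, 10, 0.5)$sigma2_bound / 4)
})

test_that("excess trajectory fixes cohorts at t0 and needs >= 3 timepoints", {
  two <- make_table(cbind(runif(10, 0.5, 1), runif(10, 0.5, 1)))
  expect_error(excess_trajectory(two, t_gens = 1), "excess_variance")
  set.seed(9)
  L <- 4000
  p0 <- runif(L, 0.5, 0.98)
  f <- cbind(p0, p0 + rnorm(L, 0, 0.01), p0 + rnorm(L, 0, 0.02))
  f <- pmin(pmax(f, 0), 1)
  colnames(f) <- c("t0", "t1", "t2")
  tab <- make_table(f)
  traj <- excess_trajectory(tab, t_gens = c(5, 10), min_loci = 50)
  expect_equal(nrow(traj), 2)
  expect_equal(traj$t_gens, c(5, 10))
  expect_equal(traj$n, rep(traj$n[1], 2))       # cohort fixed at t0
  expect_equal(traj$excess, traj$C_p - traj$C_pstar)
})
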