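#' Wright-Fisher variance coefficient
#'
#' Closed-form variance coefficient of neutral allele-frequency change under
#' Wright-Fisher drift: after `t` generations in a diploid population of size
#' `N`, `Var(dp | p) = C_t p(1-p)` with `C_t = 1 - (1 - 1/2N)^t`. The same
#' form with `N` replaced by a variance effective size `N_e` covers a broad
#' class of exchangeable drift models.
#'
#' @param N Diploid (effective) population size, `>= 1`.
#' @param t Number of generations, `>= 0` (need not be an integer).
#' @return The variance coefficient `C_t`, a number in `[0, 1]`.
#' @examples
#' wf_variance_coefficient(1000, 10) # ~ 10/2000 for t << N
#' @export
wf_variance_coefficient <- function(N, t) {
  stopifnot(is.numeric(N), is.numeric(t), all(N >= 1), all(t >= 0))
  1 - (1 - 1 / (2 * N))^t
}

#' Selective divergence after t generations
#'
#' Variance of allele-frequency change created by among-locus variation in
#' total selection coefficients. For a cohort at initial frequency `p` with
#' per-generation among-locus variance `sigma2_per_gen`, the contribution is
#' `[p(1-p)]^2 Var(sum_i s_i)`, where the sum runs over the `t` intervening
#' generations. The temporal covariance structure of the per-generation
#' coefficients sets the growth law:
#' \describe{
#'   \item{`"full"`}{perfectly persistent selection; `Var(sum s_i) = t^2 sigma2`
#'     (quadratic growth).}
#'   \item{`"none"`}{temporally uncorrelated selection; `Var(sum s_i) = t sigma2`
#'     (linear growth, a selective random walk).}
#'   \item{`"decay"`}{geometric decay of among-locus covariance,
#'     `Cov(s_i, s_j) = rho^|i-j| sigma2`, the phenomenological analogue of
#'     linkage-disequilibrium decay `(1-r)^|j-i|` under recombination.}
#' }
#'
#' @param sigma2_per_gen Among-locus variance of the per-generation total
#'   selection coefficient (per-generation^2 scale), `>= 0`.
#' @param t Generations, positive integer.
#' @param p Initial allele frequency, in `(0, 1)`.
#' @param covariance_model One of `"full"`, `"none"`, `"decay"`.
#' @param rho Covariance decay rate per generation of separation, in `[0, 1]`;
#'   only used for `covariance_model = "decay"`. `rho = 1` reproduces `"full"`,
#'   `rho = 0` reproduces `"none"`.
#' @return Variance contribution to `Var(dp | p)` (not divided by `p(1-p)`).
#' @examples
#' selective_divergence(1e-4, 10, 0.5, "full") # 6.25e-4
#' selective_divergence(1e-4, 10, 0.5, "none") # 6.25e-5
#' @export
selective_divergence <- function(sigma2_per_gen, t, p,
                                 covariance_model = c("full", "none", "decay"),
                                 rho = NULL) {
  covariance_model <- match.arg(covariance_model)
  stopifnot(sigma2_per_gen >= 0, t >= 1, t == as.integer(t), p > 0, p < 1)
  nsum <- switch(covariance_model,
    full = t^2,
    none = t,
    decay = {
      if (is.null(rho) || rho < 0 || rho > 1) {
        stop("'rho' must be in [0, 1] for the decay covariance model")
      }
      # sum_{i,j} rho^|i-j| = t + 2 * sum_{d=1}^{t-1} (t - d) rho^d
      d <- seq_len(max(t - 1, 0))
      t + 2 * sum((t - d) * rho^d)
    }
  )
  (p * (1 - p))^2 * nsum * sigma2_per_gen
}

#' Selective perturbation of the drift variance
#'
#' When a cohort has a mean selective bias, its frequencies are displaced and
#' the drift contribution to divergence is perturbed by
#' `D_t c (1 - 2p) E[sum_i s_i]`, where `c` is a frequency-independent constant
#' of order 1 whose exact value is population-model specific. The perturbation
#' vanishes at `p = 0.5` and is antisymmetric about it.
#'
#' @param D_t Drift variance coefficient over the measurement interval.
#' @param c Order-1 constant (default 1; sign unconstrained).
#' @param p Initial allele frequency.
#' @param mean_total_s Expected summed total selection coefficient
#'   `E[sum_i s_i]` over the interval.
#' @return Additive perturbation to `C_t(p)` (same units as `C_t`).
#' @export
drift_perturbation <- function(D_t, c = 1, p, mean_total_s) {
  stopifnot(D_t >= 0, p > 0, p < 1)
  D_t * c * (1 - 2 * p) * mean_total_s
}

#' Migration divergence term
#'
#' Migration from a differentiated source population contributes
#' `Var(m (p* - p) | p) = m^2 Var(p* - p | p)` to the among-locus variance of
#' frequency change, where `m` is the fraction of the focal population replaced
#' by migrants each generation and `p*` the source-population frequency.
#'
#' @param m Migration fraction per generation, in `[0, 1]`.
#' @param var_source_diff `Var(p* - p | p)`, `>= 0`.
#' @return Variance contribution `m^2 Var(p* - p | p)`.
#' @export
migration_divergence <- function(m, var_source_diff) {
  stopifnot(m >= 0, m <= 1, var_source_diff >= 0)
  m^2 * var_source_diff
}

#' Sampling standard error of a variance coefficient
#'
#' Assuming approximately normal `dp`, the sample variance over `L` independent
#' loci has variance `2 Var(dp|p)^2 / (L - 1) ~ 2 Var(dp|p)^2 / L`, so the
#' standard error of `C_t(p) = Var(dp|p)/p(1-p)` is `sqrt(2/L) C_t(p)`
#' (large-L form).
#'
#' @param C Variance coefficient magnitude.
#' @param L Number of independent loci, `>= 2`.
#' @return Standard error of `C`.
#' @export
se_variance_coefficient <- function(C, L) {
  stopifnot(C >= 0, all(L >= 2))
  sqrt(2 / L) * C
}

#' Minimum number of independent loci to detect selective divergence
#'
#' The excess-variance signal contributed by among-locus selection variance
#' `sigma2` at frequency `p` over `t` generations is `t^2 p(1-p) sigma2` (in
#' `C_t` units). Detection requires this signal to reach `k` standard errors
#' `sqrt(2/L) C`, giving the closed form
#' `L = 2 (k C / (t^2 p(1-p) sigma2))^2`.
#'
#' @param C Variance-coefficient magnitude (drift plus measurement noise).
#' @param sigma2 Among-locus variance of the per-generation total selection
#'   coefficient, `> 0` for a finite answer.
#' @param p Cohort frequency in `(0, 1)`.
#' @param t Generations between measurements.
#' @param k Detection threshold in standard-error multiples (default 1, the
#'   scale of statistically detectable differences).
#' @return Minimum `L`; `Inf` if `sigma2` is zero.
#' @examples
#' detection_limit(1e-2, 1e-4, 0.5, 1) # 3.2e5, i.e. at least ~1e5 SNPs
#' @export
detection_limit <- function(C, sigma2, p, t, k = 1) {
  stopifnot(C > 0, sigma2 >= 0, p > 0, p < 1, t > 0, k > 0)
  if (sigma2 == 0) {
    return(Inf)
  }
  signal <- t^2 * p * (1 - p) * sigma2
  2 * (k * C / signal)^2
}
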