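#' Polarize a table to the major allele at a reference timepoint
#'
#' Flips each locus (`p -> 1 - p` at every timepoint) if and only if its
#' frequency at `ref_timepoint` is below 0.5, so that the reported allele is
#' the major allele at the reference timepoint. Ties at exactly 0.5 keep the
#' original orientation. Idempotent.
#'
#' @param table A `freq_table`.
#' @param ref_timepoint Timepoint label used to define the major allele
#'   (default: first timepoint).
#' @return A `freq_table` with attribute `flipped` (logical per locus).
#' @export
polarize_major <- function(table, ref_timepoint = t_labels(table)[1]) {
  stopifnot(inherits(table, "freq_table"))
  lb <- t_labels(table)
  if (!ref_timepoint %in% lb) {
    stop("ref_timepoint '", ref_timepoint, "' not among timepoints")
  }
  flip <- !is.na(table[[paste0("freq_", ref_timepoint)]]) &
    table[[paste0("freq_", ref_timepoint)]] < 0.5
  out <- table
  for (l in lb) {
    cn <- paste0("freq_", l)
    out[[cn]] <- ifelse(flip, 1 - out[[cn]], out[[cn]])
  }
  attr(out, "flipped") <- flip
  out
}

#' Frequency binning scheme
#'
#' Half-open major-allele frequency bins `[lo, lo + width)` tiling `range`.
#'
#' @param bin_width Bin width in frequency units (default 0.025, i.e. 2.5%
#'   bins), `0 < bin_width <= 0.5`.
#' @param range Two-element range on the major-allele scale (default
#'   `c(0.5, 1)`).
#' @param min_loci Minimum loci per bin for a defined variance estimate
#'   (default 100); bins below carry `NA`.
#' @return An object of class `binning_scheme`.
#' @export
binning_scheme <- function(bin_width = 0.025, range = c(0.5, 1),
                           min_loci = 100) {
  stopifnot(bin_width > 0, bin_width <= 0.5, length(range) == 2,
            range[2] > range[1], min_loci >= 2)
  n_bins <- ceiling((range[2] - range[1]) / bin_width - 1e-9)
  # snap edges to a fine grid so values like 0.975 land on their bin boundary
  structure(list(bin_width = bin_width, range = range, min_loci = min_loci,
                 breaks = round(range[1] + bin_width * seq(0, n_bins), 12)),
            class = "binning_scheme")
}

#' Assign loci to frequency bins
#'
#' A locus with initial major-allele frequency `p0` in `[lo, lo + width)` is
#' assigned to that bin; `p0 = 1` (fixed at the reference timepoint) and `p0`
#' outside the scheme range are unassigned (`NA`).
#'
#' @param p0 Initial major-allele frequencies (values below 0.5 are an
#'   internal consistency error when the scheme range starts at 0.5).
#' @param scheme A [binning_scheme()].
#' @return Integer bin index per locus (`NA` for unassigned).
#' @export
bin_by_frequency <- function(p0, scheme = binning_scheme()) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (any(!is.na(p0) & p0 < scheme$range[1] - 1e-12)) {
    stop("internal consistency error: frequency below the scheme range ",
         "(polarize to the major allele first?)")
  }
  br <- scheme$breaks
  idx <- findInterval(p0, br, rightmost.closed = FALSE, left.open = FALSE)
  idx[!is.na(p0) & (p0 >= br[length(br)] | p0 >= 1)] <- NA_integer_
  idx[!is.na(idx) & idx == 0] <- NA_integer_
  idx
}

#' Frequency-binned variance coefficients C_t(p)
#'
#' For each major-allele frequency bin (defined by the frequency at `t0`),
#' computes `C = Var(dp) / pbar (1 - pbar)` where `dp = p(t1) - p(t0)` across
#' loci in the bin, `Var` is the sample variance (denominator `n - 1`) and
#' `pbar` is the bin mean of `p(t0)`. Loci with a missing frequency at either
#' timepoint are excluded; bins with fewer than `min_loci` loci are reported
#' with `C = NA`. Under neutral exchangeable drift `C` is frequency
#' independent.
#'
#' @param table A polarized `freq_table` (see [polarize_major()]).
#' @param t0,t1 Timepoint labels bracketing the interval.
#' @param t_gens Generations elapsed between `t0` and `t1` (stored, not used in
#'   the computation).
#' @param scheme A [binning_scheme()].
#' @return A `variance_profile` data frame with columns `bin_lo`, `bin_hi`,
#'   `p_bar`, `C`, `n` and attributes `t_gens`, `min_loci`.
#' @export
variance_coefficient <- function(table, t0 = t_labels(table)[1],
                                 t1 = t_labels(table)[2], t_gens,
                                 scheme = binning_scheme()) {
  stopifnot(inherits(table, "freq_table"), t_gens > 0)
  lb <- t_labels(table)
  if (!all(c(t0, t1) %in% lb)) stop("timepoints not present in table")
  p0 <- table[[paste0("freq_", t0)]]
  p1 <- table[[paste0("freq_", t1)]]
  ok <- !is.na(p0) & !is.na(p1)
  idx <- rep(NA_integer_, length(p0))
  idx[ok] <- bin_by_frequency(p0[ok], scheme)
  br <- scheme$breaks
  nb <- length(br) - 1
  out <- data.frame(bin_lo = br[-length(br)], bin_hi = br[-1],
                    p_bar = NA_real_, C = NA_real_, n = 0L)
  dp <- p1 - p0
  use <- !is.na(idx)
  if (any(use)) {
    n <- tabulate(idx[use], nbins = nb)
    sums_p <- vapply(seq_len(nb), function(b) sum(p0[use][idx[use] == b]),
                     numeric(1))
    out$n <- n
    defined <- n >= 2
    out$p_bar[defined] <- sums_p[defined] / n[defined]
    v <- tapply(dp[use], factor(idx[use], levels = seq_len(nb)), stats::var)
    est <- defined & n >= scheme$min_loci
    out$C[est] <- as.numeric(v)[est] /
      (out$p_bar[est] * (1 - out$p_bar[est]))
  }
  if (!any(!is.na(out$C))) {
    stop(sprintf("empty profile: no bin has >= %d loci", scheme$min_loci))
  }
  structure(out, t_gens = t_gens, min_loci = scheme$min_loci,
            class = c("variance_profile", "data.frame"))
}

#' Subtract the minimum variance coefficient
#'
#' Shifts all defined `C` values by the minimum over defined bins so the
#' profile minimum is zero. Used when overlaying replicates so that
#' between-replicate differences in overall magnitude do not obscure the
#' frequency dependence within each replicate. Idempotent; the excess variance
#' is invariant to it.
#'
#' @param profile A `variance_profile`.
#' @return The shifted `variance_profile`.
#' @export
normalize_min <- function(profile) {
  stopifnot(inherits(profile, "variance_profile"))
  if (all(is.na(profile$C))) stop("no defined bins to normalize")
  profile$C <- profile$C - min(profile$C, na.rm = TRUE)
  profile
}

find_bin <- function(profile, bin, what = "bin") {
  hit <- which(abs(profile$bin_lo - bin[1]) < 1e-9 &
                 abs(profile$bin_hi - bin[2]) < 1e-9)
  if (length(hit) != 1) {
    stop(sprintf("%s [%g, %g) does not match a profile bin (check bin_width)",
                 what, bin[1], bin[2]))
  }
  hit
}

#' Excess variance between two frequency bins
#'
#' The headline selection statistic: `C_t(p) - C_t(p*)`, the elevation of the
#' variance coefficient of an intermediate-frequency cohort over a
#' high-frequency reference cohort. Frequency-independent contributions
#' (genetic drift, binomial measurement noise) cancel in the difference.
#'
#' @param profile A `variance_profile`.
#' @param p_bin Two-element edges of the cohort bin (default `[0.5, 0.55)`).
#' @param p_star_bin Edges of the reference bin (default `[0.9, 0.95)`).
#' @return An `excess_variance` list: `excess`, `p_bin`, `p_star_bin`,
#'   `p_bar` (cohort bin mean frequency), `t_gens`, `n`, `n_star`.
#' @export
excess_variance <- function(profile, p_bin = c(0.5, 0.55),
                            p_star_bin = c(0.9, 0.95)) {
  stopifnot(inherits(profile, "variance_profile"))
  i <- find_bin(profile, p_bin, "p_bin")
  j <- find_bin(profile, p_star_bin, "p_star_bin")
  if (is.na(profile$C[i])) stop(sprintf("bin [%g, %g) is undefined (n = %d)",
                                        p_bin[1], p_bin[2], profile$n[i]))
  if (is.na(profile$C[j])) stop(sprintf("bin [%g, %g) is undefined (n = %d)",
                                        p_star_bin[1], p_star_bin[2],
                                        profile$n[j]))
  structure(list(excess = profile$C[i] - profile$C[j],
                 p_bin = p_bin, p_star_bin = p_star_bin,
                 p_bar = profile$p_bar[i], t_gens = attr(profile, "t_gens"),
                 n = profile$n[i], n_star = profile$n[j]),
            class = "excess_variance")
}

#' @export
print.excess_variance <- function(x, ...) {
  cat(sprintf(
    "excess variance C_t(p) - C_t(p*) = %.4g  (t = %g gens; p in [%g,%g), n = %d; p* in [%g,%g), n = %d)\n",
    x$excess, x$t_gens, x$p_bin[1], x$p_bin[2], x$n,
    x$p_star_bin[1], x$p_star_bin[2], x$n_star))
  invisible(x)
}

#' Temporal trajectory of excess variance
#'
#' For a table with `>= 3` timepoints, fixes cohort membership (both the `p`
#' and `p*` bins) by the major-allele frequency at `t0`, then for each later
#' timepoint computes the excess variance of `dp = p(tk) - p(t0)` within the
#' fixed cohorts. Under temporally consistent selection the excess grows
#' quadratically with generations; under temporally uncorrelated selection it
#' grows linearly.
#'
#' @param table A `freq_table` with at least 3 timepoints. Polarization to the
#'   major allele at `t0` is applied internally.
#' @param t0 Cohort-defining timepoint label (default first).
#' @param p_bin,p_star_bin Cohort and reference bin edges.
#' @param t_gens Numeric vector of generations from `t0` to each later
#'   timepoint (length `= number of timepoints after t0`).
#' @param min_loci Minimum cohort size.
#' @return A data frame with one row per later timepoint: `t_label`, `t_gens`,
#'   `excess`, `C_p`, `C_pstar`, `n`, `n_star`.
#' @export
excess_trajectory <- function(table, t0 = t_labels(table)[1],
                              p_bin = c(0.5, 0.55), p_star_bin = c(0.9, 0.95),
                              t_gens, min_loci = 100) {
  stopifnot(inherits(table, "freq_table"))
  lb <- t_labels(table)
  if (length(lb) < 3) {
    stop("need >= 3 timepoints for a trajectory; use excess_variance() for 2")
  }
  later <- lb[seq(which(lb == t0) + 1, length(lb))]
  if (length(t_gens) != length(later)) {
    stop(sprintf("t_gens must have length %d (timepoints after t0)",
                 length(later)))
  }
  tab <- polarize_major(table, ref_timepoint = t0)
  p0 <- tab[[paste0("freq_", t0)]]
  ok <- complete_loci(tab)
  in_p <- ok & !is.na(p0) & p0 >= p_bin[1] & p0 < p_bin[2]
  in_ps <- ok & !is.na(p0) & p0 >= p_star_bin[1] & p0 < p_star_bin[2]
  if (sum(in_p) < min_loci || sum(in_ps) < min_loci) {
    stop("cohort below min_loci at t0")
  }
  pb <- mean(p0[in_p])
  pbs <- mean(p0[in_ps])
  res <- lapply(seq_along(later), function(k) {
    pk <- tab[[paste0("freq_", later[k])]]
    C_p <- stats::var(pk[in_p] - p0[in_p]) / (pb * (1 - pb))
    C_ps <- stats::var(pk[in_ps] - p0[in_ps]) / (pbs * (1 - pbs))
    data.frame(t_label = later[k], t_gens = t_gens[k],
               excess = C_p - C_ps, C_p = C_p, C_pstar = C_ps,
               n = sum(in_p), n_star = sum(in_ps))
  })
  out <- do.call(rbind, res)
  attr(out, "p_bar") <- pb
  out
}

#' Lower bound on the selection-coefficient variance
#'
#' Converts an excess variance into a lower bound on the among-locus variance
#' of the time-averaged total selection coefficient:
#' `sigma^2(sbar | p) > (C_t(p) - C_t(p*)) / (t^2 pbar (1 - pbar))`,
#' on a per-generation^2 scale. Drift and binomial measurement noise cancel in
#' the excess; because the reference bin may itself carry selective
#' divergence, only a lower bound is obtained. Sampling noise can make the
#' bound negative; negative values are reported as-is with a flag.
#'
#' @param excess An `excess_variance` object, or a bare number.
#' @param t_gens Generations between timepoints (default taken from `excess`).
#' @param p_bar Mean initial major-allele frequency of the cohort bin
#'   (default taken from `excess`), strictly inside `(0, 1)`.
#' @return A `selection_variance_bound` list: `sigma2_bound`, `t_gens`,
#'   `p_bar`, `negative` flag.
#' @examples
#' sigma2_lower_bound(2.5e-3, t_gens = 10, p_bar = 0.5) # 1e-4, sigma(s) ~ 1%
#' @export
sigma2_lower_bound <- function(excess, t_gens = NULL, p_bar = NULL) {
  if (inherits(excess, "excess_variance")) {
    if (is.null(t_gens)) t_gens <- excess$t_gens
    if (is.null(p_bar)) p_bar <- excess$p_bar
    excess <- excess$excess
  }
  stopifnot(is.numeric(excess), t_gens > 0)
  if (is.null(p_bar) || p_bar <= 0 || p_bar >= 1) {
    stop("domain error: p_bar must lie strictly inside (0, 1)")
  }
  b <- excess / (t_gens^2 * p_bar * (1 - p_bar))
  structure(list(sigma2_bound = b, t_gens = t_gens, p_bar = p_bar,
                 negative = b < 0),
            class = "selection_variance_bound")
}

#' @export
print.selection_variance_bound <- function(x, ...) {
  cat(sprintf("sigma^2(sbar|p) lower bound: %.4g per gen^2 (t = %g, pbar = %.3f)%s\n",
              x$sigma2_bound, x$t_gens, x$p_bar,
              if (x$negative) "  [negative: sampling noise]" else ""))
  cat(sprintf("  implied sigma(sbar|p) >= %.3g per generation\n",
              sqrt(max(x$sigma2_bound, 0))))
  invisible(x)
}
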