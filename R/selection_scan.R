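#' Excess-variance selection scan
#'
#' The headline analysis: polarizes a two-timepoint allele-frequency table to
#' the major allele at `t0`, computes frequency-binned variance coefficients
#' `C_t(p)`, the excess variance `C_t(p) - C_t(p*)` between an intermediate
#' cohort and a high-frequency reference cohort, and the implied lower bound
#' on the among-locus variance of total selection coefficients
#' `sigma^2(sbar | p)`, with block-bootstrap confidence intervals over genomic
#' windows for the profile, the excess and the bound.
#'
#' @param table A `freq_table`.
#' @param t0,t1 Timepoint labels (defaults: first and second).
#' @param t_gens Generations between `t0` and `t1`.
#' @param p_bin Cohort bin edges (default `[0.5, 0.55)`).
#' @param p_star_bin Reference bin edges (default `[0.9, 0.95)`).
#' @param scheme A [binning_scheme()]; its width must match the bins.
#' @param B Bootstrap replicates (default 1000; 0 disables the bootstrap).
#' @param block_size Bootstrap window size in bp (default 1 Mb).
#' @param alpha Two-sided miscoverage for intervals (default 0.05).
#' @param seed Root bootstrap seed.
#' @return An object of class `selscan` with components `profile`
#'   (the `variance_profile` on the full data), `excess`, `bound`,
#'   `boot` (`bootstrap_result` over `(excess, sigma2_bound)`),
#'   `profile_ci` (per-bin bootstrap bounds, or `NULL`), `n_loci`,
#'   `n_blocks`, `call`.
#' @seealso [excess_variance()], [sigma2_lower_bound()], [block_bootstrap()]
#' @export
selection_scan <- function(table, t0 = t_labels(table)[1],
                           t1 = t_labels(table)[2], t_gens,
                           p_bin = c(0.5, 0.55), p_star_bin = c(0.9, 0.95),
                           scheme = binning_scheme(bin_width = p_bin[2] - p_bin[1]),
                           B = 1000, block_size = 1e6, alpha = 0.05,
                           seed = NULL) {
  stopifnot(inherits(table, "freq_table"), t_gens > 0)
  keep <- !is.na(table[[paste0("freq_", t0)]]) &
    !is.na(table[[paste0("freq_", t1)]])
  n_excluded <- sum(!keep)
  tab <- if (n_excluded > 0) subset_loci(table, which(keep)) else table
  pol <- polarize_major(tab, ref_timepoint = t0)
  profile <- variance_coefficient(pol, t0, t1, t_gens, scheme)
  exc <- excess_variance(profile, p_bin, p_star_bin)
  bound <- sigma2_lower_bound(exc)
  blocks <- make_blocks(tab, block_size)
  stat <- function(x) {
    pr <- variance_coefficient(polarize_major(x, ref_timepoint = t0),
                               t0, t1, t_gens, scheme)
    e <- excess_variance(pr, p_bin, p_star_bin)
    c(excess = e$excess,
      sigma2_bound = sigma2_lower_bound(e)$sigma2_bound,
      stats::setNames(pr$C, sprintf("C[%g,%g)", pr$bin_lo, pr$bin_hi)))
  }
  boot <- block_bootstrap(stat, tab, blocks, B = B, alpha = alpha, seed = seed)
  profile_ci <- NULL
  if (B > 0) {
    profile_ci <- data.frame(bin_lo = profile$bin_lo, bin_hi = profile$bin_hi,
                             ci_lo = boot$ci_lo[-(1:2)],
                             ci_hi = boot$ci_hi[-(1:2)])
  }
  structure(list(profile = profile, excess = exc, bound = bound,
                 boot = boot, profile_ci = profile_ci,
                 n_loci = n_loci(tab), n_excluded = n_excluded,
                 n_blocks = nrow(blocks), t0 = t0, t1 = t1, t_gens = t_gens,
                 alpha = alpha, seed = seed, call = match.call()),
            class = "selscan")
}

#' @export
print.selscan <- function(x, ...) {
  cat("Excess allele-frequency variance scan\n")
  cat(sprintf("  %d loci (%d excluded for missingness), %d blocks, t = %g generations\n",
              x$n_loci, x$n_excluded, x$n_blocks, x$t_gens))
  e <- x$excess
  if (x$boot$B > 0) {
    cat(sprintf("  excess C_t(p) - C_t(p*): %.4g  [%.4g, %.4g]\n",
                e$excess, x$boot$ci_lo[1], x$boot$ci_hi[1]))
    cat(sprintf("  sigma^2(sbar|p) > %.4g  [%.4g, %.4g] per gen^2\n",
                x$bound$sigma2_bound, x$boot$ci_lo[2], x$boot$ci_hi[2]))
  } else {
    cat(sprintf("  excess C_t(p) - C_t(p*): %.4g\n", e$excess))
    cat(sprintf("  sigma^2(sbar|p) > %.4g per gen^2\n", x$bound$sigma2_bound))
  }
  invisible(x)
}

#' @export
summary.selscan <- function(object, ...) {
  x <- object
  print(x)
  cat(sprintf("  cohort p in [%g, %g): n = %d, pbar = %.3f\n",
              x$excess$p_bin[1], x$excess$p_bin[2], x$excess$n,
              x$excess$p_bar))
  cat(sprintf("  reference p* in [%g, %g): n = %d\n",
              x$excess$p_star_bin[1], x$excess$p_star_bin[2],
              x$excess$n_star))
  if (x$bound$sigma2_bound > 0) {
    cat(sprintf("  implied sigma(sbar|p) >= %.3g per generation\n",
                sqrt(x$bound$sigma2_bound)))
  }
  cat("\nVariance-coefficient profile:\n")
  print.data.frame(as.data.frame(x$profile), digits = 4)
  invisible(x)
}

#' @export
coef.selscan <- function(object, ...) {
  c(excess = object$excess$excess,
    sigma2_bound = object$bound$sigma2_bound)
}

#' @export
confint.selscan <- function(object, parm, level = 0.95, ...) {
  if (object$boot$B == 0) stop("scan was run without bootstrap replicates")
  if (abs(1 - object$alpha - level) > 1e-9) {
    stop(sprintf("intervals were computed at level %g; re-run selection_scan with alpha = %g",
                 1 - object$alpha, 1 - level))
  }
  ci <- cbind(object$boot$ci_lo[1:2], object$boot$ci_hi[1:2])
  dimnames(ci) <- list(c("excess", "sigma2_bound"),
                       sprintf("%g %%", c(object$alpha / 2,
                                          1 - object$alpha / 2) * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Plot a variance-coefficient profile
#'
#' Plots `C_t(p)` against the bin mean major-allele frequency, after
#' min-subtraction if requested, with bootstrap intervals when available.
#'
#' @param x A `selscan` object.
#' @param normalize Subtract the profile minimum before plotting (default
#'   `TRUE`, as when overlaying replicates).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.selscan <- function(x, normalize = TRUE, ...) {
  pr <- x$profile
  shift <- if (normalize) min(pr$C, na.rm = TRUE) else 0
  ok <- !is.na(pr$C)
  graphics::plot(pr$p_bar[ok], pr$C[ok] - shift,
                 xlab = "major allele frequency p",
                 ylab = if (normalize) "C_t(p) - min C_t" else "C_t(p)",
                 pch = 19, ...)
  if (!is.null(x$profile_ci)) {
    graphics::segments(pr$p_bar[ok], x$profile_ci$ci_lo[ok] - shift,
                       pr$p_bar[ok], x$profile_ci$ci_hi[ok] - shift)
  }
  invisible(x)
}
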