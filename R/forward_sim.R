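#' Forward-simulation parameters
#'
#' Parameter bundle for the forward Wright-Fisher simulator. Mutation influx
#' is steady: neutral mutations arise as a Poisson process over the genome at
#' rate `mu_neutral` per bp per haploid genome per generation; non-neutral
#' mutations arise at rate `U` per diploid individual per generation, at a
#' uniform position, all with selection coefficient `s_sel` (sign gives the
#' regime) and dominance `h`.
#'
#' @param N Diploid population size (`>= 2`; even when `n_demes = 2`).
#' @param genome_length Genome length in bp.
#' @param r Recombination rate per bp per generation (crossovers are Poisson
#'   with mean `genome_length * r` per meiosis).
#' @param mu_neutral Neutral mutation rate per bp per generation.
#' @param U Non-neutral genomic mutation rate per diploid per generation.
#' @param s_sel Selection coefficient of non-neutral mutations, `|s_sel| < 1`.
#' @param h Dominance coefficient (default 0.5, genic selection); fitness is
#'   `1 + h s` for heterozygotes, `1 + s` for homozygotes, multiplicative
#'   across loci.
#' @param burn_in Burn-in generations before the first snapshot (default
#'   `10 N`).
#' @param t_interval Generations between the two recorded timepoints
#'   (default 10).
#' @param n_demes 1 (panmictic) or 2 (symmetric two-deme structure).
#' @param m Migration fraction per generation between demes (`n_demes = 2`).
#' @param seed Integer seed for the simulator's own RNG stream; if `NULL`, one
#'   is drawn from R's RNG.
#' @return A `sim_params` list.
#' @export
sim_params <- function(N = 1000, genome_length = 1e8, r = 1e-8,
                       mu_neutral = 1e-8, U = 0, s_sel = 0, h = 0.5,
                       burn_in = 10 * N, t_interval = 10, n_demes = 1,
                       m = 0, seed = NULL) {
  stopifnot(N >= 2, genome_length > 0, r >= 0, mu_neutral >= 0, U >= 0,
            abs(s_sel) < 1, h >= 0, h <= 1, burn_in >= 0, t_interval >= 1,
            n_demes %in% c(1, 2), m >= 0, m <= 1)
  if (n_demes == 2 && N %% 2 != 0) stop("structured runs need even N")
  structure(list(N = N, genome_length = genome_length, r = r,
                 mu_neutral = mu_neutral, U = U, s_sel = s_sel, h = h,
                 burn_in = burn_in, t_interval = t_interval,
                 n_demes = n_demes, m = m, seed = seed),
            class = "sim_params")
}

#' Desk-scale regime presets
#'
#' Reduced-scale presets of the archetypal selection regimes: a steady influx
#' of deleterious mutations (`"negative"`: U = 1, s = -0.05), no non-neutral
#' mutations (`"neutral"`: U = 0), a steady influx of beneficial mutations
#' (`"positive"`: U = 0.1, s = +0.02), and a two-deme `"structured"` neutral
#' population. The genome is shrunk while per-genome totals are preserved:
#' one expected neutral mutation and a 1-Morgan map per haploid genome per
#' generation, so regime ratios match the full-scale setting.
#'
#' @param regime One of `"neutral"`, `"negative"`, `"positive"`,
#'   `"structured"`.
#' @param N Diploid population size (default 200).
#' @param genome_length Genome length in bp (default 2 Mb).
#' @param mu_genome Expected neutral mutations per haploid genome per
#'   generation (default 1, the full-scale total).
#' @param map_length Genome map length in Morgans (default 1).
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` list.
#' @export
desk_params <- function(regime = c("neutral", "negative", "positive",
                                   "structured"),
                        N = 200, genome_length = 2e6, mu_genome = 1,
                        map_length = 1, ...) {
  regime <- match.arg(regime)
  base <- list(N = N, genome_length = genome_length,
               mu_neutral = mu_genome / genome_length,
               r = map_length / genome_length, burn_in = 10 * N)
  reg <- switch(regime,
    neutral = list(U = 0, s_sel = 0),
    negative = list(U = 1, s_sel = -0.05),
    positive = list(U = 0.1, s_sel = 0.02),
    structured = list(U = 0, s_sel = 0, n_demes = 2, m = 0.01))
  args <- utils::modifyList(c(base, reg), list(...))
  do.call(sim_params, args)
}

# continuous positions -> strictly increasing integer bp (1-based)
.integer_positions <- function(pos) {
  p <- floor(sort(pos)) + 1
  while (any(d <- diff(p) <= 0)) p[which(d) + 1] <- p[which(d)] + 1
  p
}

#' Run a forward Wright-Fisher simulation
#'
#' Burns in, snapshots all segregating mutations at generation `G = burn_in`
#' (frequencies and total selection coefficients), advances `t_interval`
#' further generations, and records the same loci again. The generational
#' cycle is: fitness evaluation, fitness-proportional parent sampling,
#' Poisson-crossover recombination of each parent's two haplotypes, then
#' mutation influx. Deterministic given `seed`.
#'
#' @param params A [sim_params()] or [desk_params()] bundle.
#' @param chrom Chromosome label for the output table (default `"sim1"`).
#' @param return_state Also return the 0/1 haplotype-by-locus genotype matrix
#'   at the snapshot (small simulations only).
#' @return A list with `table` (a two-timepoint `freq_table`, labels `"t0"`,
#'   `"t1"`), `selection` (a `TotalSelectionTable` data frame: `chrom`, `pos`,
#'   `p`, `s_total`, `s_direct`, `neutral`, `origin`), `mean_fitness`,
#'   `params`, and optionally `genotypes` plus `s_values`.
#' @export
run_regime <- function(params, chrom = "sim1", return_state = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  seed <- params$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  res <- wf_sim_cpp(params$N, params$genome_length, params$r,
                    params$mu_neutral, params$U, params$s_sel, params$h,
                    params$burn_in, params$t_interval, params$n_demes,
                    params$m, seed, return_state)
  ord <- order(res$pos)
  pos <- .integer_positions(res$pos)
  tab <- freq_table(rep(chrom, length(pos)), pos,
                    cbind(t0 = res$freq0[ord], t1 = res$freq1[ord]),
                    sort = FALSE)
  sel <- data.frame(chrom = chrom, pos = pos, p = res$freq0[ord],
                    s_total = res$s_total[ord], s_direct = res$s[ord],
                    neutral = res$s[ord] == 0, origin = res$origin[ord])
  out <- list(table = tab, selection = sel, mean_fitness = res$mean_fitness,
              n_fixed = res$n_fixed, params = params, seed = seed)
  if (return_state) {
    out$genotypes <- res$genotypes[, ord, drop = FALSE]
    out$s_values <- res$s[ord]
  }
  out
}

#' Run a two-deme structured simulation
#'
#' Two equal demes evolving with symmetric migration fraction `m`; output
#' frequencies are deme-size-weighted means. `m = 0.5` is effectively
#' panmictic; small `m` lets the demes differentiate during burn-in, which
#' creates a variance deficit at intermediate frequencies relative to high
#' frequencies.
#'
#' @param params A [sim_params()] with `n_demes = 2`.
#' @param ... Passed to [run_regime()].
#' @return As [run_regime()].
#' @export
run_structured <- function(params, ...) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_demes != 2) stop("run_structured needs n_demes = 2")
  run_regime(params, ...)
}

#' Total selection coefficients from a genotype matrix
#'
#' Reference implementation of the total selection coefficient
#' `s = (wF - wNF) / wbar` for every segregating locus of an explicit
#' population: `wF` is the allele-dosage-weighted mean fitness of carriers of
#' the focal allele (an individual with two copies counts twice), `wNF` the
#' same for the alternative allele, and `wbar` the population mean fitness.
#' Captures direct selection and all linked selection through fitness
#' associations. Fixed or lost loci get `NA`.
#'
#' @param genotypes 0/1 matrix, haplotypes x loci. For `ploidy = "diploid"`,
#'   consecutive row pairs form individuals.
#' @param s Direct selection coefficient per locus (0 for neutral loci).
#' @param h Dominance (diploid only; default 0.5).
#' @param ploidy `"diploid"` (fitness `1 + h s` het / `1 + s` hom,
#'   multiplicative across loci) or `"haploid"` (fitness `prod(1 + s)` over
#'   carried alleles; each haplotype is an individual).
#' @return Numeric vector of total selection coefficients per locus.
#' @export
total_selection_coefficients <- function(genotypes, s, h = 0.5,
                                         ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  genotypes <- as.matrix(genotypes)
  stopifnot(ncol(genotypes) == length(s),
            all(genotypes %in% c(0, 1)))
  if (ploidy == "diploid") {
    if (nrow(genotypes) %% 2 != 0) stop("diploid mode needs an even number of haplotype rows")
    ind <- rep(seq_len(nrow(genotypes) / 2), each = 2)
    dosage <- rowsum(genotypes, ind)             # individuals x loci, 0/1/2
    logw <- dosage
    logw[] <- 0
    sel <- which(s != 0)
    for (j in sel) {
      logw[, j] <- ifelse(dosage[, j] == 2, log1p(s[j]),
                          ifelse(dosage[, j] == 1, log1p(h * s[j]), 0))
    }
    w <- exp(rowSums(logw))
    n_cop <- colSums(dosage)
    sumw_focal <- colSums(dosage * w)
    tot_copies <- 2 * nrow(dosage)
    Wtot <- sum(w)
    wbar <- mean(w)
    wF <- sumw_focal / n_cop
    wNF <- (2 * Wtot - sumw_focal) / (tot_copies - n_cop)
  } else {
    sel <- which(s != 0)
    w <- exp(genotypes[, sel, drop = FALSE] %*% log1p(s[sel]))[, 1]
    n_cop <- colSums(genotypes)
    tot_copies <- nrow(genotypes)
    sumw_focal <- colSums(genotypes * w)
    Wtot <- sum(w)
    wbar <- mean(w)
    wF <- sumw_focal / n_cop
    wNF <- (Wtot - sumw_focal) / (tot_copies - n_cop)
  }
  out <- (wF - wNF) / wbar
  out[n_cop == 0 | n_cop == tot_copies] <- NA_real_
  out
}

#' Frequency-binned selection-coefficient variance from simulation truth
#'
#' Bins the segregating loci of a `TotalSelectionTable` by major-allele
#' frequency and computes the among-locus variance of the time-averaged total
#' selection coefficient per bin, `sigma^2(sbar | p)`, and its product with
#' `pbar (1 - pbar)` (the overall selective divergence per `t^2`). When only a
#' single-snapshot `s_total` is available, the constancy approximation
#' `sbar ~ s_total` is used and flagged.
#'
#' @param sel_table The `selection` data frame from [run_regime()] (or pooled
#'   rows from several replicates).
#' @param scheme A [binning_scheme()].
#' @param per_generation_s Optional loci x generations matrix of
#'   per-generation total selection coefficients; when supplied, `sbar` is its
#'   row mean instead of the snapshot value.
#' @return A data frame per bin: `bin_lo`, `bin_hi`, `p_bar`, `sigma2_sbar`,
#'   `weighted` (`pbar (1-pbar) sigma2`), `n`; attribute
#'   `constancy_approximation`.
#' @export
sigma2_by_frequency <- function(sel_table, scheme = binning_scheme(),
                                per_generation_s = NULL) {
  p <- sel_table$p
  sbar <- if (is.null(per_generation_s)) {
    sel_table$s_total
  } else {
    rowMeans(per_generation_s)
  }
  # polarize to the major allele: flipping the focal allele flips the sign of s
  flip <- p < 0.5
  p_maj <- ifelse(flip, 1 - p, p)
  s_maj <- ifelse(flip, -sbar, sbar)
  idx <- bin_by_frequency(p_maj, scheme)
  br <- scheme$breaks
  nb <- length(br) - 1
  out <- data.frame(bin_lo = br[-length(br)], bin_hi = br[-1],
                    p_bar = NA_real_, sigma2_sbar = NA_real_,
                    weighted = NA_real_, n = 0L)
  use <- !is.na(idx)
  if (any(use)) {
    f <- factor(idx[use], levels = seq_len(nb))
    out$n <- as.integer(table(f))
    pb <- tapply(p_maj[use], f, mean)
    v <- tapply(s_maj[use], f, stats::var)
    est <- out$n >= scheme$min_loci
    out$p_bar[est] <- as.numeric(pb)[est]
    out$sigma2_sbar[est] <- as.numeric(v)[est]
    out$weighted[est] <- out$p_bar[est] * (1 - out$p_bar[est]) *
      out$sigma2_sbar[est]
  }
  attr(out, "constancy_approximation") <- is.null(per_generation_s)
  out
}

#' Pooled-sequencing measurement noise
#'
#' Applies the two-stage sampling that generates pool-seq measurement error:
#' at each locus and timepoint, `2 n` chromosomes are drawn binomially from
#' the population frequency, then `depth` reads are drawn binomially from the
#' sampled pool frequency. The resulting error variance is
#' `p(1-p) (1/2n + 1/depth - 1/(2n depth))` - binomial in form, hence a
#' frequency-independent contribution to the variance coefficient.
#'
#' @param table A `freq_table` of true population frequencies.
#' @param n_individuals Individuals pooled (`>= 1`).
#' @param depth Read depth per locus and timepoint (`>= 1`).
#' @param seed Optional seed.
#' @return A `freq_table` of read-based frequencies with depths set to
#'   `depth`.
#' @export
pool_seq_noise <- function(table, n_individuals, depth, seed = NULL) {
  stopifnot(inherits(table, "freq_table"), n_individuals >= 1, depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- freqs(table)
  out <- f
  for (k in seq_len(ncol(f))) {
    ok <- !is.na(f[, k])
    pool <- stats::rbinom(sum(ok), 2 * n_individuals, f[ok, k]) /
      (2 * n_individuals)
    out[ok, k] <- stats::rbinom(sum(ok), depth, pool) / depth
  }
  freq_table(table$chrom, table$pos, out,
             depth = matrix(depth, nrow(f), ncol(f)),
             t_labels = t_labels(table), sort = FALSE)
}

#' Fast linkage-free cohort sampler
#'
#' Orders-of-magnitude faster generator than [run_regime()] for estimator
#' validation: each locus evolves independently for `t_gens` generations as
#' `p <- p + s_g p(1-p) + drift`, where drift is a binomial increment with
#' per-generation variance coefficient `drift_C_per_gen` (realized through an
#' effective size `Ne = 1/(2 drift_C_per_gen)`) and `s_g` is the
#' per-generation total selection coefficient under one of three models:
#' `"none"` (`s = 0`), `"constant"` (one draw per locus from
#' `Normal(mean_s, sigma_s^2)`, held fixed - maximal temporal covariance,
#' quadratic divergence growth), or `"iid"` (redrawn independently every
#' generation - zero temporal covariance, linear growth). Optional pool-seq
#' noise is applied to every recorded timepoint. Frequencies escaping `[0, 1]`
#' after the selection step are clipped and counted.
#'
#' @param L Number of loci.
#' @param p0 Initial frequencies: a single value, a length-`L` vector, or a
#'   function `n -> n` frequencies.
#' @param s_model `"none"`, `"constant"` or `"iid"`.
#' @param sigma_s Among-locus (or per-generation) standard deviation of `s`.
#' @param mean_s Mean of `s` (default 0).
#' @param s_fixed Optional explicit per-locus `s` vector (constant model),
#'   overriding `sigma_s`/`mean_s`.
#' @param t_gens Total generations simulated.
#' @param drift_C_per_gen Per-generation drift variance coefficient (0
#'   disables drift). The realized value `1/(2 round(1/(2 drift_C)))` is
#'   stored in attribute `drift_C_realized`.
#' @param n_individuals,depth Optional pool-seq noise parameters (both must be
#'   supplied to enable noise).
#' @param record_at Generation offsets to record (default `c(0, t_gens)`);
#'   must start at 0 and end at `t_gens`.
#' @param locus_spacing Spacing in bp between consecutive loci on the
#'   synthetic chromosome (default 1000, so a 1 Mb block holds 1000 loci).
#' @param chrom Chromosome label (default `"sim1"`).
#' @param seed Optional seed.
#' @return A `freq_table` with one timepoint per entry of `record_at`
#'   (labels `t<g>`), attributes `s_values` (per-locus `s`, constant model),
#'   `n_clipped`, and `drift_C_realized`.
#' @export
fast_cohort_sampler <- function(L, p0, s_model = c("none", "constant", "iid"),
                                sigma_s = 0, mean_s = 0, s_fixed = NULL,
                                t_gens, drift_C_per_gen = 0,
                                n_individuals = NULL, depth = NULL,
                                record_at = c(0, t_gens),
                                locus_spacing = 1000, chrom = "sim1",
                                seed = NULL) {
  s_model <- match.arg(s_model)
  stopifnot(L >= 1, t_gens >= 1, sigma_s >= 0, drift_C_per_gen >= 0,
            drift_C_per_gen < 0.5)
  if (!is.null(seed)) set.seed(seed)
  record_at <- sort(unique(as.integer(record_at)))
  if (record_at[1] != 0 || record_at[length(record_at)] != t_gens) {
    stop("record_at must start at 0 and end at t_gens")
  }
  p <- if (is.function(p0)) p0(L) else rep_len(p0, L)
  stopifnot(all(p >= 0 & p <= 1))
  two_ne <- if (drift_C_per_gen > 0) 2 * round(1 / (2 * drift_C_per_gen)) else NA
  s_loc <- switch(s_model,
    none = rep(0, L),
    constant = if (!is.null(s_fixed)) rep_len(s_fixed, L) else
      stats::rnorm(L, mean_s, sigma_s),
    iid = NULL)
  rec <- matrix(NA_real_, L, length(record_at),
                dimnames = list(NULL, paste0("t", record_at)))
  rec[, 1] <- p
  n_clipped <- 0L
  ri <- 2L
  for (g in seq_len(t_gens)) {
    s_g <- if (s_model == "iid") stats::rnorm(L, mean_s, sigma_s) else s_loc
    if (s_model != "none") {
      p2 <- p + s_g * p * (1 - p)
      n_clipped <- n_clipped + sum(p2 < 0 | p2 > 1)
      p <- pmin(pmax(p2, 0), 1)
    }
    if (drift_C_per_gen > 0) {
      p <- stats::rbinom(L, two_ne, p) / two_ne
    }
    if (ri <= length(record_at) && g == record_at[ri]) {
      rec[, ri] <- p
      ri <- ri + 1L
    }
  }
  tab <- freq_table(rep(chrom, L), seq_len(L) * locus_spacing, rec,
                    sort = FALSE)
  if (!is.null(n_individuals) && !is.null(depth)) {
    tab <- pool_seq_noise(tab, n_individuals, depth)
  }
  attr(tab, "s_values") <- if (s_model == "constant") s_loc else NULL
  attr(tab, "n_clipped") <- n_clipped
  attr(tab, "drift_C_realized") <-
    if (drift_C_per_gen > 0) 1 / two_ne else 0
  tab
}
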