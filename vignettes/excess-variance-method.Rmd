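---
title: "Detecting genome-wide linked selection from temporal allele-frequency variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genome-wide linked selection from temporal allele-frequency variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excessvar)
```

## The model

Write $p$ for the frequency of an allele and $\Delta_t p$ for its change over
$t$ generations. For a cohort of neutrally evolving alleles with initial
frequency $p$, essentially every exchangeable model of genetic drift gives the
binomial variance form

$$\mathrm{Var}(\Delta_t p \mid p) = C_t\, p(1-p),$$

with a frequency-independent variance coefficient $C_t$. In the Wright-Fisher
model $C_t = 1 - (1 - 1/2N)^t$ for diploid population size $N$, and the same
form with an effective size $N_e$ covers a broad family of drift models.
Binomial pooled-sequencing measurement error adds a frequency-independent
constant $M$ of the same form.

Selection breaks this. Each allele carries a *total selection coefficient*
$s = (\bar w_F - \bar w_{NF})/\bar w$ — the fitness contrast between carriers
and non-carriers of the focal allele, combining direct selection and all
linked selection through fitness associations. A single generation changes the
expectation by $s\,p(1-p)$, so among-locus variation in $s$ adds a *selective
divergence* term $[p(1-p)]^2 \sigma^2(s\mid p)$ to the variance of frequency
change. Over $t$ generations the growth of this term depends on the temporal
covariance of the per-generation coefficients $s_i$:

* perfectly persistent selection gives $t^2$ growth (quadratic);
* temporally uncorrelated selection gives $t$ growth (a selective random
  walk);
* geometric decay of covariance at rate $\rho$ per generation of separation —
  the phenomenological analogue of linkage-disequilibrium decay under
  recombination — interpolates between the two
  (`selective_divergence()`).

Putting the pieces together, the variance coefficient becomes frequency
dependent:

$$C_t(p) = D_t + D_t\,c\,(1-2p)\,E\!\left[\textstyle\sum_i s_i \mid p\right]
  + p(1-p)\,\sigma^2\!\left(\textstyle\sum_i s_i \mid p\right),$$

a frequency-independent drift term $D_t$, a selective *drift perturbation*
(the drift variance evaluated at selectively displaced frequencies; $c$ is an
order-1, population-specific constant exposed as a parameter of
`drift_perturbation()`), and the selective divergence. Because of the extra
factor of $p(1-p)$, the divergence is most visible at intermediate
frequencies.

## The statistic and the estimator

The scan (`selection_scan()`) polarizes every SNP to its major allele at the
first timepoint, bins loci by that initial frequency (half-open bins, default
2.5% width, 100-locus minimum), and computes per bin

$$\hat C_t = \frac{\widehat{\mathrm{Var}}(\Delta_t p)}{\bar p(1-\bar p)},$$

with the sample variance ($n-1$ denominator) and $\bar p$ the bin mean initial
frequency. The *excess variance* between an intermediate cohort and a
high-frequency reference cohort,

$$C_t(p) - C_t(p^*), \qquad p \in [0.5, 0.55),\; p^* \in [0.9, 0.95),$$

cancels every frequency-independent contribution — drift and binomial
measurement error alike — leaving a selection signal. Because the reference
cohort may itself carry selective divergence, dividing by $t^2\bar p(1-\bar p)$
yields only a *lower bound* on the among-locus variance of the time-averaged
total selection coefficient,

$$\sigma^2(\bar s \mid p) >
  \frac{C_t(p) - C_t(p^*)}{t^2\, \bar p(1-\bar p)},$$

reported on a per-generation$^2$ scale by `sigma2_lower_bound()`. Sampling
noise can push the bound negative; negative values are reported as-is with a
flag rather than truncated, so that replicate averages stay unbiased.

Uncertainty comes from a block bootstrap (`block_bootstrap()`): chromosomes
are tiled with 1 Mb windows, windows are resampled with replacement, and the
entire scan (binning included) is recomputed per replicate, which is necessary
because $C_t(p)$ is a ratio statistic. Percentile intervals are reported
without bias correction; the default is 1000 replicates. A single root seed
drives all replicate resampling, so results are reproducible.

Detection power follows from the sampling error of a variance: with $L$
independent loci, $\mathrm{SE}(C_t) \approx \sqrt{2/L}\,C_t$
(`se_variance_coefficient()`). Setting the selective signal
$t^2 p(1-p)\sigma^2$ equal to $k$ standard errors gives the closed-form
minimum $L = 2\,(k C / (t^2 p(1-p) \sigma^2))^2$ (`detection_limit()`; the
default threshold is $k = 1$, the scale at which differences become
statistically resolvable). At $C \sim 10^{-2}$, $\sigma^2 \sim 10^{-4}$,
$p = 0.5$, $t = 1$ this is $3.2 \times 10^5$ — the "at least $\sim 10^5$
SNPs" regime of modern pooled resequencing.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bin_width` | 0.025 (profile), bin-pair width for scans | frequency | narrow enough that $p(1-p)$ is constant within a bin |
| `min_loci` | 100 | loci | variance estimates below this are dominated by sampling error, especially as $p \to 1$ |
| `p_bin`, `p_star_bin` | $[0.5,0.55)$, $[0.9,0.95)$ | frequency | maximal contrast while staying clear of the unreliable $p = 1$ boundary |
| `block_size` | $10^6$ | bp | larger than typical linkage scales in dense metazoan genomes |
| `B` | 1000 | replicates | percentile CIs stable to a few percent |
| `t_gens` | data-defined | generations | enters the bound as $1/t^2$ |
| `h` (simulator) | 0.5 | — | genic selection; heterozygote $1 + hs$, homozygote $1+s$, multiplicative across loci |

Ties at exactly $p_0 = 0.5$ keep their original orientation when polarizing;
any consistent rule works because the variance is symmetric under
$p \to 1-p$. The $p(1-p)$ denominator uses the bin mean rather than the bin
midpoint or per-locus values: with 2.5% bins the three differ negligibly, and
the bin mean is the quantity the lower-bound formula needs. Trajectory
analyses (`excess_trajectory()`) fix both cohort memberships at the first
timepoint and re-use them at every later timepoint, polarizing once at that
reference timepoint.

## What the simulators emulate

`run_regime()` is a forward Wright-Fisher simulator with recombination:
non-overlapping generations, fitness-proportional parent sampling,
Poisson-crossover meiosis, and a steady influx of neutral mutations (Poisson
over the genome) plus non-neutral mutations at genomic rate `U` per diploid
per generation, all sharing one selection coefficient `s_sel`. Mutations live
at continuous positions, so crossovers never coincide with loci. Fitness is
multiplicative across loci with dominance `h`. After a burn-in of $10N$
generations it snapshots every segregating locus (frequency and total
selection coefficient, computed from the realized fitnesses by the
dosage-weighted contrast above), advances $t$ further generations and records
the same loci again. The archetypal regimes are presets
(`desk_params()`): a steady influx of deleterious mutations
($U = 1$, $s = -0.05$), none ($U = 0$), beneficial mutations
($U = 0.1$, $s = +0.02$), and a two-deme neutral population with symmetric
migration.

Desk scale: the presets default to a 2 Mb genome carrying the full-scale
per-genome totals — one neutral mutation and a 1-Morgan map per haploid
genome per generation — so the regime ratios (selected influx per Morgan,
selected vs neutral rates) match the full-scale setting while only $N$ and
the physical genome shrink. The calibration experiments in the test suite use
$N = 200$ with 50 replicates (drift calibration is cheap and exact), and the
selection-regime contrasts use $N = 500$ with 16 positive and 10 negative
replicates — the largest sizes whose suites complete in minutes on one core.
What shrinking cannot preserve: a full-scale Drosophila-like genome
(~100 Mb, ~1 Morgan per 100 Mb arm set, $N \sim 10^3$) averages over many
simultaneously selected neighbourhoods per replicate, while a 1-Morgan desk
genome holds only a handful, so the *realized* selective
divergence varies far more between desk-scale replicates than between
full-scale ones. The mean positive-regime excess matches the
simulation-truth prediction, but its replicate-to-replicate sign is less
consistent than at full scale — passing desk-scale tests therefore
demonstrates correctness of the machinery and direction of the effects, not
full-scale effect sizes or replicate consistency.

`fast_cohort_sampler()` is the linkage-free complement: each locus evolves
independently as
$p \leftarrow p + s_g\,p(1-p) + \text{binomial drift}(C_1)$,
with $s_g$ fixed per locus (maximal temporal covariance, quadratic growth) or
redrawn i.i.d. per generation (zero covariance, linear growth). It generates
$10^5$-locus cohorts in seconds, realizes drift through an effective size
$N_e = 1/(2 C_1)$ (rounded; the realized coefficient is recorded), clips and
counts frequencies that selection pushes past the boundaries, and can overlay
pooled-sequencing noise. Pool-seq noise (`pool_seq_noise()`) is two-stage
binomial sampling — $2n$ chromosomes from the population, then `depth` reads
from the pool — with error variance
$p(1-p)\left(\tfrac{1}{2n} + \tfrac{1}{d} - \tfrac{1}{2nd}\right)$, binomial
in form and hence invisible to the excess statistic. What the sampler does
*not* emulate: linkage (by design), variable depth across loci, unequal
individual contributions to the pool, and reference bias.

## Numerical choices

* Sample variances use the $n-1$ denominator everywhere.
* Bins are half-open $[lo, lo + w)$; $p_0 = 1$ belongs to no bin (a locus
  fixed at the reference timepoint carries no variance information).
* Bin edges are snapped to a $10^{-12}$ grid so that decimal edges like
  0.975 land in the intended bin despite floating-point representation.
* A locus with a missing frequency (zero sequencing depth) at any scanned
  timepoint is excluded from that scan and counted.
* Bootstrap replicates on which the statistic is undefined (an emptied bin)
  are dropped and counted; more than 20% dropped raises a warning.
* Sample variances taken within a single simulated replicate are biased
  down by the average pairwise correlation of frequency changes between
  linked loci; calibration checks therefore bin the replicate-pooled table,
  where cross-replicate locus pairs are independent.
* The simulator purges fixed mutations every 10 generations — relative
  fitnesses, and hence dynamics, are unchanged — to keep haplotypes sparse.
* Simulator determinism: a dedicated 64-bit Mersenne-Twister stream seeded
  from the `seed` parameter, independent of R's RNG state.

## Design choices on genuinely open points

* **Tri-allelic sites.** The sync reader keeps only biallelic loci (exactly
  two alleles with nonzero counts pooled across the selected timepoints) and
  reports the dropped count. Pooling across timepoints keeps the allele
  identity stable over time, which per-timepoint majority calling would not.
* **Dominance and fitness combination.** The simulator defaults to $h = 0.5$
  and multiplicative fitness across loci, the standard default of forward
  simulators in this field.
* **Per-generation selection coefficients.** Total selection coefficients are
  computed from the snapshot generation only, and `sigma2_by_frequency()`
  flags the constancy approximation $\bar s \approx s_{\text{snapshot}}$;
  per-generation tracking is supported through its `per_generation_s`
  argument when the caller records it.
* **Bootstrap replicate count.** 1000 by default; percentile method without
  bias correction.
* **U per diploid.** The non-neutral influx `U` is defined per diploid
  individual per generation (each gamete draws $\mathrm{Poisson}(U/2)$).

## Known limitations

* The bound is a lower bound twice over: the reference cohort subtracts its
  own selective divergence, and the excess also discards any
  frequency-independent component of selection.
* Migration from a differentiated source mimics selective divergence
  (`migration_divergence()` quantifies the term); the scan cannot separate
  them — closed populations are the clean use case.
* Population structure produces a variance *deficit* at intermediate
  frequencies, biasing the scan conservative, not anticonservative.
* Binned variance estimates degrade as $p^* \to 1$: heteroskedastic
  sampling noise interacts with binning on the *measured* frequency and
  inflates the apparent $C_t$ near fixation (visible with the pool-seq
  noise model at depth $\sim 100$). Keep the reference bin at or below
  $[0.9, 0.95)$; the estimator-recovery experiments in the test suite use
  $[0.85, 0.90)$ with 1000 pooled individuals at depth 1000, conditions
  under which a noise-only scan shows no measurable excess.
* The desk-scale simulator validates machinery and directions, not
  full-scale effect sizes (see above).
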