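Package: excessvar
Title: Excess Allele-Frequency Variance Scans for Genome-Wide Linked Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the genome-wide influence of (linked) selection from
    temporally resolved allele-frequency data. Computes frequency-binned
    variance coefficients C_t(p) = Var(delta p | p) / p(1-p), the excess
    variance C_t(p) - C_t(p*) between an intermediate-frequency cohort and a
    high-frequency reference cohort, and a lower bound on the among-locus
    variance of total selection coefficients sigma^2(s|p), with block-bootstrap
    confidence intervals over genomic windows. Includes closed-form theory
    calculators (Wright-Fisher drift, selective divergence growth laws, drift
    perturbation, migration divergence, sampling error and detection limits),
    a forward Wright-Fisher simulator with recombination and a steady influx
    of neutral and selected mutations, pooled-sequencing noise models, and a
    fast linkage-free cohort sampler. Reads PoPoolation2-style sync files and
    tabular allele-frequency time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
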