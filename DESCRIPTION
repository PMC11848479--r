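Package: seamnet
Title: Gene Regulatory Network Inference for Seam-Cell smFISH Counts
Version: 0.1.0
Authors@R:
    person("seamnet", "developers", email = "seamnet@example.org",
           role = c("aut", "cre"))
Description: Infers a small gene regulatory network from single-cell
    transcript counts measured across wild-type and hypomorphic mutant
    backgrounds. Implements Modular Response Analysis adapted to
    partial-loss-of-function alleles (activity-corrected central
    fractional differences, bootstrap interaction matrices), a
    Hill-function ODE model family with combinatorial AND/OR
    co-regulation logic and genotype activity fractions, and a sparse
    likelihood-free Gibbs sampler with per-parameter shrinkage priors
    for model discovery, plus double-mutant validation and network
    assembly. Ships a mixed-Poisson synthetic data generator emulating
    smFISH count structure (shared animal-level extrinsic noise, paired
    seam cells) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
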