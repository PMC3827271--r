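Package: kabcoal
Title: Kernel-ABC Demographic Inference Under a Two-Population Divergence Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Likelihood-free Bayesian inference of demographic history for a
    pair of diverging populations, motivated by the brown bear / polar bear
    system. Provides a coalescent simulator with infinite-sites mutation and
    optional intra-locus recombination, site and haplotype frequency spectrum
    summary statistics with Sturges-rule binning, a kernel ridge-regression
    posterior-mean estimator (kernel-ABC) with cross-validated hyperparameter
    selection, TMRCA estimation, mutation-rate calibration from outgroup
    divergence, classical neutrality tests (Tajima's D, Fu and Li's D and F,
    Fay and Wu's H) with coalescent null distributions, four-gamete editing of
    non-recombining alignments, and a synthetic-data generator emulating
    multi-locus population alignments with outgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
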