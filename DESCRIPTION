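Package: navtrig
Title: Biophysical Modelling of Mutant NaV1.1 Channels in Trigeminal
    Nociceptive Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley style models of wild-type and mutant NaV1.1
    sodium channels (familial hemiplegic migraine type 3 and epilepsy
    variants), simulated voltage-clamp protocols with Boltzmann curve
    fitting, ligand-gated receptor (P2X3, P2X2, 5-HT3) generator currents
    at nerve terminals, compartmental cable simulation of branched
    myelinated A-delta and unmyelinated C fibers, whole-nerve ensembles,
    inter-spike-interval statistics with two-sample Kolmogorov-Smirnov
    testing, and in-silico "virtual treatment" by component-wise
    correction of mutant gating parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    rlang,
    generics,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    yaml,
    withr,
    minpack.lm
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
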