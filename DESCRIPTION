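Package: driftpulse
Title: Wright-Fisher Drift and Single-Pulse Admixture Models for
    Haplogroup Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-time haploid Wright-Fisher simulation of a biallelic
    Y-chromosome marker (haplogroup carrier versus non-carrier) with
    single-pulse admixture, and a resampling-based model-selection
    framework built on it.  Three demographic models -- pure drift from a
    shared ancestor, a shared admixture pulse, and population-specific
    admixture pulses from a source population -- are compared by the rate
    at which conditioned simulations reproduce observed sample
    frequencies, and the population-specific model is fitted by rejection
    sampling (approximate Bayesian computation) to give posterior
    summaries of the admixture proportions and the source-population
    carrier frequency.  Includes readers for population haplogroup count
    tables, a synthetic-data generator with known ground truth, and
    command-style pipeline entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
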