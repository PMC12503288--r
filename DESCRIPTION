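Package: migsim
Title: Stochastic Evolution Modelling of International Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates international migration as a stochastic demographic
    accounting process.  Bilateral emigration, return and birth flows are
    sampled from probability distributions calibrated on partitioned
    bilateral flow data (emigration rates by origin population size,
    destination shares by GDP-per-capita ratio and relative diaspora size,
    unpartitioned return rates), and native populations and migrant stock
    matrices are evolved year by year through balance equations.  Provides
    Monte-Carlo ensembles with median trajectories and 50%/95% prediction
    intervals, a deterministic median-substitution mode, a synthetic-world
    generator for closed-loop testing, and readers/writers for the tabular
    input formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
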