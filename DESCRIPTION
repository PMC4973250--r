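Package: repeatburst
Title: Branching-Process Models of Selfish DNA Expansion and k-mer
    Abundance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the expansion of a selfish DNA repeat family (such as
    the primate Alu SINEs) as a continuous-time branching process: a burst of
    duplications during which active elements copy themselves at rate gamma,
    each new copy being active with probability delta, followed by a silent
    phase in which elements only accumulate mutations, with hypermutable CpG
    dinucleotides. Provides the analytic theory for the resulting k-mer
    abundance spectra, whose tails are power laws with a k-dependent exponent
    alpha(k), and a full inference pipeline (discrete Hill estimator, single
    parameter exponent-curve fit, element-count and burst/silent-time
    estimators) to recover the model parameters from repeat sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
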