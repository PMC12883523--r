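Package: phycoMS
Title: Native Mass Spectrometry Analysis of Phycobiliprotein Complex Heterogeneity
Version: 0.1.0
Authors@R:
    person("phycoMS", "Developers", email = "phycoms@example.org", role = c("aut", "cre"))
Description: Tools for detecting and ruling out heterogeneous phycobiliprotein
    complexes by native electrospray mass spectrometry. Computes PTM-adjusted
    average masses of phycobiliprotein subunits from sequence, enumerates
    candidate complex stoichiometries under configurable assembly rules, picks
    peaks above a signal-to-noise threshold, groups them into charge-state
    series to estimate neutral masses, matches experimental masses to candidate
    compositions under a percent-error threshold with abundance classification,
    and issues presence/absence verdicts for queried heterogeneous
    stoichiometries. Includes a synthetic-spectrum generator with ground truth
    for end-to-end validation, and pairwise sequence-identity analysis of
    subunit isoforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
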