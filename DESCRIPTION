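Package: mcoex
Title: Coexistence, Interaction and Identification Analysis for Model
    Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for testing stable coexistence in serial-transfer
    bacterial communities. Enumerates invasion-from-rare and all-subset
    co-culture assay designs, simulates batch-culture community dynamics
    under a generalized Lotka-Volterra model with optional higher-order
    interaction terms and lognormal plate-count noise, computes
    invasion-from-rare fitness statistics (relative Malthusian growth
    rates, one-sample tests, false discovery rate correction), estimates
    pairwise and indirect (higher-order) species interactions from
    co-culture and spent-media assays, compares supernatant and
    co-culture interaction estimates by standardized major axis
    regression and sign agreement, tallies morphotype identification
    reliability, and quality-controls Sanger reads with Mott trimming
    and secondary-peak filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deSolve,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
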