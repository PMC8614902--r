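Package: markerdiv
Title: Genetic Diversity from Dominant Molecular Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of binary presence/absence matrices from dominant
    molecular markers (RAPD, ISSR, REMAP) in structured populations.
    Computes Nei-Li band-sharing diversity between individual profiles and
    between population consensus profiles, within- and between-population
    diversity summaries with ratios and differences, and UPGMA dendrograms
    with character-resampling bootstrap support. Includes a simulator for
    multi-population dominant-marker data with species-wide monomorphic
    bands, population-diagnostic bands, and a Balding-Nichols
    differentiation parameter, together with closed-form expectations for
    parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
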