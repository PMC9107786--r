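Package: phenohill
Title: Phenological Hill Numbers for Community Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the diversity of phenological patterns in an
    ecological community as phenological Hill numbers (qPD): discrete
    species-by-time activity records are smoothed into continuous curves
    by a Morlet continuous wavelet transform, pairwise temporal-niche
    distances are computed with a modified Morisita-Horn overlap index,
    and distance-based (attribute) Hill diversity of any order q is
    evaluated, yielding diversity profiles in units of effective
    phenological curves. Includes a simulator for benchmark community
    scenarios and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
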