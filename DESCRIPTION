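Package: micdiv
Title: Microbial Physiology, Necromass and Soil Carbon Along Plant
    Diversity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving soil microbial physiology from substrate-
    independent tracer incubations and relating it to plant diversity in
    randomized-block grassland experiments. Converts raw incubation
    measurements (headspace CO2, 18O enrichment of genomic DNA,
    chloroform-fumigation extracts, cell-wall amino sugars) into microbial
    respiration, gross growth, carbon uptake, carbon use efficiency,
    biomass-specific rates, turnover time, microbial biomass carbon and
    fungal/bacterial necromass carbon. Implements the plot-level inference
    chain used in such experiments: block correction, sequential
    likelihood-ratio tests in linear mixed models, block-corrected Pearson
    correlation matrices, and piecewise structural equation models with
    Shipley's test of directed separation (Fisher's C), standardized path
    coefficients, indirect effects and marginal/conditional R-squared. A
    synthetic-data generator emulates the experimental design and inverts
    the measurement equations down to instrument-level tables, so the whole
    pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
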