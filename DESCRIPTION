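Package: ventgrowth
Title: Growth Phenotyping of Microbes Across Salinity, pH and Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing microplate growth assays run over a
    salinity x pH x temperature factorial design. Fits the four-parameter
    Richards generalized logistic model to blank-subtracted optical density
    time series, derives a normalized average growth rate from the fitted
    parameters, runs the aligned rank transform (ART) two-way ANOVA with
    Kruskal-Wallis/Dunn post-hoc comparisons and compact letter displays on
    the replicate-level rates, and classifies organisms into
    environmental-response groups from their growth occurrence profiles.
    Includes a synthetic plate-reader simulator with known ground truth so
    every stage of the pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
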