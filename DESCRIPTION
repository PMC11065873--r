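Package: socialvec
Title: Reference-Frame Analysis of Social-Spatial Coding in Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of hippocampal social-spatial coding from calcium-imaging
    sessions of freely interacting mice. Builds occupancy-normalised event-rate
    maps of a cell's activity in four coordinate systems (self position, partner
    position, and partner-relative-to-self position in arena-fixed or
    head-rotating axes), classifies cells as place cells or social-vector cells
    against temporally shuffled null distributions, decodes position from
    population activity with a naive Bayes decoder under cross-validation,
    quantifies remapping across partners and contexts with split-half map
    correlations and normalised population-vector dot products, and analyses
    annular-track pursuit sessions through one-dimensional angle maps and
    population autocorrelograms. A synthetic-session generator with known
    ground-truth tuning supports end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
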