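Package: ecowarn
Title: Ecological Security Early-Warning Indices and GM(1,1) Grey Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite ecological-security early-warning indices from
    region-by-year indicator panels using entropy-derived weights, grades them
    on a five-level alarm scale, and forecasts their evolution with the GM(1,1)
    grey model. Includes min-max normalization for positive and negative
    indicators, entropy weighting with subsystem (type) weight decomposition,
    the accumulated generating operation (AGO) and its inverse, least-squares
    estimation of the grey development coefficient, two restoration formulas,
    and the double accuracy test (posterior-error ratio and small-error
    probability, residual and stage-ratio checks). A synthetic panel generator
    with known ground truth supports end-to-end validation, and a pipeline
    driver orchestrates the full analysis from raw panel to graded forecasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
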