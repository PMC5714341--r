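Package: crossvar
Title: Predicting the Mean and Segregation Variance of Biparental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form prediction of the mean and the segregation variance of
    the genotypic values of fully homozygous lines (doubled haploids or
    single-seed-descent inbreds, optionally after generations of random
    intermating) derived from a cross of two homozygous parents. Marker
    effects are estimated by ridge-regression BLUP from a training panel;
    per-cross means, variances, superior progeny values and usefulness
    criteria are computed from the expected linkage disequilibrium between
    marker pairs under the chosen mating system. Includes exact enumeration
    and Monte Carlo meiosis simulators that verify the formulas, a synthetic
    data generator, quality-control filters for marker panels, and a
    command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
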