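Package: tetraclass
Title: Trait Complexity Classification from Tetrad-Structured Segregant Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the genetic complexity (monogenic, oligogenic or
    complex) of quantitative traits from the phenotype distributions of
    tetrad-structured yeast segregant panels. Provides a meiotic
    segregation simulator producing 2:2-segregating genotypes under
    additive and epistatic architectures, a 24-feature representation of
    a phenotype distribution (quantiles, two-component Gaussian mixture
    parameters, Ashman's D, a Kolmogorov-Smirnov comparison against a
    matched normal, and tetrad segregation profiles), a random-forest
    regressor of primary-locus weight with ROC threshold calibration, a
    decision tree assigning complexity levels from mode proportions and
    parental placements, colony-size preprocessing (baseline filtering,
    growth ratios, duplicate averaging), and survey summaries including
    Shannon entropy of complexity spectra across half-diallel panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
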