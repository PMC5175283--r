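Package: msihet
Title: Quantitative Heterogeneity Analysis for MALDI Mass Spectrometry
    Imaging of Drugs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the spatial distribution of a drug in tissue
    sections imaged by MALDI mass spectrometry imaging (MSI). Implements
    per-pixel normalization of the drug ion signal against a uniformly
    sprayed deuterated internal standard to compensate spatially varying
    ion suppression, linear calibration of normalized signal against
    spotted drug amounts with reverse quantification in pmol/mm2,
    background thresholding from untreated control sections,
    percent-positive-pixel and connected-particle heterogeneity metrics,
    three-level intensity zonation with per-zone absolute quantification
    and fold ratios, reproducibility metrics (RSD%), and group comparison
    statistics. Includes readers and writers for imzML 1.1 (ibd binary)
    and a plain CSV grid format, plus a synthetic tissue-phantom generator
    with ground truth for validating every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
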