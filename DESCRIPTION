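Package: hsipath
Title: Patch-Based Tumor Classification for Hyperspectral H&E Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating glioblastoma from non-tumor tissue in
    hyperspectral microscopy of hematoxylin-and-eosin stained slides. Provides
    ENVI-style cube input/output, flat-field conversion from radiance to
    transmittance, spectral band reduction, RGB synthesis from spectra,
    87x87 patch extraction with blank-light rejection, patient-disjoint
    cross-validation folds with rotation-based class balancing, a patch-level
    convolutional classifier trained with stochastic gradient descent,
    confusion-matrix and ROC/AUC evaluation with per-patient aggregation, and
    sliding-window tumor-probability heat maps. Includes a synthetic slide
    generator (Beer-Lambert stain optics, seeded nuclear point process, paired
    blank references) so the whole pipeline can be exercised end to end
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
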