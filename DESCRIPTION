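Package: sicklevol
Title: Hematocrit-Corrected ASL Perfusion Quantification and Brain
    Volumetrics in Sickle Cell Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools linking sickle-cell physiology to brain volume:
    single post-labeling-delay pseudocontinuous arterial spin labeling
    (pCASL) cerebral blood flow quantification with hematocrit-dependent
    blood T1, arterial oxygen content and white-matter-volume
    derivations, silent-cerebral-infarct burden accounting with the
    SIT-trial lesion criterion, per-exposure multivariable regression
    families with Benjamini-Hochberg correction, demographics-table
    group comparisons, and a synthetic cohort and ASL-study generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
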