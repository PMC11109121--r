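Package: codrp
Type: Package
Title: Growth-Adjusted Drug-Sensitivity Indices for Patient-Derived Organoid Screens
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Dose-response analysis for patient-derived cancer organoid drug
    screens: DMSO-normalised viability, four-parameter logistic curve fits,
    normalised area-under-the-curve (AUC) sensitivity summaries, cohort
    Z-scoring, the growth-adjusted CODRP composite index, sensitive/resistant
    classification at a fixed cutoff, and concordance of organoid calls with
    RECIST-derived clinical response labels. Ships the clinical cohort tables
    of a 14-patient EGFR-mutant lung-cancer study as plain-text fixtures and a
    synthetic plate/cohort generator so the whole pipeline can be exercised
    end to end without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, minpack.lm, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
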