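Package: biopsycoder
Title: Rule-Based SNOMED CT Coding of Prostate Biopsy Laboratory Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codes prostate-biopsy laboratory information system (LIS)
    extracts into cancer-registry-style variables using SNOMED CT
    morphology (M) and topography (T) axis codes. Chained,
    comma-separated code strings are parsed and normalised, unique code
    combinations are classified into a diagnosis (benign, malignant,
    atypia/dysplasia, uncertain), a sub-diagnosis, an inflammation
    sub-result and ICD-O-3 codes via reusable lookup tables, and the
    coded variables are joined back onto biopsy episodes with left-outer
    -join semantics. Includes descriptive reporting (capture contingency
    tables, top code-combination frequencies, nested diagnosis frequency
    tables), a synthetic LIS-extract generator and exact-count fixture
    builders for fully offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
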