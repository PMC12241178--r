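Package: moviefc
Title: Sex, Age and Clip Effects in Movie-Watching Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for movie-watching functional connectivity
    (FC): construction of Fisher z-transformed, proportionally
    sparsity-thresholded connectivity matrices from parcellated BOLD time
    series; per-edge mixed-effects testing of sex, age and movie-clip
    effects with partial eta squared and Benjamini-Hochberg false discovery
    rate control; fingerprint-based movie-clip decoding using the Average
    Cross-Session Correlation (ACSC) feature-selection score with
    subject-level cross-validation; and a synthetic-data generator that
    emulates the subject x clip structure of the HCP 7T movie-watching
    release so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    lme4,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
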