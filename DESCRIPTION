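Package: ramanbone
Title: Raman Spectroscopic Prescreening of Archaeological Bone for Collagen Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing collagen preservation in archaeological bone
    from FT-Raman spectra before destructive wet chemistry. Implements band-area
    integration over the C-H stretch (3060-2800 1/cm) and phosphate nu1
    (983-930 1/cm) and nu2 (566-300 1/cm) windows with chord baseline
    correction, the organic-phosphate ratio, replicate aggregation with
    fluorescence rejection and qualitative C-H presence scoring, wet-chemistry
    quality control (atomic C:N, delta notation, collagen-yield flags),
    correlation of the ratio with collagen, carbon and nitrogen yields
    including influence diagnostics, sensitivity re-analysis and Steiger's
    test for dependent overlapping correlations, and threshold-based
    screening decisions evaluated against wet-chemistry ground truth.
    Ships the published reference tables for a tropical burial cohort and a
    synthetic spectrum/cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
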