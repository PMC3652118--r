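Package: agcdx
Title: Fuzzy Expert System for Cervical Cytology Diagnostic Support
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage Mamdani fuzzy expert system supporting the diagnosis
    of cervical neoplasia precursor lesions, with emphasis on atypical
    glandular cells (AGC). Stage one scores the risk of cervical neoplasia
    from seven clinical-background variables; stage two extracts nucleus
    morphometry (mean area, staining, eccentricity, nucleolus counts) from
    stained cytology micrographs; a final injury-resolution model fuses both
    into a Normal / AGC / Positive-to-malignity call. Includes a generic
    configurable Mamdani inference engine with centroid defuzzification, a
    confidence-interval procedure for calibrating membership plateaus from
    per-condition feature means, a synthetic cytology-image and clinical
    cohort generator with pixel-level ground truth, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
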