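Package: arvcvalidity
Title: Semiquantitative Gene-Disease Clinical Validity Scoring for
    Arrhythmogenic Right Ventricular Cardiomyopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the semiquantitative gene-disease clinical
    validity framework used by gene curation expert panels to reappraise
    genes reported for arrhythmogenic right ventricular cardiomyopathy
    (ARVC): case-level genetic evidence points with per-category and
    overall caps, segregation scoring from LOD estimates based on counts
    of informative meioses, case-control evidence, experimental evidence
    with an ARVC-specific model-phenotype gate, classification into
    validity bands (Limited, Moderate, Strong, Definitive) with expert
    Disputed/Refuted overrides, allele-frequency admissibility rules for
    candidate variants (maximum credible population allele frequency and
    a confidence-bounded filtering allele frequency), blinded
    dual-curation concordance reporting, and ClinVar-style variant-class
    distribution summaries. Ships a transcription of the 26-gene ARVC
    reappraisal as a packaged fixture and a synthetic-data generator
    whose expected score breakdowns are tallied independently of the
    scoring code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
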