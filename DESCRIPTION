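Package: tflens
Title: Lineage-Specific Transcription Factor Profiling via Internal Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies lineage-specific transcription factors (TFs) from bulk
    expression cohorts using within-sample (internal) Z-score standardization,
    which makes samples comparable without cross-sample normalization. Provides
    per-sample internal Z-scores, trimmed-mean lineage scores, threshold
    classification into shared and lineage-specific TF sets, cross-cohort
    consolidation, longitudinal phase-trajectory analysis with a dormant-TF
    screen, a self-contained two-class gene set enrichment analysis (GSEA)
    validator with phenotype permutation, and a synthetic-cohort generator with
    known ground truth. Developed around the prostatic adenocarcinoma to
    neuroendocrine prostate cancer (NEPC) transdifferentiation setting but
    applicable to any two-lineage comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
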