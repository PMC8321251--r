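Package: stageGRN
Title: Stage-Specific Gene Regulatory Networks for Disease-Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts stage-specific candidate disease genes from paired
    tumor/normal cohorts by integrating differential expression with DNA
    methylation status, building per-stage transcription-factor-to-target
    regulatory networks by correlation filtering, detecting co-expression
    modules with a dynamic tree cut, selecting stage-specific modules by
    over-representation of stage-exclusive genes, and intersecting
    correlation-core with topology-core genes. Ships a synthetic
    paired-cohort simulator with planted ground truth so every step of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
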