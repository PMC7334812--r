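Package: longiplasma
Title: Longitudinal Plasma Proteome Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal multiplexed affinity
    plasma-proteomics cohorts: per-plate probabilistic quotient and
    plate-mean normalization of bead-array intensities, intraclass
    correlation (ICC(3,1)) profiling of technical versus longitudinal
    stability, mixed-model protein-trait and seasonal association scans,
    per-visit co-expression module detection with cross-visit core-module
    tracking, additive cis-pQTL scanning with Bonferroni control, and
    per-individual baseline/trend/fluctuation deviation signatures. Includes
    a synthetic cohort generator with full ground truth so every stage can
    be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    mclust,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
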