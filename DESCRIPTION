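Package: fhhrisk
Title: Family Health History Risk Assessment Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structured capture, validation and quality scoring of
    relationship-coded family health histories; expansion to explicit
    parent-linked pedigree graphs with LINKAGE/PED export; a Mendelian
    (BRCAPro-style) carrier-probability model computed by exact pedigree
    peeling; absolute-risk calculators for breast cancer (Gail,
    Tyrer-Cuzick simplification) and cardiovascular disease (Framingham
    general CVD, Reynolds, pooled cohort equations) with a uniform
    missing-data contract; a three-tier guideline rule engine emitting
    auditable risk-management recommendations; cohort-level familial
    clustering statistics and patient-activation scoring; and a seeded
    synthetic-cohort simulator with controllable familial clustering so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
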