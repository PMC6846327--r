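Package: MissenseStability
Title: Structure-Based Stability Assessment of Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aggregates predicted protein stability changes (ddG, kcal/mol)
    across an ensemble of crystal structures to assess missense variants,
    computes solvent accessibility (Shrake-Rupley) and relative solvent
    accessibility on the Tien theoretical scale, quantifies interface
    effects (dddG, dRSA) between complexed and isolated chains, and
    evaluates threshold-based pathogenicity classification (confusion
    metrics, ROC/AUC, combination with REVEL scores). Includes a seeded
    synthetic-data module generating variant cohorts, per-structure ddG
    tables and toy helical structures so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
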