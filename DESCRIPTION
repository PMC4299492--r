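Package: ebaflux
Title: Integrated Transcription-Metabolism Modeling with Expression Balance Analysis
Version: 0.1.0
Authors@R: person("EBAflux", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multi-scale modeling of bacterial gene expression and
    growth. A linear transcriptional model is trained from a regulatory
    network and an expression compendium; Expression Balance Analysis (EBA)
    predicts genome-wide expression under genetic and environmental
    perturbations by minimizing transcription-factor equation slacks in a
    box-constrained quadratic program; expression-gated flux bounds (TRAME)
    couple the predicted profile to a flux-balance metabolic layer; and a
    cost-benefit composition yields relative growth predictions. Includes
    FBA/FVA linear programming, gene-protein-reaction rule evaluation,
    in-silico essentiality screening, an evaluation protocol with an
    empirical null model, a greedy GO-coverage experiment designer, and
    seeded synthetic-data generators so every component is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    methods,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
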