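Package: comorbinet
Title: Disease Comorbidity Networks from Patient Diagnosis Trajectories
Version: 0.1.0
Authors@R: person("comorbinet", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Builds thresholded Disease Comorbidity Networks (DCN) from
    patient-visit ICD-10 diagnosis records using Relative Risk and
    phi-correlation, characterises their topology and hierarchical modularity,
    detects comorbidity communities with a multi-level greedy modularity
    (BGLL/Louvain) optimiser, validates comorbidity strength against shared
    disease genes and pathways, and predicts disease occurrence from comorbid
    trajectories with four classifier families under grouped cross-validation.
    Includes a synthetic-cohort generator with planted, recoverable structure
    (modular comorbidity, hierarchy, heavy-tailed prevalence, gene-sharing
    coupling, temporal risk rules) and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Matrix,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
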