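Package: gcflux
Title: Glucocorticoid Partitioning, Protease-Regulated Binding, and
    Steady-State Tracer Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of glucocorticoid
    availability under control of the neutrophil elastase /
    alpha-1-antitrypsin / corticosteroid-binding-globulin (NE/AAT/CBG)
    axis. Solves mass-action partitioning of cortisol or corticosterone
    among intact CBG, protease-cleaved CBG, a nonsaturable albumin pool
    and the free fraction; models serpin inhibition of neutrophil
    elastase and time- and dose-dependent CBG cleavage; analyses
    steady-state deuterated-cortisol (D4/D3) tracer-dilution studies
    including clearance, whole-body rates of appearance and
    arterio-venous net balances; reduces ultrafiltration, equilibrium
    dialysis, radioligand saturation and relative qPCR assays; computes
    metabolic phenotyping indices (HOMA-IR, glucose-tolerance AUC,
    insulin-tolerance decay rate); and generates seeded synthetic
    cohorts with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
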