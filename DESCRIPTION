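Package: cryofx
Title: Direct, Intergenerational and Transgenerational Effect Analysis for
    Embryo Cryopreservation-Transfer Studies
Version: 0.1.0
Authors@R: person("cryofx", "maintainers", email = "cryofx@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for detecting direct (F1), intergenerational
    (F2) and transgenerational (F3) effects of an embryo
    cryopreservation-transfer procedure on phenotypic, transcriptomic and
    metabolomic traits. Implements a Gibbs-sampled Bayesian two-group trait
    model with bounded flat priors, posterior summaries (contrast mean, P0,
    highest-posterior-density intervals, batch-means Monte Carlo errors,
    Geweke Z) and a biological-relevance decision rule; differential
    transcript calling on count/FPKM matrices with Benjamini-Hochberg FDR
    control and a coefficient-of-variation post-filter; internal-standard
    normalisation and ANOVA/Tukey calling of differentially accumulated
    metabolites with per-fraction fold-change summaries; cross-generation
    inheritance partitioning of identifier sets; derived reproductive traits
    (average weight gain, sperm kinematic coefficients, litter sizes); and
    synthetic-data generators emulating the two-group, three-generation
    design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
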