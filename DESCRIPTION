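Package: phenoprint
Title: Temporal Phenotype Fingerprinting of Prodromal Clinical Trajectories
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes longitudinal pre-diagnosis clinical features of a patient
    cohort into temporal images (feature-by-week matrices), applies a
    max-Gaussian temporal-blurring operator so that Euclidean distances reflect
    clinical rather than purely temporal similarity, clusters patients with
    K-means, derives per-cluster phenotype fingerprints (mean temporal images),
    and compares clusters on one-year outcomes using chi-square/ANOVA tests and
    absolute standardized differences. Includes a synthetic-cohort generator
    with planted prodromal archetypes so the full pipeline can be exercised and
    validated without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
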