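Package: pneumotyper
Title: Stratification of the Transcriptionally Active Lung Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers recurring community configurations (pneumotypes) in
    taxa-by-sample read-count profiles of the lower airway microbiome and
    links them to clinical features and host gene expression. Provides
    relative-abundance handling with a prevalence-style 1% detection filter,
    square-root Jensen-Shannon divergence, deterministic k-medoids (PAM)
    with Calinski-Harabasz model selection, Dirichlet multinomial mixture
    clustering fitted by EM, cluster validation by average silhouette width,
    prediction strength and a simulation-based significance test,
    MEGAN-style lowest-common-ancestor taxonomic assignment from tabular
    alignment hits, exact and rank-based association tests with
    Benjamini-Hochberg and Storey q-value control, microbe-host expression
    correlation screens, and seeded synthetic-data generators that emulate
    the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
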