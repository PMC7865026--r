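Package: plaquenet
Title: Multi-Omic Integration of Transcription Factor Activity, miRNA
    Targeting and Cytokine Networks in HIV-Associated Atherosclerosis
Version: 0.1.0
Authors@R:
    person("plaquenet", "developers", email = "plaquenet@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a multi-omic integration
    pipeline for studying atherosclerosis in people living with HIV:
    single-person transcription-factor activity scoring from the PCA of
    target-gene expression, miRNA-target anticorrelation filtering with
    linear-discriminant gene selection, discretized blood-cell-type miRNA
    atlas summaries, negative-binomial Wald differential expression, and a
    sparse-PLS cytokine/miRNA/mRNA association network with differential
    eigenvector centrality between disease groups. Includes a synthetic
    cohort generator that emulates the statistical structure of the study
    data so every stage is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
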