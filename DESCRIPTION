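Package: tmeniche
Title: Tissue Preference, Spatial Niches and Cytokine Response Enrichment
    for Tumor Microenvironment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how immune cell subtypes distribute across tissue
    compartments and spatial niches in tumor microenvironment studies.
    Implements the observed/expected (Ro/e) tissue-preference statistic with
    chi-square or Fisher significance, binned-control gene-signature scoring,
    k-nearest-bead neighborhood composition with Louvain niche detection and
    Wilcoxon/FDR niche enrichment, a ridge-based predictor-target spatial
    colocalization importance model, and cytokine response enrichment by
    cosine similarity against a cytokine-signature dictionary with a
    permutation FDR, plus per-sample pseudobulk differential expression and
    gene-gene correlation. Ships simulators that plant known composition
    shifts, spatial niches, colocalization structure and cytokine programs
    so every estimator has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
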