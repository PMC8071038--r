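Package: brainwcn
Title: Weighted Correlation Networks of Brain Morphometry Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds structural covariance networks from subject-by-feature
    tables of morphometric brain measures (FreeSurfer aseg/aparc stats
    layout), thresholds the Spearman correlation matrix at a fixed link
    density, assigns chordal-distance edge weights, computes twelve node
    centrality measures on the binary and weighted graphs, and compares a
    case group against a subsampled-control null distribution with
    Box-Cox regularized z-scores and empirical p-values, at whole-network
    and single-node level. Includes a synthetic two-group cohort generator
    with block-correlated features and plantable group differences, so the
    full pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
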