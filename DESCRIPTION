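Package: erythroclust
Title: Cross-Dataset Consensus Clustering of Erythroid Differentiation
    Time-Course Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare dynamic transcriptomes of erythroid
    differentiation across multiple cell sources. Implements control-gene
    normalisation and expression filtering of replicate-level intensity
    matrices, empirical-Bayes moderated differential-expression statistics
    with joint p-value / fold-change / log-odds selection, a tunable
    split-merge clustering algorithm (SMART) run repeatedly per dataset,
    fuzzy consensus partition matrices with delta = 0 binarisation
    (Bi-CoPaM), and exact Bimax biclustering of the cross-dataset binary
    membership matrix to extract gene clusters consistently co-expressed
    in every dataset. Includes a synthetic time-course generator with
    planted co-expression structure for end-to-end validation, plus PCA
    and hierarchical-clustering views of the selected genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    nortest,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
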