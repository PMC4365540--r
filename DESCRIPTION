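Package: subgroupCentering
Title: Subgroup-Specific Gene Centering for Molecular Subtype Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Centroid-based molecular subtype classifiers (such as PAM50 for
    breast cancer) assume that the study cohort has the same clinicopathological
    composition as the classifier's training cohort, because gene expression is
    made comparable by per-gene median (or mean) centering on the study cohort
    itself. When the study cohort is skewed -- for example all ER-positive, all
    triple-negative, or any stated mixture -- standard centering misplaces the
    per-gene baseline and corrupts the subtype calls. This package implements
    subgroup-specific gene centering: the training-cohort baseline of each gene
    is mapped to its percentile within a clinicopathologically matched training
    subgroup, and the study cohort is centered on the expression value at that
    percentile. It provides the percentile-mapping transforms (including
    repeated-subsampling and weighted variants for mixture subgroups), a
    nearest-centroid subtype classifier, evaluation utilities (confusion
    summaries, paired McNemar comparisons, ER-composition sweep experiments),
    a synthetic breast-cancer cohort simulator for end-to-end testing, readers
    and writers for the tab-delimited interchange formats, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Classification, Normalization, Transcriptomics
RoxygenNote: 7.3.3
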