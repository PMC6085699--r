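Package: clonalpair
Title: Clonality Testing for Tumour Pairs from Multi-Omics Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies the two tumours of a patient as clonally related
    (a true recurrence) or as independent primaries from copy number,
    DNA methylation, gene expression, variant and fusion-transcript
    profiles.  Implements the similarity-index family (SI and its
    methylation variant) with permutation nulls built from artificial
    cross-patient tumour pairs, Euclidean distance and single-linkage
    dendrogram cherry tests, exact-breakpoint shared-segment and
    shared-mutation counting with percentile thresholds, histopathological
    concordance classification, Cohen's kappa agreement between callers,
    and a seeded synthetic cohort generator with ground-truth clonality
    labels for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
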