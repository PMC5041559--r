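Package: promopanel
Title: Promoter-Activity Biomarker Screening and IHC Panel Evaluation for
    Lung Cancer Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens promoter-level (CAGE-like) count matrices for markers
    that discriminate squamous cell carcinoma from adenocarcinoma of the
    lung, and evaluates immunohistochemistry marker panels for definitive
    subtype diagnosis. Provides library QC, CPM normalisation, inactivity
    filtering, multidimensional scaling, a negative-binomial exact test
    with common dispersion and Benjamini-Hochberg correction, a
    complete-separation screen, exact Clopper-Pearson confidence intervals
    for diagnostic proportions, exhaustive and sequential two-marker panel
    search, average-linkage clustering of binary marker profiles, and a
    synthetic cohort generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
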