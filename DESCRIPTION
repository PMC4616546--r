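Package: markerscreen
Title: Subtype-Specific Marker Gene Screening and Diagnostic Validation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and validation of tumor-subtype-specific diagnostic
    marker genes from bulk expression cohorts. Implements a genome-wide
    percentile-threshold screen on housekeeping-gene-normalized expression
    (high median in a target subtype, near-absent upper percentile in every
    background subtype), diagnostic sensitivity and specificity from ordinal
    immunohistochemistry grading tables with configurable positivity rules
    and Wilson score intervals, and a CpG-level DNA-methylation association
    analysis (Kruskal-Wallis group comparison of beta values and Spearman
    rank correlation with expression). A synthetic-cohort generator with
    planted markers, coupled methylation probes, and simulated staining
    tables provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
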