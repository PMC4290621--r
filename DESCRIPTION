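Package: lncscreen
Title: Annotation, Length Classification and Clinical Screening of
    lncRNA Microarray Probe Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-annotates expression microarray probe sets that measure
    long noncoding RNAs (lncRNAs), classifies lncRNAs by a three-component
    length-distribution mixture fitted in double-log inverse-CDF space,
    screens staged tumor expression cohorts for stage-associated lncRNA
    signatures with a nearest-shrunken-centroid classifier, and calls
    knock-down-responsive target genes with a triple-criterion
    differential-expression rule. Ships a seeded synthetic-data generator
    that emulates the annotation fixtures, staged patient cohorts and
    siRNA knock-down replicate designs the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
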