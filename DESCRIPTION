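Package: MethylScreen
Title: Cross-Platform Screening for Genes Silenced by Promoter Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative screen for candidate tumor-suppressor genes
    silenced by promoter CpG-island hypermethylation. Combines Infinium-style
    beadarray methylation (beta values expressed as deltas against a
    melanocyte reference pool), constitutive expression ratios, and
    post-demethylation (5-aza-2'-deoxycytidine + TSA) re-expression fold
    changes through a filter cascade; reduces EpiTYPER-style CpG-unit
    measurements to per-gene percent methylation with a three-class call;
    and correlates methylation with expression using rank correlation.
    Includes a synthetic-data generator with planted silenced genes so the
    full pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, GeneExpression, Epigenetics, MethylationArray,
    DifferentialMethylation
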