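Package: tadenrich
Title: TAD-Level Integration of Glucocorticoid-Response Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcriptomic and epigenomic feature sets at the
    level of topologically associating domains (TADs). Builds a typed,
    genome-covering domain partition from a TAD call set (core TADs,
    inter-TADs, centromeres, telomeres), classifies features by
    differential-statistics thresholds into response clusters, assigns
    features to domains by the midpoint rule, and tests whether
    glucocorticoid-receptor-bound domains concentrate responsive features
    using an exact adjacent-domain binomial test (strict maximum among the
    center and its four flanking domains, null probability 1/5) and
    hypergeometric domain enrichment. Also provides IUPAC consensus
    scanning for steroid response elements, proximity analyses, TAD-level
    Spearman correlation with hierarchical clustering, and a synthetic-data
    generator that emulates the statistical structure of the real inputs so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    tools,
    utils,
    methods
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
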