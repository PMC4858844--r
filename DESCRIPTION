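Package: simpre
Title: Detection of Significantly Mutated Protein Regions from Somatic
    Missense and In-Frame Indel Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies protein regions significantly enriched in somatic
    cancer mutations (missense point mutations and in-frame insertions and
    deletions) against each gene's own uniform background, using a
    one-sided Fisher's exact test over seed windows with greedy boundary
    optimization and merging.  Includes the upstream mutation-cleaning
    filters (hypermutated samples, common SNP positions, clonal duplicate
    samples, low-complexity overlap), significance tiering, dominant
    mutation-type and cancer-type assignment, a disorder- and
    length-matched randomization test for annotation enrichment,
    amino-acid substitution-rate summaries partitioned by region
    membership, and a fully self-contained synthetic cohort generator for
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
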