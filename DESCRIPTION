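Package: mesoqtl
Title: Genetic Mapping of Maize Mesocotyl Elongation Under Deep Sowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetics of maize mesocotyl elongation
    in deep-sowing trials: multi-environment variance components, broad-sense
    and genotype-by-environment heritability, heterosis indices and
    rate-of-change statistics; a composite-interval-mapping (CIM) QTL scan
    over F2 genotypes and F2:3 family means with permutation thresholds and
    Stuber gene-action classification; bulked-segregant SNP/InDel-index
    mapping with simulation-based confidence bands and linked-region calling;
    and constitutive-QTL (cQTL) integration with candidate-gene nomination
    from differential-expression tables. A forward simulator of biparental
    crosses, F2:3 phenotypes, and pooled sequencing depths makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
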