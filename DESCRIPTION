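Package: sliexome
Title: Exome Variant Prioritization for Specific Language Impairment Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-annotation prioritization of exome variants in nuclear
    families ascertained for specific language impairment (SLI). Implements
    exclusion filtering of annotated variant tables, reference-panel
    frequency tiering (novel / rare / low-frequency / common), SIFT and
    PolyPhen-2 deleteriousness predicates, a candidate-gene screen, a rare
    stop-gain screen with protein truncation annotation, compound-heterozygote
    detection with proximity exclusion, multiple-hit proband reports,
    Mendelian transmission and co-segregation analysis within nuclear
    pedigrees, a within-proband permutation test for pathway sharing with an
    empirical false discovery rate, pooled hypergeometric gene-set
    over-representation with frequency-stratified gene lists, and a seeded
    synthetic cohort generator with a truth manifest for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
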