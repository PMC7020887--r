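Package: pti
Title: Top-Down Phylogenetic Tree Inference for Multi-Region Tumor Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a rooted phylogenetic tree relating multiple tumor
    biopsies of one patient from the presence/absence pattern of somatic
    mutations alone, with no need for accurate allele-frequency estimates.
    Candidate two-way splits of the sample set are scored by the ratio of the
    best to the second-best shared-mutation count; the algorithm recurses
    top-down until every sample is a leaf, collapses unsupported branches into
    multifurcations, and arbitrates tied solutions with an aggregated
    mutation-count tree weight. Includes binarization of variant allele
    frequency tables and multi-sample VCFs, driver-gene branch annotation, a
    per-leaf clade-path tree similarity score, and a clonal-evolution
    simulator for validating recovery of planted clone trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
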