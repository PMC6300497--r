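Package: apomixr
Title: Clonal Structure, Genotypic Diversity and Hybrid Parentage for
    Mixed-Ploidy Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing multilocus microsatellite genotypes in
    species complexes that mix sexual diploids with apomictic polyploids,
    such as Sorbus (Rosaceae). Implements the Bruvo stepwise-mutation
    genetic distance with genome-loss, genome-addition and combined models
    for comparing individuals of unequal ploidy; multilocus genotype (MLG)
    assignment and clonal-lineage clustering with automatic detection of
    the mutation/recombination distance threshold from the pairwise
    distance histogram; genotypic diversity statistics (unbiased Simpson's
    complement, allelic richness with rarefaction); principal coordinate
    analysis and neighbor-joining trees from distance matrices; exhaustive
    parental-pair allele-mismatch scoring and genome-specific inheritance
    ratios for inferring hybrid origins; conversion of flow-cytometry peak
    ratios to relative 2C DNA content and cytotype classification; and a
    seeded synthetic-data generator that emulates the statistical
    structure of such study systems with full ground-truth labels for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
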