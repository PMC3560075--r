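Package: paralogon
Title: Paralogon Detection and Relative Dating of Whole-Genome Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects paralogons (sets of chromosome regions related by
    whole-genome duplication) from gene coordinate tables and gene-family
    trees, dates duplication nodes into named time windows (the two basal
    vertebrate tetraploidizations, 2R, and the teleost-specific 3R) by
    gene-tree/species-tree reconciliation, and reconstructs chromosome
    fusion, fission and translocation scenarios with timing relative to
    the duplications. Includes a genome-evolution simulator that evolves
    genomes and true gene trees along a species tree under whole-genome
    duplication, gene loss and chromosomal rearrangement, and packaged
    fixtures encoding the somatostatin receptor (SSTR) gene repertoire
    and its neighboring gene families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
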