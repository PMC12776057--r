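Package: tandemtools
Title: Copy-Number, Expression and Mechanism Analysis of Near-Identical Tandem Gene Duplicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying tandemly duplicated gene clusters whose copies
    are too similar for standard reference mapping: simulation of tandem-duplication
    haplotypes with planted ground truth (microhomology junctions, unequal-crossover
    mosaics, ecotype SNPs), read-depth copy-number estimation calibrated against
    simulated reads, discriminating k-mer quantification of copy- and allele-specific
    expression from short-read RNA data, attribution of full-length transcript reads
    to individual copies via informative variants, inference of duplication mechanism
    (microhomology-mediated break-induced replication, non-allelic homologous
    recombination crossover windows), and protein-level divergence statistics with
    domain enrichment. Motivated by myosin heavy chain cluster expansions on the
    threespine stickleback sex chromosome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
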