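Package: karyoscope
Title: Virtual Karyotyping and Copy-Number Landscape Analysis from
    Multi-Platform Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs allele-specific virtual karyotypes of tumor
    genomes from three signal layers (binned sequencing read depth, SNP
    array log R ratio and B-allele frequency), with explicit grid-search
    estimation of tumor purity and baseline ploidy so that whole-genome
    doubled samples are re-baselined correctly. Downstream cohort
    analyses operate on a cytogenetic-band copy-number matrix: per-sample
    genomic-instability metrics including an arm-level aneuploidy score,
    permutation-based recurrence scoring, hierarchical clustering of
    alteration patterns, 48-channel copy-number signature profiles
    matched against reference signatures by Euclidean similarity, and
    gene-dosage integration with expression and CpG methylation layers.
    Includes a fully parameterised synthetic-cohort generator that emits
    all five data layers with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
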