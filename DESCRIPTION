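Package: mirvar
Title: Variability of miRNA Genes, Target-Site Scanning and Kinship Mixed-Model Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise single nucleotide polymorphisms in
    microRNA genes and their 3'UTR binding sites. Provides canonical
    seed-match prediction (7mer-m8 and 8mer sites) in spliced 3'UTR
    sequences with strand-aware projection to genomic coordinates,
    classification of SNPs into hairpin sub-regions (seed, anchor,
    supplementary pairing, other mature, precursor), SNP-density
    statistics per region and per mature-miRNA position with
    flanking-bin profiles, and univariate linear mixed-model
    association of SNP genotypes with expression and quantitative
    phenotypes using a genomic kinship matrix and likelihood-ratio
    testing. Seeded generators produce synthetic genomes, annotations,
    variant sets and half-sib cohorts with known ground truth so that
    every stage of the pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, GeneRegulation, Sequencing, Software
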