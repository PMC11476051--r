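Package: ArrayPopGen
Title: Population Diversity, Kinship, Runs of Homozygosity and Selection
    Scans for SNP Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for population-genetic analysis of diploid
    biallelic SNP array genotypes in small livestock populations. Provides
    PLINK (text and binary) and VCF input/output around a
    SummarizedExperiment-based genotype container; marker quality control
    with per-filter accounting; seven genetic-diversity statistics
    (observed/expected heterozygosity, polymorphism information content,
    polymorphic marker ratio, minor allele frequency, effective allele
    number, and LD-based effective population size); VanRaden genomic
    relationship and identity-by-state distance matrices with principal
    component analysis and neighbour-joining family partitioning; sliding
    window detection of runs of homozygosity with the genomic inbreeding
    coefficient F_ROH; and three selection-signature scans (ROH islands,
    windowed nucleotide diversity, windowed Tajima's D) with gene-interval
    annotation and candidate-set intersection. A synthetic genotype
    generator with family structure and planted autozygosity supports
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    igraph,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
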