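Package: mirvarmap
Title: Population Variability Maps of Human microRNA Genes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds population-scale variability maps of microRNA genes from
    multi-sample VCF genotypes and miRBase-style GFF3 annotation. Each
    precursor hairpin is decomposed, strand-aware, into its functional
    substructures (seed, rest-of-mature, loop and flanking arms) and cohort
    variants are classified against them. The package computes per-variant
    profiles (zygosity, carrier frequency, coverage), per-population
    Hardy-Weinberg deviation scans with a Yates-corrected chi-square test,
    per-individual variant burdens, allele-frequency spectra,
    Eigenstrat-style stratification PCA, and cross-tabulations of affected
    miRNAs against disease and pathway-category annotation. A synthetic
    cohort generator with Balding-Nichols population divergence and known
    ground truth makes every stage testable without access to controlled
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
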