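Package: panpav
Title: Pangenome Structural Variation and Presence/Absence Variation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembly-based structural variant calling from whole-genome
    alignment chains and single-coverage synteny nets; merging of
    per-accession calls into a nonredundant population set of presence/absence
    variants (PAVs) with assembly-backed genotyping and call-set evaluation;
    transposable-element and genic annotation of PAVs with gene-loss and
    expression-impact classification; gene-family occupancy and rarefaction
    analysis of a pangenome; windowed population-genetic scans (nucleotide
    diversity, Weir-Cockerham FST, composite selective-sweep intersection,
    linkage-disequilibrium decay, fourfold-degenerate site extraction); and
    GWAS post-processing (Bonferroni thresholds, iterative candidate-region
    definition, gene-haplotype phenotype tests, hypergeometric enrichment).
    Includes a seeded synthetic-data generator that emulates a selfing crop
    pangenome with a wild and several cultivated subpopulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
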