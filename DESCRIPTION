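Package: mitoscan
Title: Simulation and Association Mapping of Mitonuclear Epistasis in
    Multiparent Yeast Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping nuclear loci whose phenotypic effects depend
    on the mitochondrial genotype (mitotype) in multiparent advanced-intercross
    haploid yeast populations.  Provides a forward simulator (structured
    founder panels, Haldane recombination, rounds of random mating, mitotype
    replication, binomially sampled petite-colony counts, growth curves,
    qPCR records and mitochondrial genomes with GC-cluster elements), a SNP
    table filtering pipeline with full provenance, per-SNP main-effect and
    SNP-by-mitotype interaction scans with principal-component covariates
    and conditioning, Bonferroni, Benjamini-Hochberg and Storey q-value
    multiple-testing control, allele-frequency-weighted effect sizes, gene
    and QTL annotation from GFF3, mitochondrial GC-percent and GC-cluster
    feature analysis, and a deterministic end-to-end workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    methods,
    S4Vectors,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
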