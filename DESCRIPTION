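Package: poolBSA
Title: Bulk Segregant Mapping from Pooled Sequencing by Regional
    Averaging of SNP Frequencies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps trait loci from low-coverage pooled sequencing of
    selected and unselected progeny of a defined genetic cross (bulk
    segregant analysis). Per-pool SNP tables are merged, primary-variant
    frequencies are averaged in dynamic windows of a fixed SNP count
    sliding one SNP at a time, and candidate regions of differential
    homozygosity are called where the selected pool approaches fixation
    while the unselected pool stays heterozygous. Includes a forward
    simulator of advanced intercrosses with selection at one or two
    resistance loci followed by low-coverage pooled sequencing, and the
    downstream marker-genetics toolkit: Mendelian segregation chi-square
    and G tests, allele frequencies, Hardy-Weinberg tests, Kosambi map
    distances, two-point recombination and LOD estimation, recombinant
    count based map distances in selected advanced-intercross survivors,
    and genotype-by-dose epistasis summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, GenomeWideAssociation
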