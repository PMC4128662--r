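Package: haploscan
Title: Population-Genomic Scans for Haploid Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for population-genomic analysis of haploid
    resequencing panels such as wild yeast collections. Provides genotype-call
    filtering and repeat/feature masking down to a complete-site analysis
    matrix; site-class-resolved nucleotide diversity (synonymous and
    nonsynonymous sites via Nei-Gojobori counting, introns restricted to the
    region upstream of the CTAAC branchpoint motif, UTRs, noncoding RNA, and
    intergenic sites); Tajima's D and diversity sliding-window scans;
    between-group divergence (Dxy) scans; neighbor-joining trees, PCA and
    distance-thinned SNP subsetting; linkage-disequilibrium decay and
    least-squares estimation of the population recombination rate 4Nr from the
    expected r-squared decay curve; and the pairwise haplotype sharing (PHS)
    statistic for detecting partial selective sweeps from identity-tract
    lengths on a fitted genetic map. A block-coalescent simulator generates
    references, annotations, genotype matrices and marker tables with known
    truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
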