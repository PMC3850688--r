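Package: cytomod
Title: Unbiased Cytosine-Modification Analysis for Compact Animal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for whole-genome analysis of cytosine DNA modifications
    in compact animal genomes such as the honey bee. Provides a bisulfite
    methylation caller that does not discard non-CG (CHH/CHG) contexts: a
    reduced-alphabet bisulfite read mapper, per-site three-level (0/50/100
    percent) probabilistic methylation calling with phred-scaled quality,
    symmetric-methylation pairing, region-by-context summary tables,
    metagene profiles, splice-junction template-strand methylation analysis
    and observed/expected CpG gene classification. Also implements
    5-hydroxymethylcytosine site inference from PvuRts1I restriction
    cut-site offsets, naive peak calling and peak concordance, differential
    modification statistics (Fisher exact tests, greedy Wilcoxon rank-sum
    gene-set enrichment with permutation correction, quantile normalization,
    Benjamini-Hochberg FDR), and a full synthetic-data simulator (genome,
    gene models, planted methylome, bisulfite reads, restriction digestion
    fragment ends, immunoprecipitation fragments) so every pipeline stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
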