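Package: mircross
Title: Integrative miRNA-mRNA Cross-Analysis of Count Data Across Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative small/long RNA cross-analysis workflow for
    three-genotype (wild-type, point-mutant, knockout) count experiments:
    conditional negative-binomial exact-test differential expression with
    median-of-ratios size factors and tagwise dispersion shrinkage,
    full-quantile normalization, FPKM/CPM expression filters, classification
    of deregulated features into loss-of-function / shared / gain-of-function
    contrast classes, genomic-locus co-regulation summaries, anti-correlated
    miRNA-to-mRNA bipartite network construction from target-prediction
    scores, CLIP-peak 3'-UTR binding enrichment statistics, and canonical
    seed-match (MRE) site scanning with in-silico mutagenesis. A synthetic
    count-data generator with planted ground truth makes every stage
    testable end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
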