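#!/usr/bin/env Rscript
# Stage 2: expression filtering and differential expression.
#
# Genes are filtered at FPKM > 0.1 (expressed); miRNAs at CPM >= 1 in at
# least three samples. Both arms then go through the same engine:
# median-of-ratios size factors, tagwise shrunken NB dispersion, the
# conditional NB exact test, and BH FDR, for HOMO:WT and KO:WT.

library(mircross)

ds <- read_dataset("results/data")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

fpkm <- compute_fpkm(ds$gene_counts,
                     setNames(ds$gene_anno$eff_length, ds$gene_anno$gene_id))
expressed <- expression_filter(fpkm, 0.1, 1)
cat(sprintf("expressed genes (FPKM > 0.1 in >= 1 sample): %d of %d\n",
            length(expressed), nrow(ds$gene_counts$counts)))

cpm <- compute_cpm(ds$mirna_counts)
expressed_mir <- expression_filter(cpm, 1 - 1e-9, 3)
cat(sprintf("expressed miRNAs (CPM >= 1 in >= 3 samples): %d of %d\n",
            length(expressed_mir), nrow(ds$mirna_counts$counts)))

for (arm in c("genes", "mirnas")) {
  cm <- if (arm == "genes") ds$gene_counts else ds$mirna_counts
  feats <- if (arm == "genes") expressed else expressed_mir
  for (g in c("HOMO", "KO")) {
    de <- run_de(cm, c(g, "WT"), features = feats)
    n_up <- sum(de$direction == "up"); n_dn <- sum(de$direction == "down")
    cat(sprintf("%s %s:WT — %d up, %d down (q < 0.05)\n", arm, g, n_up, n_dn))
    write.table(de, sprintf("results/de/de_%s_%s.tsv", arm, g),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
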