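#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the structure of a three-genotype (WT / HOMO point-mutant / KO)
# motor-neuron RNA profiling experiment: NB gene and miRNA counts with
# planted contrast-class fold changes, one co-regulated miRNA locus, a
# target-prediction table whose planted anti-correlated edges score >= 0.7,
# and CLIP peaks enriched on targeted genes' 3'-UTRs.

library(mircross)

seed <- as.integer(Sys.getenv("MIRCROSS_SEED", "1"))
out <- "results/data"

params <- sim_params(seed = seed)
ds <- simulate_dataset(params)
print(ds)
write_dataset(ds, out, overwrite = TRUE)

cat("planted DE genes by class:\n")
print(table(ds$truth$gene_table$class, ds$truth$gene_table$direction))
cat("planted DE miRNAs by class:\n")
print(table(ds$truth$mirna_table$class, ds$truth$mirna_table$direction))
cat(sprintf("locus '%s': %d members, all planted shared-up\n",
            params$locus_id, length(ds$truth$locus_members)))
cat(sprintf("planted anti-correlated edges: %d; CLIP-bound genes: %d\n",
            nrow(ds$truth$planted_edges), length(ds$truth$bound_genes)))
cat("dataset written to", out, "\n")
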