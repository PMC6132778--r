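#!/usr/bin/env Rscript
# Stage 5: MRE seed-site map and in-silico mutagenesis of one target UTR.
#
# Picks the most-targeted downregulated gene from the HOMO network (the
# Gria2-like candidate), maps canonical seed sites of its regulator
# miRNAs on the 3'-UTR, then disrupts each regulator's sites in turn and
# both together — the single- and double-mutant reporter-construct logic.

library(mircross)

ds <- read_dataset("results/data")
edges <- read_network_edges("results/network/network_HOMO.tsv")
stopifnot(nrow(edges) > 0)
dir.create("results/mre", showWarnings = FALSE, recursive = TRUE)

counts <- table(edges$gene_id)
gene <- names(sort(counts, decreasing = TRUE))[1]
mirs_ids <- unique(edges$mirna_id[edges$gene_id == gene])
mirs <- ds$mirna_seqs[mirs_ids]
utr <- ds$utr_seqs[[gene]]
cat(sprintf("candidate gene %s: %d regulator miRNA(s), UTR %d nt\n",
            gene, length(mirs), nchar(utr)))

sites <- scan_seed_sites(utr, mirs)
cat(sprintf("%d seed sites found:\n", nrow(sites)))
print(sites)
write.table(sites, "results/mre/sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

muts <- list()
for (id in names(mirs)) {
  sel <- sites[sites$mirna_id == id, ]
  mut <- mutate_mres(utr, sel, mirs)
  left <- scan_seed_sites(mut$sequence, mirs)
  cat(sprintf(
    "mutant for %s: %d substitutions; %d sites of %s remain, %d of others\n",
    id, nrow(mut$changes), sum(left$mirna_id == id), id,
    sum(left$mirna_id != id)))
  muts[[paste0("mut_", id)]] <- mut$sequence
}
if (length(mirs) > 1) {
  dbl <- mutate_mres(utr, sites, mirs)
  left <- scan_seed_sites(dbl$sequence, mirs)
  cat(sprintf("double mutant: %d substitutions; %d sites remain\n",
              nrow(dbl$changes), nrow(left)))
  muts[["mut_all"]] <- dbl$sequence
}
muts[["wild_type"]] <- utr
Biostrings::writeXStringSet(Biostrings::BStringSet(unlist(muts)),
                            "results/mre/utr_constructs.fa")
cat("mutant UTR constructs written to results/mre/utr_constructs.fa\n")
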