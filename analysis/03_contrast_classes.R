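#!/usr/bin/env Rscript
# Stage 3: contrast classes (loss vs gain of function) and locus analysis.
#
# Deregulated features split into KO_only (loss of function), shared, and
# HOMO_only (gain of function). For miRNAs, the fraction of
# upregulated-in-both features mapping to the co-regulated locus mirrors
# the single-locus concentration the analysis is designed to expose.

library(mircross)

ds <- read_dataset("results/data")
rd <- function(f) {
  d <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(d) <- c("de_result", class(d))
  d
}
dir.create("results/classes", showWarnings = FALSE, recursive = TRUE)

for (arm in c("genes", "mirnas")) {
  dh <- rd(sprintf("results/de/de_%s_HOMO.tsv", arm))
  dk <- rd(sprintf("results/de/de_%s_KO.tsv", arm))
  out <- classify_features(dh, dk)
  v <- out$venn
  cat(sprintf("%s: KO_only %d | shared %d | HOMO_only %d\n",
              arm, v$n_ko_only, v$n_shared, v$n_homo_only))
  print(v$up_down)
  write.table(out$table, sprintf("results/classes/classes_%s.tsv", arm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (arm == "mirnas") {
    up_both <- out$table$feature_id[out$table$class == "shared" &
                                      out$table$concordant &
                                      out$table$dir_homo == "up"]
    map <- locus_map(ds$mirna_anno$mirna_id, ds$mirna_anno$locus)
    lf <- locus_fraction(up_both, map, ds$truth$params$locus_id)
    lc <- locus_completeness(up_both, map, ds$truth$params$locus_id,
                             expressed = dh$feature_id)
    cat(sprintf("locus fraction of up-in-both miRNAs: %.1f%% (%d/%d)\n",
                100 * lf$fraction, lf$n_in_locus, lf$n_total))
    cat(sprintf("expressed locus members upregulated: %.1f%% (complete: %s)\n",
                100 * lc$fraction_of_locus_up, lc$complete))
    jsonlite::write_json(list(fraction = lf, completeness = lc),
                         "results/classes/locus.json", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
}
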