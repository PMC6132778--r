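#!/usr/bin/env Rscript
# Stage 4: anti-correlated miRNA-mRNA networks and CLIP-binding enrichment.
#
# Per condition, edges connect significantly deregulated miRNA-gene pairs
# with opposite directions and prediction score >= 0.7. CLIP peaks are
# intersected with 3'-UTRs (strand-aware, BED half-open), and within each
# condition's deregulated genes a 2x2 chi-squared test asks whether
# targeted genes are preferentially bound.

library(mircross)

ds <- read_dataset("results/data")
rd <- function(f) {
  d <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(d) <- c("de_result", class(d))
  d
}
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

bound <- intersect_utr_peaks(ds$utrs, ds$peaks)
cat(sprintf("CLIP-bound genes (3'-UTR overlap, same strand): %d\n",
            length(bound)))
writeLines(bound, "results/network/bound_genes.txt")

cls <- read.table("results/classes/classes_genes.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
targeted_any <- character(0)

for (g in c("HOMO", "KO")) {
  dg <- rd(sprintf("results/de/de_genes_%s.tsv", g))
  dm <- rd(sprintf("results/de/de_mirnas_%s.tsv", g))
  net <- build_network(dg, dm, ds$predictions, min_score = 0.7)
  s <- net$summary
  cat(sprintf(
    "%s network: %d edges; %d down genes targeted by %d up miRNAs\n",
    g, s$n_edges, s$n_down_genes_targeted_by_up_mir,
    s$n_up_mirs_with_down_target))
  export_network(net, sprintf("results/network/network_%s.tsv", g), "tsv")
  export_network(net, sprintf("results/network/network_%s.graphml", g),
                 "graphml", bound_genes = bound)
  targeted_any <- union(targeted_any, unique(net$edges$gene_id))

  dereg <- de_significant(dg)
  targeted <- intersect(unique(net$edges$gene_id), dereg)
  bc <- binding_contingency(dereg, targeted, bound)
  cat(sprintf("  binding enrichment (%s): chi2 = %.3f, p = %.4g\n",
              g, bc$test$statistic, bc$test$pvalue))
  print(unclass(bc$table))
}

tg <- targeting_contingency_pairs(cls, intersect(targeted_any, cls$feature_id))
for (nm in names(tg)) {
  cat(sprintf("targeting enrichment %s: chi2 = %.3f, p = %.4g\n",
              nm, tg[[nm]]$test$statistic, tg[[nm]]$test$pvalue))
}
jsonlite::write_json(
  lapply(tg, function(x) list(cells = as.vector(t(unclass(x$table))),
                              statistic = x$test$statistic,
                              pvalue = x$test$pvalue)),
  "results/network/targeting_enrichment.json", auto_unbox = TRUE,
  digits = NA, pretty = TRUE)
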