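#' Pipeline configuration
#'
#' Thresholds and identifiers steering \code{\link{run_all}}. Defaults
#' follow the printed analysis choices: features count as expressed at
#' FPKM > 0.1, robustly expressed at FPKM > 1 in at least \code{n_reps}
#' samples, miRNAs enter differential testing at CPM >= 1 in at least
#' \code{n_reps} samples, prediction edges need score >= 0.7, and
#' significance is called at BH q < 0.05.
#'
#' @param sim a \code{\link{sim_params}} object (the pipeline's input
#'   generator), or NULL if a dataset is supplied to \code{run_all}.
#' @param q_threshold FDR threshold for DE calls.
#' @param lfc_threshold minimum |log2FC| for DE calls (0 by default; 0.5 is
#'   the candidate-selection filter).
#' @param fpkm_expressed FPKM floor for "expressed" genes.
#' @param fpkm_robust FPKM floor for robust expression summaries.
#' @param cpm_min CPM floor for miRNA testing ("one read per million").
#' @param min_score minimum target-prediction score.
#' @param locus_id co-regulated locus of interest; defaults to the
#'   simulation's locus.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(sim = sim_params(), q_threshold = 0.05,
                            lfc_threshold = 0, fpkm_expressed = 0.1,
                            fpkm_robust = 1, cpm_min = 1, min_score = 0.7,
                            locus_id = NULL) {
  stopifnot(q_threshold > 0, q_threshold <= 1, lfc_threshold >= 0,
            fpkm_expressed >= 0, cpm_min >= 0,
            min_score >= 0, min_score <= 1)
  structure(list(
    sim = sim, q_threshold = q_threshold, lfc_threshold = lfc_threshold,
    fpkm_expressed = fpkm_expressed, fpkm_robust = fpkm_robust,
    cpm_min = cpm_min, min_score = min_score,
    locus_id = if (is.null(locus_id) && !is.null(sim)) sim$locus_id else locus_id
  ), class = "pipeline_config")
}

#' Run the full cross-analysis
#'
#' Orchestrates the whole chain on a dataset (simulated from
#' \code{config$sim} unless one is passed in): expression filtering,
#' differential expression of genes and miRNAs for the HOMO:WT and KO:WT
#' contrasts, contrast-class partition with Venn accounting, locus
#' co-regulation summary, per-condition anti-correlated miRNA-mRNA
#' networks, CLIP-peak 3'-UTR intersection, targeting enrichment across
#' classes, and per-condition binding enrichment. Returns a structured
#' report; optionally writes every stage artifact under \code{out_dir}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param dataset optional pre-built \code{mircross_dataset}; by default
#'   simulated from \code{config$sim}.
#' @param out_dir optional directory for stage TSV/JSON artifacts.
#' @return A \code{mircross_report} list (see elements in the vignette).
#' @export
run_all <- function(config = pipeline_config(), dataset = NULL,
                    out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) {
    if (is.null(config$sim)) stop("either config$sim or dataset is required")
    dataset <- simulate_dataset(config$sim)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(paste(name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # expression filters
  filt <- stage("quantify", {
    fpkm <- compute_fpkm(dataset$gene_counts,
                         stats::setNames(dataset$gene_anno$eff_length,
                                         dataset$gene_anno$gene_id))
    expressed_genes <- expression_filter(fpkm, config$fpkm_expressed, 1L)
    n_reps <- max(table(dataset$gene_counts$sample_meta$genotype))
    robust_genes <- expression_filter(fpkm, config$fpkm_robust, n_reps)
    cpm <- compute_cpm(dataset$mirna_counts)
    expressed_mirnas <- expression_filter(cpm, config$cpm_min - 1e-9, n_reps)
    list(expressed_genes = expressed_genes, robust_genes = robust_genes,
         expressed_mirnas = expressed_mirnas)
  })

  # differential expression, both arms and both contrasts
  de <- stage("de", list(
    genes_homo = run_de(dataset$gene_counts, c("HOMO", "WT"),
                        config$q_threshold, config$lfc_threshold,
                        features = filt$expressed_genes),
    genes_ko = run_de(dataset$gene_counts, c("KO", "WT"),
                      config$q_threshold, config$lfc_threshold,
                      features = filt$expressed_genes),
    mirnas_homo = run_de(dataset$mirna_counts, c("HOMO", "WT"),
                         config$q_threshold, config$lfc_threshold,
                         features = filt$expressed_mirnas),
    mirnas_ko = run_de(dataset$mirna_counts, c("KO", "WT"),
                       config$q_threshold, config$lfc_threshold,
                       features = filt$expressed_mirnas)
  ))

  cls <- stage("classify", list(
    genes = classify_features(de$genes_homo, de$genes_ko),
    mirnas = classify_features(de$mirnas_homo, de$mirnas_ko)
  ))

  loc <- stage("locus", {
    map <- locus_map(dataset$mirna_anno$mirna_id, dataset$mirna_anno$locus)
    mt <- cls$mirnas$table
    up_both <- mt$feature_id[mt$class == "shared" & mt$concordant &
                               mt$dir_homo == "up"]
    if (!config$locus_id %in% names(map$by_locus)) {
      list(map = map, up_both = up_both,
           fraction = list(fraction = NA_real_, defined = FALSE),
           completeness = list(fraction_of_locus_up = NA_real_,
                               complete = NA, defined = FALSE))
    } else {
      list(
        map = map, up_both = up_both,
        fraction = locus_fraction(up_both, map, config$locus_id),
        completeness = locus_completeness(up_both, map, config$locus_id,
                                          expressed = filt$expressed_mirnas)
      )
    }
  })

  nets <- stage("network", list(
    homo = build_network(de$genes_homo, de$mirnas_homo, dataset$predictions,
                         config$min_score),
    ko = build_network(de$genes_ko, de$mirnas_ko, dataset$predictions,
                       config$min_score)
  ))

  bound <- stage("clipmap",
                 intersect_utr_peaks(dataset$utrs, dataset$peaks))

  targeted_any <- sort(unique(c(nets$homo$edges$gene_id, nets$ko$edges$gene_id)))
  enrich <- stage("enrich", {
    targeting <- if (nrow(cls$genes$table) > 0) {
      targeting_contingency_pairs(cls$genes$table,
                                  intersect(targeted_any,
                                            cls$genes$table$feature_id))
    } else NULL
    binding <- list(
      HOMO = binding_contingency_for(de$genes_homo, nets$homo, bound),
      KO = binding_contingency_for(de$genes_ko, nets$ko, bound)
    )
    list(targeting = targeting, binding = binding)
  })

  report <- structure(list(
    config = config,
    n_features = c(genes = nrow(dataset$gene_counts$counts),
                   mirnas = nrow(dataset$mirna_counts$counts)),
    filters = lapply(filt, length),
    venn_genes = cls$genes$venn,
    venn_mirnas = cls$mirnas$venn,
    locus = loc[c("fraction", "completeness")],
    network_summary = list(homo = nets$homo$summary, ko = nets$ko$summary),
    n_bound_genes = length(bound),
    enrichment = enrich,
    de = de, classes = cls, networks = nets, bound_genes = bound,
    truth = dataset$truth
  ), class = "mircross_report")

  if (!is.null(out_dir)) write_report_artifacts(report, dataset, out_dir)
  report
}

# binding enrichment within one condition's deregulated genes
binding_contingency_for <- function(de_genes, network, bound) {
  dereg <- de_significant(de_genes)
  if (length(dereg) == 0)
    return(list(table = NULL, test = list(statistic = NA_real_, pvalue = NA_real_),
                flagged = TRUE))
  targeted <- intersect(unique(network$edges$gene_id), dereg)
  binding_contingency(dereg, targeted, bound)
}

write_report_artifacts <- function(report, dataset, out_dir) {
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$de$genes_homo, "de_genes_HOMO.tsv")
  wt(report$de$genes_ko, "de_genes_KO.tsv")
  wt(report$de$mirnas_homo, "de_mirnas_HOMO.tsv")
  wt(report$de$mirnas_ko, "de_mirnas_KO.tsv")
  wt(report$classes$genes$table, "classes_genes.tsv")
  wt(report$classes$mirnas$table, "classes_mirnas.tsv")
  export_network(report$networks$homo, file.path(out_dir, "network_HOMO.tsv"))
  export_network(report$networks$ko, file.path(out_dir, "network_KO.tsv"))
  writeLines(report$bound_genes, file.path(out_dir, "bound_genes.txt"))
  jsonlite::write_json(report_summary(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Machine-readable summary of a pipeline report
#'
#' @param report a \code{mircross_report}.
#' @return Plain list with the headline numbers (Venn counts, locus
#'   fraction, network pattern counts, contingency cells and p-values).
#' @export
report_summary <- function(report) {
  enr <- report$enrichment
  ctab <- function(x) {
    if (is.null(x) || is.null(x$table)) return(NULL)
    list(cells = as.vector(t(unclass(x$table))),
         statistic = x$test$statistic, pvalue = x$test$pvalue)
  }
  list(
    n_features = as.list(report$n_features),
    filters = report$filters,
    venn_genes = report$venn_genes[c("n_ko_only", "n_shared", "n_homo_only")],
    venn_mirnas = report$venn_mirnas[c("n_ko_only", "n_shared", "n_homo_only")],
    locus_fraction = report$locus$fraction$fraction,
    locus_complete = report$locus$completeness$complete,
    network = report$network_summary,
    n_bound_genes = report$n_bound_genes,
    targeting = lapply(enr$targeting, ctab),
    binding = lapply(enr$binding, ctab)
  )
}

#' @export
print.mircross_report <- function(x, ...) {
  v <- x$venn_genes; vm <- x$venn_mirnas
  cat("mircross_report\n")
  cat(sprintf("  genes:  KO_only %d | shared %d | HOMO_only %d\n",
              v$n_ko_only, v$n_shared, v$n_homo_only))
  cat(sprintf("  miRNAs: KO_only %d | shared %d | HOMO_only %d\n",
              vm$n_ko_only, vm$n_shared, vm$n_homo_only))
  if (isTRUE(x$locus$fraction$defined))
    cat(sprintf("  locus fraction of up-in-both miRNAs: %.3f (%d/%d)\n",
                x$locus$fraction$fraction, x$locus$fraction$n_in_locus,
                x$locus$fraction$n_total))
  cat(sprintf("  HOMO network: %d edges, %d down genes targeted by up miRNAs\n",
              x$network_summary$homo$n_edges,
              x$network_summary$homo$n_down_genes_targeted_by_up_mir))
  hb <- x$enrichment$binding$HOMO; kb <- x$enrichment$binding$KO
  if (!is.null(hb$test$pvalue))
    cat(sprintf("  binding enrichment p: HOMO %.3g, KO %.3g\n",
                hb$test$pvalue, kb$test$pvalue))
  invisible(x)
}
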