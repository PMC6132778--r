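#' Anti-correlated miRNA-mRNA bipartite network
#'
#' Joins differential-expression calls for genes and miRNAs with a
#' target-prediction score table: an edge is retained iff the prediction
#' score passes \code{min_score} (inclusive, following the "threshold equal
#' to 0.7" convention) and both endpoints are significantly deregulated in
#' opposite directions. "Anti-correlated" is implemented as opposite
#' significant directions, not a correlation coefficient, which is the only
#' reading workable at three replicates per genotype.
#'
#' @param de_genes,de_mirnas \code{de_result} tables for one condition.
#' @param predictions data.frame with columns \code{mirna_id},
#'   \code{gene_id}, \code{score} (unique pairs, scores in [0, 1]).
#' @param min_score minimum prediction score (default 0.7, inclusive).
#' @return A \code{bipartite_network}: list with \code{edges} (data.frame
#'   \code{mirna_id}, \code{gene_id}, \code{score}, \code{pattern}),
#'   \code{mirna_nodes}, \code{gene_nodes}, \code{summary} (per-pattern gene
#'   and miRNA counts), and \code{n_dropped_predictions} (predictions that
#'   referenced unknown features).
#' @export
build_network <- function(de_genes, de_mirnas, predictions, min_score = 0.7) {
  stopifnot(all(c("mirna_id", "gene_id", "score") %in% names(predictions)))
  if (anyDuplicated(predictions[, c("mirna_id", "gene_id")]))
    stop("duplicate (mirna, gene) prediction pairs")
  if (any(!is.finite(predictions$score)))
    stop("non-finite prediction scores")
  known <- predictions$mirna_id %in% de_mirnas$feature_id &
    predictions$gene_id %in% de_genes$feature_id
  n_dropped <- sum(!known)
  if (n_dropped > 0)
    warning(n_dropped, " prediction(s) reference unknown features; dropped")
  pred <- predictions[known, , drop = FALSE]
  gdir <- stats::setNames(de_genes$direction, de_genes$feature_id)
  mdir <- stats::setNames(de_mirnas$direction, de_mirnas$feature_id)
  dg <- gdir[pred$gene_id]
  dm <- mdir[pred$mirna_id]
  keep <- pred$score >= min_score & dg != "none" & dm != "none" & dg != dm
  edges <- data.frame(
    mirna_id = pred$mirna_id[keep],
    gene_id = pred$gene_id[keep],
    score = pred$score[keep],
    pattern = ifelse(dm[keep] == "up", "up-miR/down-gene", "down-miR/up-gene"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  mirna_nodes <- data.frame(
    mirna_id = sort(unique(edges$mirna_id)),
    stringsAsFactors = FALSE
  )
  mirna_nodes$direction <- unname(mdir[mirna_nodes$mirna_id])
  gene_nodes <- data.frame(
    gene_id = sort(unique(edges$gene_id)),
    stringsAsFactors = FALSE
  )
  gene_nodes$direction <- unname(gdir[gene_nodes$gene_id])
  summ <- list(
    n_edges = nrow(edges),
    n_down_genes_targeted_by_up_mir =
      length(unique(edges$gene_id[edges$pattern == "up-miR/down-gene"])),
    n_up_genes_targeted_by_down_mir =
      length(unique(edges$gene_id[edges$pattern == "down-miR/up-gene"])),
    n_up_mirs_with_down_target =
      length(unique(edges$mirna_id[edges$pattern == "up-miR/down-gene"])),
    n_down_mirs_with_up_target =
      length(unique(edges$mirna_id[edges$pattern == "down-miR/up-gene"]))
  )
  structure(
    list(edges = edges, mirna_nodes = mirna_nodes, gene_nodes = gene_nodes,
         summary = summ, n_dropped_predictions = n_dropped,
         min_score = min_score),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "bipartite_network: %d edges (score >= %g), %d miRNAs, %d genes\n",
    nrow(x$edges), x$min_score, nrow(x$mirna_nodes), nrow(x$gene_nodes)))
  invisible(x)
}

#' Genes whose 3'-UTR overlaps a CLIP peak
#'
#' Interval intersection of 3'-UTRs with CLIP peaks in BED (0-based
#' half-open) coordinates: a gene is bound iff at least one of its UTR
#' intervals overlaps at least one peak by \code{min_overlap_bp} on the same
#' strand (strand-aware by default, as CLIP peaks are strand-specific).
#'
#' @param utrs data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{gene_id}.
#' @param peaks data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (and optionally \code{peak_id}).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @param same_strand require matching strand (default TRUE).
#' @return Character vector of bound gene ids.
#' @export
intersect_utr_peaks <- function(utrs, peaks, min_overlap_bp = 1,
                                same_strand = TRUE) {
  validate_intervals(utrs, "utrs")
  validate_intervals(peaks, "peaks")
  if (nrow(utrs) == 0 || nrow(peaks) == 0) return(character(0))
  gr_u <- as_granges(utrs)
  gr_p <- as_granges(peaks)
  hits <- GenomicRanges::findOverlaps(
    gr_u, gr_p, minoverlap = min_overlap_bp,
    ignore.strand = !same_strand
  )
  sort(unique(utrs$gene_id[S4Vectors::queryHits(hits)]))
}

validate_intervals <- function(df, what) {
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop(what, " must have columns chrom/start/end/strand")
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0)
    stop("malformed interval in ", what, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (need 0 <= start < end)")
  invisible(df)
}

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    # BED half-open [start, end) -> 1-based closed [start+1, end]
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

#' Export a bipartite network
#'
#' Writes the edge list as TSV or the full attributed graph as GraphML
#' (replacing an interactive graph-viewer import). Node attributes carry
#' direction and, when supplied, contrast class, CLIP-bound status, and a
#' functional-category passthrough label.
#'
#' @param network a \code{bipartite_network}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @param gene_class optional named vector of contrast classes per gene.
#' @param bound_genes optional character vector of CLIP-bound gene ids.
#' @param gene_category optional named vector of functional-category labels.
#' @return The path, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml"),
                           gene_class = NULL, bound_genes = NULL,
                           gene_category = NULL) {
  stopifnot(inherits(network, "bipartite_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  g <- network_igraph(network, gene_class, bound_genes, gene_category)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

network_igraph <- function(network, gene_class = NULL, bound_genes = NULL,
                           gene_category = NULL) {
  mn <- network$mirna_nodes$mirna_id
  gn <- network$gene_nodes$gene_id
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(
    g, length(mn), name = mn, type = "mirna",
    direction = network$mirna_nodes$direction,
    class = "", bound = FALSE, category = ""
  )
  lk <- function(v, ids, default) {
    if (is.null(v)) rep(default, length(ids))
    else {
      out <- v[ids]
      out[is.na(out)] <- default
      unname(out)
    }
  }
  g <- igraph::add_vertices(
    g, length(gn), name = gn, type = "gene",
    direction = network$gene_nodes$direction,
    class = lk(gene_class, gn, ""),
    bound = if (is.null(bound_genes)) rep(FALSE, length(gn)) else gn %in% bound_genes,
    category = lk(gene_category, gn, "")
  )
  if (nrow(network$edges) > 0) {
    ev <- rbind(network$edges$mirna_id, network$edges$gene_id)
    g <- igraph::add_edges(g, as.vector(ev),
                           score = network$edges$score,
                           pattern = network$edges$pattern)
  }
  g
}

#' Read an exported edge-list TSV back
#'
#' @param path TSV written by \code{\link{export_network}}.
#' @return data.frame with the edge columns.
#' @export
read_network_edges <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
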