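#' Simulate a full synthetic dataset with planted ground truth
#'
#' Generates every input the downstream analysis consumes — gene and miRNA
#' count matrices, feature annotation, a target-prediction score table,
#' 3'-UTR and CLIP-peak intervals, UTR and miRNA sequences — together with
#' a \code{truth} record of everything planted. Counts are drawn from a
#' negative binomial (NB2: variance = mu + phi * mu^2) with per-feature
#' log-normal dispersion and per-sample multiplicative library-size
#' scaling, so normalization genuinely matters downstream. Planted classes
#' shift the stated genotypes only: \code{KO_only} shifts KO vs WT,
#' \code{shared} shifts KO and HOMO concordantly, \code{HOMO_only} shifts
#' HOMO vs WT; optional HET columns carry \code{het_effect_fraction} times
#' the HOMO log2 effect.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return A \code{mircross_dataset}: list with \code{gene_counts} and
#'   \code{mirna_counts} (\code{\link{count_matrix}}), \code{gene_anno},
#'   \code{mirna_anno}, \code{predictions}, \code{utrs}, \code{peaks}
#'   (BED-style data.frames, 0-based half-open), \code{utr_seqs},
#'   \code{mirna_seqs} (named character), and \code{truth}.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  set.seed(params$seed)
  geno <- rep(params$genotypes, each = params$n_reps)
  sample_ids <- paste0(geno, "_rep", rep(seq_len(params$n_reps),
                                         times = length(params$genotypes)))

  gene_ids <- sprintf("gene_%05d", seq_len(params$n_genes))
  mirna_ids <- sprintf("mir_%04d", seq_len(params$n_mirnas))

  gene_truth <- plant_gene_classes(params)
  mirna_truth <- plant_mirna_classes(params)

  gene_counts <- draw_counts(params, gene_ids, gene_truth, geno, sample_ids)
  mirna_counts <- draw_counts(params, mirna_ids, mirna_truth, geno, sample_ids)

  gene_anno <- gene_annotation(params, gene_ids)
  mirna_anno <- mirna_annotation(params, mirna_ids, mirna_truth$locus_members)

  mirna_seqs <- random_sequences(mirna_ids, len = 22, alphabet = c("A", "C", "G", "U"))

  tg <- plant_targets(params, gene_truth, mirna_truth, gene_ids, mirna_ids)
  utr_seqs <- utr_sequences(gene_anno, tg$planted_edges, mirna_seqs)

  bnd <- plant_binding(params, gene_ids, tg$targeted_genes)
  peaks <- make_peaks(params, gene_anno, bnd$bound_genes)

  truth <- list(
    gene_table = gene_truth$table,
    mirna_table = mirna_truth$table,
    de_genes_by_class = split_by_class(gene_truth$table),
    de_mirnas_by_class = split_by_class(mirna_truth$table),
    locus_members = mirna_truth$locus_members,
    planted_edges = tg$planted_edges,
    targeted_genes = tg$targeted_genes,
    bound_genes = bnd$bound_genes,
    params = params
  )
  structure(
    list(
      gene_counts = gene_counts, mirna_counts = mirna_counts,
      gene_anno = gene_anno, mirna_anno = mirna_anno,
      predictions = tg$predictions,
      utrs = gene_anno[, c("chrom", "utr_start", "utr_end", "strand", "gene_id")] |>
        rename_utrs(),
      peaks = peaks,
      utr_seqs = utr_seqs, mirna_seqs = mirna_seqs,
      truth = truth
    ),
    class = "mircross_dataset"
  )
}

# ---- planting ---------------------------------------------------------------

# Per-feature contrast class / direction table for genes.
plant_gene_classes <- function(params) {
  n <- params$n_genes
  tab <- empty_truth_table()
  if (n > 0) {
    n_ko <- round(params$frac_de_ko_only * n)
    n_sh <- round(params$frac_de_shared * n)
    n_ho <- round(params$frac_de_homo_only * n)
    idx <- sample.int(n, n_ko + n_sh + n_ho)
    cls <- rep(c("KO_only", "shared", "HOMO_only"), times = c(n_ko, n_sh, n_ho))
    dir <- ifelse(stats::runif(length(idx)) < params$frac_up, "up", "down")
    tab <- data.frame(
      feature_id = sprintf("gene_%05d", idx), class = cls, direction = dir,
      stringsAsFactors = FALSE
    )
  }
  list(table = tab, locus_members = character(0))
}

# miRNA planting is locus-first: every locus member is shared-up, plus
# enough non-locus shared-up features that the expected locus fraction
# among up-in-both miRNAs equals frac_locus_in_up. frac_de_shared plants
# shared-down features; exclusive classes use mirna_frac_up.
plant_mirna_classes <- function(params) {
  n <- params$n_mirnas
  if (n == 0) return(list(table = empty_truth_table(), locus_members = character(0)))
  n_up_total <- min(n, round(params$locus_size / params$frac_locus_in_up))
  n_locus <- min(params$locus_size, n_up_total)
  perm <- sample.int(n)
  take <- function(k) {
    out <- utils::head(perm, k)
    perm <<- utils::tail(perm, -k)
    out
  }
  locus_idx <- take(n_locus)
  extra_up_idx <- take(max(0, n_up_total - n_locus))
  sh_down_idx <- take(min(length(perm), round(params$frac_de_shared * n)))
  ko_idx <- take(min(length(perm), round(params$frac_de_ko_only * n)))
  ho_idx <- take(min(length(perm), round(params$frac_de_homo_only * n)))
  tab <- rbind(
    truth_rows(locus_idx, "shared", "up"),
    truth_rows(extra_up_idx, "shared", "up"),
    truth_rows(sh_down_idx, "shared", "down"),
    truth_rows(ko_idx, "KO_only",
               ifelse(stats::runif(length(ko_idx)) < params$mirna_frac_up,
                      "up", "down")),
    truth_rows(ho_idx, "HOMO_only",
               ifelse(stats::runif(length(ho_idx)) < params$mirna_frac_up,
                      "up", "down"))
  )
  list(table = tab, locus_members = sprintf("mir_%04d", sort(locus_idx)))
}

truth_rows <- function(idx, class, direction) {
  if (length(idx) == 0) return(empty_truth_table())
  data.frame(feature_id = sprintf("mir_%04d", idx), class = class,
             direction = direction, stringsAsFactors = FALSE)
}

empty_truth_table <- function() {
  data.frame(feature_id = character(0), class = character(0),
             direction = character(0), stringsAsFactors = FALSE)
}

split_by_class <- function(tab) {
  lapply(split(tab, tab$class), function(d)
    stats::setNames(d$direction, d$feature_id))
}

# ---- counts -----------------------------------------------------------------

# log2 effect per feature x genotype implied by the planted classes
effect_matrix <- function(params, feature_ids, truth_table) {
  delta <- matrix(0, length(feature_ids), length(params$genotypes),
                  dimnames = list(feature_ids, params$genotypes))
  if (nrow(truth_table) > 0) {
    sgn <- ifelse(truth_table$direction == "up", 1, -1) * params$lfc_magnitude
    i <- match(truth_table$feature_id, feature_ids)
    hit_ko <- truth_table$class %in% c("KO_only", "shared")
    hit_homo <- truth_table$class %in% c("HOMO_only", "shared")
    if ("KO" %in% params$genotypes)
      delta[i[hit_ko], "KO"] <- sgn[hit_ko]
    if ("HOMO" %in% params$genotypes)
      delta[i[hit_homo], "HOMO"] <- sgn[hit_homo]
    if ("HET" %in% params$genotypes)
      delta[, "HET"] <- params$het_effect_fraction * delta[, "HOMO"]
  }
  delta
}

draw_counts <- function(params, feature_ids, truth, geno, sample_ids) {
  n <- length(feature_ids)
  L <- stats::runif(length(sample_ids), params$libsize_range[1],
                    params$libsize_range[2])
  f <- L / exp(mean(log(L)))
  if (n == 0) {
    m <- matrix(0, 0, length(sample_ids),
                dimnames = list(character(0), sample_ids))
    return(count_matrix(m, genotype = geno))
  }
  b <- exp(stats::runif(n, params$baseline_mean_log_range[1],
                        params$baseline_mean_log_range[2]))
  phi <- stats::rlnorm(n, log(params$dispersion_shape), 0.4)
  delta <- effect_matrix(params, feature_ids, truth$table)
  mu <- b * 2^delta[, geno, drop = FALSE]
  mu <- sweep(mu, 2, f, "*")
  m <- matrix(stats::rnbinom(n * length(sample_ids), mu = mu, size = 1 / phi),
              nrow = n, dimnames = list(feature_ids, sample_ids))
  count_matrix(m, genotype = geno)
}

# ---- annotation -------------------------------------------------------------

gene_annotation <- function(params, gene_ids) {
  n <- length(gene_ids)
  if (n == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), eff_length = integer(0),
                      utr_start = integer(0), utr_end = integer(0),
                      biotype = character(0), stringsAsFactors = FALSE))
  }
  chrom <- paste0("chr", 1 + (seq_len(n) - 1) %% 19)
  slot <- (seq_len(n) - 1) %/% 19           # position index along a chromosome
  gstart <- slot * 50000L
  utr_len <- sample(200:2000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(
    gene_id = gene_ids, chrom = chrom,
    start = gstart, end = gstart + 10000L + utr_len,
    strand = strand,
    eff_length = round(stats::runif(n, 500, 5000)),
    utr_start = gstart + 10000L, utr_end = gstart + 10000L + utr_len,
    biotype = "protein_coding", stringsAsFactors = FALSE
  )
}

mirna_annotation <- function(params, mirna_ids, locus_members) {
  n <- length(mirna_ids)
  if (n == 0) {
    return(data.frame(mirna_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), locus = character(0),
                      stringsAsFactors = FALSE))
  }
  in_locus <- mirna_ids %in% locus_members
  chrom <- ifelse(in_locus, "chr12",
                  paste0("chr", 1 + (seq_len(n) - 1) %% 19))
  start <- integer(n)
  # locus members sit consecutively on chr12; others scatter over a distinct band
  start[in_locus] <- 3000000L + 2000L * (seq_len(sum(in_locus)) - 1L)
  start[!in_locus] <- 80000000L + 5000L * (seq_len(sum(!in_locus)) - 1L)
  data.frame(
    mirna_id = mirna_ids, chrom = chrom, start = start, end = start + 100L,
    strand = "+",
    locus = ifelse(in_locus, params$locus_id, NA_character_),
    stringsAsFactors = FALSE
  )
}

rename_utrs <- function(df) {
  names(df) <- c("chrom", "start", "end", "strand", "gene_id")
  df
}

# ---- targets, sequences, binding -------------------------------------------

plant_targets <- function(params, gene_truth, mirna_truth, gene_ids, mirna_ids) {
  gt <- gene_truth$table
  mt <- mirna_truth$table
  down_genes <- gt[gt$direction == "down", , drop = FALSE]
  n_target <- round(params$frac_targeted * nrow(down_genes))
  sel <- if (nrow(down_genes) > 0) {
    down_genes[sample.int(nrow(down_genes), n_target), , drop = FALSE]
  } else down_genes
  up_in_homo <- mt$feature_id[mt$direction == "up" &
                                mt$class %in% c("shared", "HOMO_only")]
  up_in_ko <- mt$feature_id[mt$direction == "up" &
                              mt$class %in% c("shared", "KO_only")]
  edges <- NULL
  lo <- max(0.7, params$pred_score_range[1])
  hi <- max(lo, params$pred_score_range[2])
  for (i in seq_len(nrow(sel))) {
    pool <- if (sel$class[i] %in% c("shared", "HOMO_only")) up_in_homo else up_in_ko
    if (length(pool) == 0) next
    edges <- rbind(edges, data.frame(
      mirna_id = pool[sample.int(length(pool), 1)],
      gene_id = sel$feature_id[i],
      score = stats::runif(1, lo, hi),
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(edges))
    edges <- data.frame(mirna_id = character(0), gene_id = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  predictions <- edges
  if (length(mirna_ids) > 0 && length(gene_ids) > 0) {
    n_bg <- 4L * length(mirna_ids)
    bg <- data.frame(
      mirna_id = sample(mirna_ids, n_bg, replace = TRUE),
      gene_id = sample(gene_ids, n_bg, replace = TRUE),
      score = stats::runif(n_bg, params$pred_score_range[1],
                           params$pred_score_range[2]),
      stringsAsFactors = FALSE
    )
    key <- function(d) paste(d$mirna_id, d$gene_id)
    bg <- bg[!duplicated(key(bg)) & !key(bg) %in% key(edges), , drop = FALSE]
    predictions <- rbind(edges, bg)
  }
  rownames(predictions) <- NULL
  list(planted_edges = edges,
       targeted_genes = sort(unique(edges$gene_id)),
       predictions = predictions)
}

random_sequences <- function(ids, len, alphabet = c("A", "C", "G", "T")) {
  stats::setNames(vapply(ids, function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1)), ids)
}

# UTR sequences of the annotated lengths; each planted edge's miRNA gets an
# 8mer seed-match site embedded in its target gene's UTR.
utr_sequences <- function(gene_anno, planted_edges, mirna_seqs) {
  if (nrow(gene_anno) == 0) return(stats::setNames(character(0), character(0)))
  lens <- gene_anno$utr_end - gene_anno$utr_start
  seqs <- stats::setNames(vapply(seq_len(nrow(gene_anno)), function(i) {
    paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE), collapse = "")
  }, character(1)), gene_anno$gene_id)
  for (i in seq_len(nrow(planted_edges))) {
    g <- planted_edges$gene_id[i]
    m <- normalize_seq(mirna_seqs[[planted_edges$mirna_id[i]]])
    site <- paste0(revcomp(substr(m, 2, 8)), "A")  # 8mer site
    s <- seqs[[g]]
    pos <- min(21L, nchar(s) - 7L)
    substr(s, pos, pos + 7L) <- site
    seqs[[g]] <- s
  }
  seqs
}

plant_binding <- function(params, gene_ids, targeted_genes) {
  if (length(gene_ids) == 0) return(list(bound_genes = character(0)))
  p <- ifelse(gene_ids %in% targeted_genes,
              params$p_bound_targeted, params$p_bound_untargeted)
  bound <- gene_ids[stats::runif(length(gene_ids)) < p]
  list(bound_genes = bound)
}

# One peak inside each bound gene's UTR (same strand), plus unbound decoy
# peaks on a spare chromosome so intersection has true negatives.
make_peaks <- function(params, gene_anno, bound_genes) {
  rows <- gene_anno[gene_anno$gene_id %in% bound_genes, , drop = FALSE]
  n_decoy <- max(1L, round(0.2 * nrow(gene_anno)))
  peak <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), peak_id = character(0), stringsAsFactors = FALSE
  )
  if (nrow(rows) > 0) {
    w <- pmin(50L, rows$utr_end - rows$utr_start)
    off <- floor((rows$utr_end - rows$utr_start - w) / 2)
    peak <- data.frame(
      chrom = rows$chrom, start = rows$utr_start + off,
      end = rows$utr_start + off + w, strand = rows$strand,
      peak_id = sprintf("peak_%05d", seq_len(nrow(rows))),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(gene_anno) > 0) {
    decoy <- data.frame(
      chrom = "chrU", start = 1000L * seq_len(n_decoy),
      end = 1000L * seq_len(n_decoy) + 50L, strand = "+",
      peak_id = sprintf("peak_decoy_%05d", seq_len(n_decoy)),
      stringsAsFactors = FALSE
    )
    peak <- rbind(peak, decoy)
  }
  rownames(peak) <- NULL
  peak
}

#' @export
print.mircross_dataset <- function(x, ...) {
  cat(sprintf(
    "mircross_dataset: %d genes, %d miRNAs, %d samples; %d planted DE genes, %d planted DE miRNAs, %d planted edges, %d bound genes\n",
    nrow(x$gene_counts$counts), nrow(x$mirna_counts$counts),
    ncol(x$gene_counts$counts), nrow(x$truth$gene_table),
    nrow(x$truth$mirna_table), nrow(x$truth$planted_edges),
    length(x$truth$bound_genes)))
  invisible(x)
}
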