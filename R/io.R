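#' Write a simulated dataset to disk
#'
#' Serializes every component as plain text: TSV count matrices (first
#' column the feature id, header the sample ids), a sample sheet TSV,
#' annotation TSVs, BED6 intervals (0-based half-open), FASTA sequences,
#' a predictions TSV, and the truth record as JSON. The files round-trip
#' losslessly through \code{\link{read_dataset}}.
#'
#' @param dataset a \code{mircross_dataset}.
#' @param directory output directory (created if absent).
#' @param overwrite allow overwriting existing files (default FALSE).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, directory, overwrite = FALSE) {
  stopifnot(inherits(dataset, "mircross_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_counts = file.path(directory, "gene_counts.tsv"),
    mirna_counts = file.path(directory, "mirna_counts.tsv"),
    samples = file.path(directory, "samples.tsv"),
    gene_anno = file.path(directory, "gene_anno.tsv"),
    mirna_anno = file.path(directory, "mirna_anno.tsv"),
    predictions = file.path(directory, "predictions.tsv"),
    utrs = file.path(directory, "utrs.bed"),
    peaks = file.path(directory, "peaks.bed"),
    utr_seqs = file.path(directory, "utr_seqs.fa"),
    mirna_seqs = file.path(directory, "mirna_seqs.fa"),
    truth = file.path(directory, "truth.json")
  )
  if (!overwrite && any(file.exists(paths)))
    stop("output files exist; pass overwrite = TRUE to replace them")
  write_count_tsv(dataset$gene_counts, paths["gene_counts"])
  write_count_tsv(dataset$mirna_counts, paths["mirna_counts"])
  utils::write.table(dataset$gene_counts$sample_meta, paths["samples"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$gene_anno, paths["gene_anno"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$mirna_anno, paths["mirna_anno"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$predictions, paths["predictions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed6(dataset$utrs, dataset$utrs$gene_id, paths["utrs"])
  write_bed6(dataset$peaks, dataset$peaks$peak_id, paths["peaks"])
  write_fasta(dataset$utr_seqs, paths["utr_seqs"])
  write_fasta(dataset$mirna_seqs, paths["mirna_seqs"])
  truth <- dataset$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param directory directory containing the files.
#' @return A \code{mircross_dataset}.
#' @export
read_dataset <- function(directory) {
  samples <- utils::read.table(file.path(directory, "samples.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  gene_counts <- read_count_tsv(file.path(directory, "gene_counts.tsv"), samples)
  mirna_counts <- read_count_tsv(file.path(directory, "mirna_counts.tsv"), samples)
  rd <- function(f) utils::read.table(file.path(directory, f), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
  utrs <- read_bed6(file.path(directory, "utrs.bed"))
  names(utrs)[names(utrs) == "name"] <- "gene_id"
  peaks <- read_bed6(file.path(directory, "peaks.bed"))
  names(peaks)[names(peaks) == "name"] <- "peak_id"
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  structure(
    list(
      gene_counts = gene_counts, mirna_counts = mirna_counts,
      gene_anno = rd("gene_anno.tsv"), mirna_anno = rd("mirna_anno.tsv"),
      predictions = rd("predictions.tsv"),
      utrs = utrs, peaks = peaks,
      utr_seqs = read_fasta(file.path(directory, "utr_seqs.fa")),
      mirna_seqs = read_fasta(file.path(directory, "mirna_seqs.fa")),
      truth = truth
    ),
    class = "mircross_dataset"
  )
}

write_count_tsv <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_count_tsv <- function(path, samples) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- samples[match(colnames(m), samples$sample_id), ]
  count_matrix(m, genotype = meta$genotype, replicate = meta$replicate)
}

write_bed6 <- function(df, names, path) {
  bed <- data.frame(df$chrom, df$start, df$end, names, 0L, df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_bed6 <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  bed[, c("chrom", "start", "end", "strand", "name")]
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
}

read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}
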