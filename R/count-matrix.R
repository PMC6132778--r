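#' Count matrix with sample metadata
#'
#' Container for an integer read-count matrix (features in rows, samples in
#' columns) together with the genotype/replicate design of the samples. All
#' differential-expression and normalization functions in the package take
#' this container.
#'
#' @param counts integer matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids). Values must be non-negative integers.
#' @param genotype character vector, one genotype label per sample
#'   (e.g. \code{"WT"}, \code{"HOMO"}, \code{"KO"}).
#' @param replicate integer vector, replicate index per sample. Defaults to
#'   a running index within genotype.
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (the matrix) and \code{sample_meta} (a data.frame with
#'   columns \code{sample_id}, \code{genotype}, \code{replicate}).
#' @export
count_matrix <- function(counts, genotype, replicate = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have rownames (feature ids)")
  if (is.null(colnames(counts))) stop("counts must have colnames (sample ids)")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  if (length(genotype) != ncol(counts))
    stop("genotype must have one entry per sample")
  genotype <- as.character(genotype)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(genotype), genotype, FUN = seq_along)
  }
  storage.mode(counts) <- "double"  # keeps large libraries safe; values stay integral
  structure(
    list(
      counts = counts,
      sample_meta = data.frame(
        sample_id = colnames(counts),
        genotype = genotype,
        replicate = as.integer(replicate),
        stringsAsFactors = FALSE
      )
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d features x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s:%d", names(table(x$sample_meta$genotype)),
                  as.integer(table(x$sample_meta$genotype))), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Columns of a count_matrix belonging to one genotype.
genotype_columns <- function(cm, genotype) {
  which(cm$sample_meta$genotype == genotype)
}

# Subset samples, keeping metadata in step.
subset_samples <- function(cm, idx) {
  count_matrix(cm$counts[, idx, drop = FALSE],
               genotype = cm$sample_meta$genotype[idx],
               replicate = cm$sample_meta$replicate[idx])
}
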