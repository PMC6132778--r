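#' Fragments per kilobase per million (FPKM)
#'
#' Converts raw counts to FPKM using supplied effective feature lengths:
#' \code{count / ((length/1e3) * (libsize/1e6))}. FPKM is used in this
#' workflow only as an expression filter (e.g. "expressed" at FPKM > 0.1),
#' never as the differential-expression statistic.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param eff_len_bp named numeric vector of effective lengths in bp; must
#'   cover every feature in \code{counts}.
#' @param libsizes per-sample library sizes (total mapped reads); defaults
#'   to column sums of the matrix.
#' @return An \code{expression_matrix}: numeric matrix with attribute
#'   \code{unit = "FPKM"} and the sample metadata carried along.
#' @export
compute_fpkm <- function(counts, eff_len_bp, libsizes = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  missing <- setdiff(rownames(m), names(eff_len_bp))
  if (length(missing) > 0)
    stop("missing effective length for feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  len <- eff_len_bp[rownames(m)]
  if (any(len <= 0)) stop("effective lengths must be positive")
  if (is.null(libsizes)) libsizes <- colSums(m)
  if (any(libsizes <= 0)) stop("library sizes must be positive")
  fpkm <- m / (len / 1e3)                      # per kilobase
  fpkm <- sweep(fpkm, 2, libsizes / 1e6, "/")  # per million mapped
  expression_matrix(fpkm, unit = "FPKM", sample_meta = counts$sample_meta)
}

#' Counts per million (CPM)
#'
#' \code{count * 1e6 / libsize}; the unit behind the "at least one read per
#' million" expression floor applied to miRNA counts.
#'
#' @inheritParams compute_fpkm
#' @return An \code{expression_matrix} with unit \code{"CPM"}.
#' @export
compute_cpm <- function(counts, libsizes = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (is.null(libsizes)) libsizes <- colSums(m)
  if (any(libsizes <= 0)) stop("library sizes must be positive (zero-libsize sample)")
  cpm <- sweep(m, 2, libsizes / 1e6, "/")
  expression_matrix(cpm, unit = "CPM", sample_meta = counts$sample_meta)
}

#' Full-quantile normalization
#'
#' Forces all samples to share the same count distribution: the value at
#' within-sample rank r is replaced by the mean over samples of the r-th
#' order statistics. Ties within a sample receive the mean of the reference
#' values assigned to their tied ranks, so the transform is deterministic.
#' After normalization the per-sample sorted vectors are identical.
#'
#' @param counts a \code{\link{count_matrix}} (or plain numeric matrix).
#' @return An \code{expression_matrix} with unit \code{"FQ"}.
#' @export
full_quantile_normalize <- function(counts) {
  meta <- NULL
  if (inherits(counts, "count_matrix")) {
    meta <- counts$sample_meta
    m <- counts$counts
  } else {
    m <- as.matrix(counts)
  }
  if (ncol(m) < 2) stop("full-quantile normalization requires >= 2 samples")
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    v <- ref[rank(x, ties.method = "first")]
    # tied input values share the mean of the reference values they received
    stats::ave(v, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  expression_matrix(out, unit = "FQ", sample_meta = meta)
}

#' Expression filter
#'
#' Features with value strictly greater than \code{threshold} in at least
#' \code{min_samples} samples. The strict inequality follows the printed
#' filters "FPKM > 0.1" and "FPKM > 1".
#'
#' @param expr an \code{expression_matrix} (or numeric matrix).
#' @param threshold non-negative expression cut-off.
#' @param min_samples minimum number of samples above threshold.
#' @return Character vector of passing feature ids.
#' @export
expression_filter <- function(expr, threshold, min_samples = 1L) {
  if (threshold < 0) stop("threshold must be non-negative")
  m <- unclass_expr(expr)
  if (min_samples > ncol(m)) stop("min_samples exceeds number of samples")
  keep <- rowSums(m > threshold) >= min_samples
  rownames(m)[keep]
}

expression_matrix <- function(values, unit, sample_meta = NULL) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  attr(values, "unit") <- unit
  attr(values, "sample_meta") <- sample_meta
  class(values) <- c("expression_matrix", class(values))
  values
}

unclass_expr <- function(x) {
  if (inherits(x, "expression_matrix")) {
    class(x) <- setdiff(class(x), "expression_matrix")
    attr(x, "unit") <- NULL
    attr(x, "sample_meta") <- NULL
  }
  as.matrix(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}
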