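#' 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (row 1 = a, b; row 2 = c, d).
#' @param rows,cols optional length-2 label vectors.
#' @return A \code{contingency_2x2} object (2x2 integer matrix with
#'   dimnames).
#' @export
contingency_2x2 <- function(a, b, c, d, rows = c("row1", "row2"),
                            cols = c("col1", "col2")) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("empty table (N = 0)")
  m <- matrix(as.numeric(cells), 2, 2, byrow = TRUE,
              dimnames = list(rows, cols))
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Closed-form Pearson statistic
#' \code{N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with 1 degree of freedom,
#' optionally with the Yates continuity correction. A zero marginal leaves
#' the statistic undefined; the test is then flagged and p reported as 1
#' with a warning.
#'
#' @param table a \code{\link{contingency_2x2}} (or plain 2x2 matrix).
#' @param yates_correction apply continuity correction (default FALSE).
#' @return list \code{statistic}, \code{pvalue}, \code{df = 1},
#'   \code{defined}.
#' @export
chi2_2x2 <- function(table, yates_correction = FALSE) {
  m <- unclass(table)
  stopifnot(all(dim(m) == c(2, 2)))
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    warning("zero marginal: chi-squared statistic undefined; p reported as 1")
    return(list(statistic = NA_real_, pvalue = 1, df = 1L, defined = FALSE))
  }
  num <- abs(a * d - b * c)
  if (yates_correction) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(marg)
  list(statistic = stat,
       pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, defined = TRUE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Small-count companion to \code{\link{chi2_2x2}}: conditioning on both
#' margins, the two-sided p-value sums the hypergeometric probabilities of
#' all tables (with the same margins) no more probable than the observed
#' one.
#'
#' @param table a \code{\link{contingency_2x2}} (or plain 2x2 matrix).
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  m <- unclass(table)
  stopifnot(all(dim(m) == c(2, 2)))
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) stop("empty table")
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Targeting enrichment between two contrast classes
#'
#' Builds the 2x2 table {class_a, class_b} x {targeted, not targeted} over a
#' contrast-class table and a set of miRNA-targeted genes, and applies the
#' chi-squared test. This is the comparison showing that gain-of-function
#' (HOMO-only) deregulated genes carry a higher fraction of anti-correlated
#' miRNA targets than the loss-of-function or shared classes.
#'
#' @param classes contrast-class data.frame (\code{table} element of
#'   \code{\link{classify_features}}).
#' @param targeted character vector of targeted gene ids (must be classified).
#' @param class_a,class_b class labels to compare.
#' @param yates_correction passed to \code{\link{chi2_2x2}}.
#' @return list \code{table} (\code{contingency_2x2}), \code{test}
#'   (\code{chi2_2x2} result), \code{flagged} (TRUE when a class is empty).
#' @export
targeting_contingency <- function(classes, targeted, class_a, class_b,
                                  yates_correction = FALSE) {
  if (!all(targeted %in% classes$feature_id))
    stop("targeted must be a subset of the classified universe")
  in_a <- classes$feature_id[classes$class == class_a]
  in_b <- classes$feature_id[classes$class == class_b]
  flagged <- length(in_a) == 0 || length(in_b) == 0
  ta <- sum(in_a %in% targeted); tb <- sum(in_b %in% targeted)
  tab <- contingency_2x2(
    ta, length(in_a) - ta, tb, length(in_b) - tb,
    rows = c(class_a, class_b), cols = c("targeted", "not_targeted")
  )
  list(table = tab, test = chi2_2x2(tab, yates_correction), flagged = flagged)
}

#' Both default pairwise targeting comparisons
#'
#' HOMO_only vs KO_only and HOMO_only vs shared, the two comparisons behind
#' the paired p-values reported for the targeting asymmetry.
#'
#' @inheritParams targeting_contingency
#' @return Named list of \code{\link{targeting_contingency}} results.
#' @export
targeting_contingency_pairs <- function(classes, targeted,
                                        yates_correction = FALSE) {
  list(
    HOMO_only_vs_KO_only = targeting_contingency(
      classes, targeted, "HOMO_only", "KO_only", yates_correction),
    HOMO_only_vs_shared = targeting_contingency(
      classes, targeted, "HOMO_only", "shared", yates_correction)
  )
}

#' CLIP-binding enrichment among targeted deregulated genes
#'
#' Within one condition's deregulated genes, builds the 2x2 table
#' {targeted, non-targeted} x {bound, unbound} (bound = 3'-UTR overlaps a
#' CLIP peak) and applies the chi-squared test — the per-condition analysis
#' showing that targeted deregulated mRNAs are preferentially bound in
#' their 3'-UTR in the mutant but not the knockout condition.
#'
#' @param deregulated character vector of deregulated gene ids (the
#'   universe for this condition).
#' @param targeted subset of \code{deregulated} with an anti-correlated
#'   miRNA edge.
#' @param bound character vector of CLIP-bound gene ids (may extend beyond
#'   \code{deregulated}).
#' @param yates_correction passed to \code{\link{chi2_2x2}}.
#' @return list \code{table}, \code{test}, \code{flagged}.
#' @export
binding_contingency <- function(deregulated, targeted, bound,
                                yates_correction = FALSE) {
  if (length(deregulated) == 0) stop("empty deregulated set")
  if (!all(targeted %in% deregulated))
    stop("targeted must be a subset of deregulated")
  nt <- setdiff(deregulated, targeted)
  a <- sum(targeted %in% bound); b <- length(targeted) - a
  c <- sum(nt %in% bound); d <- length(nt) - c
  flagged <- length(targeted) == 0 || length(nt) == 0
  tab <- contingency_2x2(a, b, c, d,
                         rows = c("targeted", "non_targeted"),
                         cols = c("bound", "unbound"))
  list(table = tab, test = chi2_2x2(tab, yates_correction), flagged = flagged)
}
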