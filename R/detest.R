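#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the geometric-mean reference feature, restricted to
#' features expressed in every sample, then rescaled so the factors have
#' geometric mean 1.
#'
#' @param counts a \code{\link{count_matrix}} or numeric matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (any(colSums(m) == 0)) stop("every sample needs at least one nonzero count")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("no feature expressed in all samples; filter low-count features first")
  logref <- rowMeans(log(m[all_pos, , drop = FALSE]))
  s <- apply(m[all_pos, , drop = FALSE], 2, function(x) {
    stats::median(exp(log(x) - logref))
  })
  s <- s / exp(mean(log(s)))
  s
}

#' Tagwise negative-binomial dispersion with shrinkage
#'
#' Method-of-moments tagwise dispersion per feature from within-group means
#' and variances (NB2 parameterization, variance = mu + phi * mu^2), shrunk
#' toward the common (all-feature) estimate and floored at \code{phi_floor}.
#' The shrinkage weight on the common value is
#' \code{w = n_features / (n_features + 20 * df)} where \code{df} is the
#' total within-group residual degrees of freedom, so small-replicate designs
#' lean heavily on the common dispersion.
#'
#' @param norm_counts numeric matrix of size-factor-normalized counts.
#' @param groups factor/character vector of group labels per column.
#' @param phi_floor minimum dispersion (default 1e-4).
#' @param common_prior dispersion used when no group has replicates
#'   (with a warning).
#' @return data.frame with columns \code{feature_id}, \code{phi},
#'   \code{phi_tagwise}, \code{phi_common}, \code{method}.
#' @export
estimate_dispersion <- function(norm_counts, groups, phi_floor = 1e-4,
                                common_prior = 0.1) {
  m <- as.matrix(norm_counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  glev <- unique(groups)
  nrep <- vapply(glev, function(g) sum(groups == g), integer(1))
  df <- sum(pmax(nrep - 1L, 0L))
  if (df == 0) {
    warning("single replicate everywhere; using common prior dispersion")
    return(data.frame(
      feature_id = rownames(m),
      phi = rep(max(common_prior, phi_floor), nrow(m)),
      phi_tagwise = NA_real_,
      phi_common = max(common_prior, phi_floor),
      method = "common",
      stringsAsFactors = FALSE
    ))
  }
  # pooled within-group moments
  mu_all <- rowMeans(m)
  ssq <- rep(0, nrow(m)); wsum <- 0; musq <- rep(0, nrow(m))
  for (g in glev) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    mu_g <- rowMeans(m[, idx, drop = FALSE])
    v_g <- apply(m[, idx, drop = FALSE], 1, stats::var)
    ssq <- ssq + (length(idx) - 1L) * v_g
    musq <- musq + (length(idx) - 1L) * mu_g^2
    wsum <- wsum + (length(idx) - 1L)
  }
  v_pool <- ssq / wsum
  musq_pool <- musq / wsum
  phi_tag <- (v_pool - mu_all) / pmax(musq_pool, .Machine$double.eps)
  phi_tag[!is.finite(phi_tag)] <- 0
  # common dispersion: moment estimate on the pooled (mean, var) cloud
  ok <- mu_all > 0
  phi_common <- sum(pmax(v_pool[ok] - mu_all[ok], 0)) /
    sum(musq_pool[ok])
  phi_common <- max(phi_common, phi_floor)
  w <- nrow(m) / (nrow(m) + 20 * df)
  phi <- pmax(w * phi_common + (1 - w) * phi_tag, phi_floor)
  data.frame(
    feature_id = rownames(m),
    phi = phi,
    phi_tagwise = pmax(phi_tag, phi_floor),
    phi_common = phi_common,
    method = ifelse(phi <= phi_floor, "floored", "tagwise"),
    stringsAsFactors = FALSE
  )
}

#' Conditional negative-binomial exact test
#'
#' Two-group exact test for count data conditioning on the pooled sum.
#' Counts are first brought to equal libraries (divided by size factors and
#' rounded half to even), group sums are formed, and under the null the
#' group-A sum given the total S follows the distribution proportional to
#' \code{dnbinom(a, size = nA/phi, mu = nA*mu) * dnbinom(S - a, ...)} with
#' \code{mu = S/(nA+nB)}. The two-sided p-value sums the conditional
#' probabilities of all splits no more probable than the observed one.
#' At \code{phi = 0} the kernel degenerates to Poisson and the test matches
#' the conditional binomial exact test.
#'
#' @param countsA,countsB numeric count vectors for the two groups (one
#'   entry per replicate).
#' @param phi NB dispersion (>= 0).
#' @param size_factors optional per-sample size factors, concatenated as
#'   \code{c(A, B)}; counts are divided by them before pseudo-count rounding.
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(countsA, countsB, phi, size_factors = NULL) {
  if (any(c(countsA, countsB) < 0)) stop("negative counts")
  if (phi < 0) stop("phi must be >= 0")
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == length(countsA) + length(countsB))
    sfA <- size_factors[seq_along(countsA)]
    sfB <- size_factors[length(countsA) + seq_along(countsB)]
    countsA <- round(countsA / sfA)  # round() is half-to-even
    countsB <- round(countsB / sfB)
  } else {
    countsA <- round(countsA)
    countsB <- round(countsB)
  }
  nA <- length(countsA); nB <- length(countsB)
  sA <- sum(countsA); sB <- sum(countsB)
  S <- sA + sB
  if (S == 0) return(1)
  mu <- S / (nA + nB)
  support <- 0:S
  if (S > 20000) {
    # negligible-tail window; total excluded mass < 1e-12
    lo <- min(conditional_window(nA, mu, phi), conditional_window(nB, mu, phi))
    hi <- max(conditional_window(nA, mu, phi, upper = TRUE),
              conditional_window(nB, mu, phi, upper = TRUE))
    support <- max(0, lo):min(S, max(hi, S - lo))
    support <- union(support, c(sA))
    support <- sort(unique(pmin(pmax(support, 0), S)))
  }
  logp <- cond_split_logprob(support, S, nA, nB, mu, phi)
  p_obs <- logp[match(sA, support)]
  tot <- logsumexp(logp)
  sel <- logp <= p_obs + 1e-10
  p <- exp(logsumexp(logp[sel]) - tot)
  min(max(p, .Machine$double.xmin), 1)
}

cond_split_logprob <- function(a, S, nA, nB, mu, phi) {
  if (phi <= 0) {
    stats::dpois(a, nA * mu, log = TRUE) + stats::dpois(S - a, nB * mu, log = TRUE)
  } else {
    stats::dnbinom(a, size = nA / phi, mu = nA * mu, log = TRUE) +
      stats::dnbinom(S - a, size = nB / phi, mu = nB * mu, log = TRUE)
  }
}

conditional_window <- function(n, mu, phi, upper = FALSE) {
  q <- if (upper) 1 - 1e-14 else 1e-14
  if (phi <= 0) stats::qpois(q, n * mu) else stats::qnbinom(q, size = n / phi, mu = n * mu)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Run differential expression for one contrast
#'
#' Full per-feature pipeline for a two-genotype contrast: median-of-ratios
#' size factors, tagwise shrunken dispersion, conditional NB exact test,
#' and Benjamini-Hochberg FDR across the tested features. The first
#' genotype of \code{contrast} is the numerator of the fold change and the
#' second (typically \code{"WT"}) the reference.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param contrast character pair \code{c(A, B)}; log2 fold change is A over B.
#' @param q_threshold FDR threshold for calling direction (default 0.05).
#' @param lfc_threshold minimum |log2FC| for calling direction (default 0;
#'   0.5 matches the candidate-selection filter used for validation picks).
#' @param features optional feature subset to test (ids); by default all.
#' @return data.frame of class \code{de_result}: \code{feature_id},
#'   \code{contrast}, \code{log2fc}, \code{pvalue}, \code{qvalue},
#'   \code{mean_expr}, \code{direction}.
#' @export
run_de <- function(counts, contrast, q_threshold = 0.05, lfc_threshold = 0,
                   features = NULL) {
  stopifnot(inherits(counts, "count_matrix"), length(contrast) == 2)
  geno <- counts$sample_meta$genotype
  for (g in contrast) {
    if (sum(geno == g) < 2)
      stop("contrast genotype absent or unreplicated: ", g)
  }
  idx <- which(geno %in% contrast)
  cm <- subset_samples(counts, idx)
  if (!is.null(features)) {
    cm$counts <- cm$counts[intersect(rownames(cm$counts), features), , drop = FALSE]
  }
  sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  grp <- cm$sample_meta$genotype
  disp <- estimate_dispersion(norm, grp)
  ia <- which(grp == contrast[1]); ib <- which(grp == contrast[2])
  pvals <- vapply(seq_len(nrow(cm$counts)), function(i) {
    nb_exact_test(cm$counts[i, ia], cm$counts[i, ib], disp$phi[i],
                  size_factors = sf[c(ia, ib)])
  }, numeric(1))
  prior <- 0.5
  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  lfc <- log2((mA + prior) / (mB + prior))
  qvals <- stats::p.adjust(pvals, method = "BH")
  sig <- qvals < q_threshold & abs(lfc) > lfc_threshold
  res <- data.frame(
    feature_id = rownames(cm$counts),
    contrast = paste(contrast, collapse = ":"),
    log2fc = lfc,
    pvalue = pvals,
    qvalue = qvals,
    mean_expr = rowMeans(norm),
    direction = ifelse(sig & lfc > 0, "up", ifelse(sig & lfc < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("de_result", class(res))
  res
}

#' Significant features of a DE table
#'
#' @param de a \code{de_result} table.
#' @param direction optionally restrict to \code{"up"} or \code{"down"}.
#' @return Character vector of feature ids with a called direction.
#' @export
de_significant <- function(de, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") de$direction != "none" else de$direction == direction
  de$feature_id[keep]
}
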