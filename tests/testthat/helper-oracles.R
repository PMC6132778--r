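# Independent oracle implementations used to validate the package's
# computations. These deliberately use different code paths (explicit
# loops, lgamma/lchoose arithmetic) from the implementation they check.

# conditional NB exact test by exhaustive enumeration of all splits of the
# pooled sum, NB pmf written out via lgamma
oracle_exact_test_enum <- function(countsA, countsB, phi) {
  nA <- length(countsA); nB <- length(countsB)
  S <- sum(countsA) + sum(countsB)
  if (S == 0) return(1)
  mu <- S / (nA + nB)
  lp <- vapply(0:S, function(a) {
    nb_lpmf_group(a, nA, mu, phi) + nb_lpmf_group(S - a, nB, mu, phi)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[sum(countsA) + 1]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

nb_lpmf_group <- function(x, n, mu, phi) {
  if (phi <= 0) return(stats::dpois(x, n * mu, log = TRUE))
  r <- n / phi
  m <- n * mu
  lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    r * log(r / (r + m)) + x * log(m / (r + m))
}

# conditional binomial exact test (Poisson limit)
oracle_binomial_test <- function(countsA, countsB) {
  nA <- length(countsA); nB <- length(countsB)
  S <- sum(countsA) + sum(countsB)
  if (S == 0) return(1)
  pr <- stats::dbinom(0:S, S, nA / (nA + nB))
  obs <- pr[sum(countsA) + 1]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# sliding-window canonical seed-site scan, strongest class per core match
oracle_seed_scan <- function(utr, mirna_id, mirna_seq) {
  norm <- function(s) chartr("U", "T", toupper(s))
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  utr <- norm(utr); m <- norm(mirna_seq)
  core <- rc(substr(m, 2, 7))
  m8 <- rc(substr(m, 8, 8))
  res <- NULL
  n <- nchar(utr)
  for (s in seq_len(max(0, n - 5))) {
    if (substr(utr, s, s + 5) != core) next
    has_m8 <- s > 1 && substr(utr, s - 1, s - 1) == m8
    has_a1 <- s + 6 <= n && substr(utr, s + 6, s + 6) == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
    else if (has_a1) "7mer-A1" else "6mer"
    st <- if (has_m8) s - 1L else s
    en <- if (has_a1) s + 6L else s + 5L
    res <- rbind(res, data.frame(mirna_id = mirna_id, site_class = cls,
                                 start = st, end = en,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(res))
    res <- data.frame(mirna_id = character(0), site_class = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  res
}

# all-pairs interval overlap (BED half-open)
oracle_overlap <- function(utrs, peaks, min_overlap = 1, same_strand = TRUE) {
  bound <- character(0)
  for (i in seq_len(nrow(utrs))) {
    for (j in seq_len(nrow(peaks))) {
      if (utrs$chrom[i] != peaks$chrom[j]) next
      if (same_strand && utrs$strand[i] != peaks$strand[j]) next
      ov <- min(utrs$end[i], peaks$end[j]) - max(utrs$start[i], peaks$start[j])
      if (ov >= min_overlap) bound <- c(bound, utrs$gene_id[i])
    }
  }
  sort(unique(bound))
}

# triple-loop anti-correlation join
oracle_network_edges <- function(de_genes, de_mirnas, predictions, min_score) {
  keep <- logical(nrow(predictions))
  for (k in seq_len(nrow(predictions))) {
    g <- predictions$gene_id[k]; m <- predictions$mirna_id[k]
    ig <- which(de_genes$feature_id == g)
    im <- which(de_mirnas$feature_id == m)
    if (length(ig) == 0 || length(im) == 0) next
    dg <- de_genes$direction[ig]; dm <- de_mirnas$direction[im]
    keep[k] <- predictions$score[k] >= min_score &&
      dg != "none" && dm != "none" && dg != dm
  }
  e <- predictions[keep, c("mirna_id", "gene_id", "score")]
  e[order(e$mirna_id, e$gene_id), , drop = FALSE]
}

# two-sided Fisher p by explicit table enumeration with lchoose
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(xs, lp, numeric(1)))
  obs <- exp(lp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small random DE-result-like table over a shared feature universe
random_de_table <- function(features, contrast = "HOMO:WT", p_sig = 0.3) {
  dir <- sample(c("up", "down", "none"), length(features), replace = TRUE,
                prob = c(p_sig / 2, p_sig / 2, 1 - p_sig))
  data.frame(feature_id = features, contrast = contrast,
             log2fc = ifelse(dir == "up", 1, ifelse(dir == "down", -1, 0)),
             pvalue = stats::runif(length(features)),
             qvalue = stats::runif(length(features)),
             mean_expr = 10, direction = dir, stringsAsFactors = FALSE)
}

# NB count_matrix with two groups and optional planted fold changes
sim_two_group_counts <- function(n_features, n_per_group = 3, phi = 0.1,
                                 mean_range = c(20, 500), lfc = NULL,
                                 groups = c("A", "B")) {
  mu <- exp(stats::runif(n_features, log(mean_range[1]), log(mean_range[2])))
  fc <- rep(1, n_features)
  if (!is.null(lfc)) fc <- 2^lfc
  m <- cbind(
    matrix(stats::rnbinom(n_features * n_per_group, mu = mu, size = 1 / phi),
           n_features),
    matrix(stats::rnbinom(n_features * n_per_group, mu = mu * fc, size = 1 / phi),
           n_features)
  )
  dimnames(m) <- list(sprintf("f%04d", seq_len(n_features)),
                      paste0(rep(groups, each = n_per_group), "_",
                             seq_len(n_per_group)))
  count_matrix(m, genotype = rep(groups, each = n_per_group))
}
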