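cm3 <- function(m, geno = c("A", "A", "B")) {
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  count_matrix(m, genotype = geno[seq_len(ncol(m))])
}

unclass_mat <- function(x) {
  attributes(x)[c("unit", "sample_meta")] <- NULL
  class(x) <- NULL
  x
}

test_that("FPKM follows count / ((len/1e3) * (libsize/1e6))", {
  cm <- cm3(matrix(c(10, 0, 20), 3, 1), geno = "A")
  lens <- c(g1 = 1000, g2 = 500, g3 = 2000)
  f <- compute_fpkm(cm, lens, libsizes = 1e6)
  expect_equal(unname(f[, 1]), c(10, 0, 10))
  f2 <- compute_fpkm(cm3(matrix(20, 1, 1), "A"), c(g1 = 2000), libsizes = 2e6)
  expect_equal(unname(f2[1, 1]), 5)
  expect_equal(attr(f, "unit"), "FPKM")
  expect_error(compute_fpkm(cm, lens[1:2]), "g3")
})

test_that("CPM scales counts to per-million and rejects zero library", {
  cm <- cm3(matrix(c(1, 5), 2, 1), "A")
  expect_equal(unname(compute_cpm(cm, libsizes = 1e6)[, 1]), c(1, 5))
  expect_equal(unname(compute_cpm(cm, libsizes = 5e5)[, 1]), c(2, 10))
  z <- cm3(matrix(0, 2, 2), c("A", "B"))
  expect_error(compute_cpm(z), "zero-libsize")
})

test_that("FPKM and CPM are linear in counts, inverse-linear in libsize", {
  set.seed(11)
  m <- matrix(rpois(60, 50), 10, 6)
  cm <- cm3(m, rep(c("A", "B"), each = 3))
  lens <- setNames(runif(10, 300, 3000), rownames(cm$counts))
  L <- runif(6, 1e6, 2e6)
  f1 <- compute_fpkm(cm, lens, L)
  f2 <- compute_fpkm(cm3(2 * m, rep(c("A", "B"), each = 3)), lens, L)
  expect_equal(unclass_mat(f2), 2 * unclass_mat(f1))
  f3 <- compute_fpkm(cm, lens, 2 * L)
  expect_equal(unclass_mat(f3), unclass_mat(f1) / 2)
})

test_that("full-quantile normalization matches the hand rank-mean oracle", {
  # identical columns are a fixed point
  m <- matrix(c(3, 1, 2), 3, 4)
  cm <- cm3(m, c("A", "A", "B", "B"))
  expect_equal(unclass_mat(full_quantile_normalize(cm)), unname(m),
               ignore_attr = TRUE)
  # (1,2,3) and (4,5,6) -> both (2.5, 3.5, 4.5)
  m2 <- cm3(cbind(1:3, 4:6), c("A", "B"))
  fq <- full_quantile_normalize(m2)
  expect_equal(unname(fq[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(fq[, 2]), c(2.5, 3.5, 4.5))
  # tie rule: tied entries receive the mean of the values at their ranks
  m3 <- cm3(cbind(c(1, 1, 3), c(2, 4, 6)), c("A", "B"))
  fq3 <- full_quantile_normalize(m3)
  # sorted references: rowMeans of (1,1,3) and (2,4,6) = (1.5, 2.5, 4.5)
  expect_equal(unname(fq3[, 1]), c(2, 2, 4.5))
  expect_equal(unname(fq3[, 2]), c(1.5, 2.5, 4.5))
  expect_error(full_quantile_normalize(cm3(matrix(1:3, 3, 1), "A")),
               ">= 2 samples")
})

test_that("full-quantile output has identical sorted columns, equal sums, preserved order", {
  set.seed(5)
  for (i in 1:10) {
    # tie-free columns: each sample becomes an exact permutation of the
    # rank-wise reference, so sorted columns coincide exactly
    m <- matrix(rnbinom(300, mu = 50, size = 2) + runif(300), 50, 6,
                dimnames = list(sprintf("f%02d", 1:50), NULL))
    fq <- full_quantile_normalize(m)
    sorted <- apply(fq, 2, sort)
    for (j in 2:6) expect_identical(sorted[, j], sorted[, 1])
    expect_equal(max(colSums(fq)) - min(colSums(fq)), 0)
    # tied integer counts: tie groups collapse to their mean, which still
    # preserves per-sample sums and within-sample order
    mt <- matrix(rnbinom(300, mu = 5, size = 1), 50, 6)
    fqt <- full_quantile_normalize(cm3(mt, rep(c("A", "B"), each = 3)))
    expect_equal(max(colSums(fqt)) - min(colSums(fqt)), 0, tolerance = 1e-9)
    for (j in 1:6) {
      expect_true(all(diff(fqt[order(mt[, j]), j]) >= -1e-12))
    }
  }
})

test_that("full-quantile agrees with limma's implementation on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(9)
  m <- matrix(rnbinom(600, mu = 30, size = 1) + runif(600), 100, 6)
  fq <- unclass_mat(full_quantile_normalize(m))
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(fq), unname(ref), tolerance = 1e-12)
})

test_that("expression filter is strict and matches the brute-force oracle", {
  m <- rbind(a = c(0.1, 0.1, 0.1), b = c(0.2, 0, 0))
  expect_identical(expression_filter(m, 0.1, 1), "b")  # 0.1 excluded, strict
  m2 <- rbind(x = c(2, 2, 2, 0, 0, 0), y = c(2, 2, 0, 0, 0, 0))
  expect_identical(expression_filter(m2, 1, 3), "x")
  expect_error(expression_filter(m, -1, 1), "non-negative")
  set.seed(3)
  r <- matrix(runif(300, 0, 3), 50, 6,
              dimnames = list(sprintf("f%02d", 1:50), NULL))
  for (thr in c(0.1, 1)) {
    for (ms in c(1, 3, 6)) {
      brute <- rownames(r)[vapply(seq_len(50), function(i) {
        n <- 0
        for (j in 1:6) if (r[i, j] > thr) n <- n + 1
        n >= ms
      }, logical(1))]
      expect_identical(expression_filter(r, thr, ms), brute)
    }
  }
})
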