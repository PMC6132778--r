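small_params <- function(seed = 1, ...) {
  sim_params(seed = seed, n_genes = 300, n_mirnas = 80, locus_size = 10, ...)
}

test_that("parameter validation guards the generator contracts", {
  expect_error(sim_params(frac_de_ko_only = 0.6, frac_de_shared = 0.3,
                          frac_de_homo_only = 0.2), "sum")
  expect_error(sim_params(genotypes = c("HOMO", "KO")), "WT")
  expect_error(sim_params(n_genes = -1), ">= 0")
  expect_error(sim_params(n_reps = 1), "n_reps")
  expect_error(sim_params(pred_score_range = c(0.9, 0.1)), "pred_score_range")
})

test_that("empty and deterministic generation contracts hold", {
  p0 <- sim_params(seed = 3, n_genes = 0, n_mirnas = 0)
  ds0 <- simulate_dataset(p0)
  expect_equal(nrow(ds0$gene_counts$counts), 0)
  expect_equal(nrow(ds0$truth$gene_table), 0)
  expect_equal(nrow(ds0$truth$planted_edges), 0)
  p <- small_params(seed = 11)
  expect_identical(simulate_dataset(p), simulate_dataset(p))
  # different seeds differ
  expect_false(identical(simulate_dataset(small_params(1))$gene_counts$counts,
                         simulate_dataset(small_params(2))$gene_counts$counts))
})

test_that("planted class sizes follow the requested fractions exactly", {
  p <- sim_params(seed = 5, n_genes = 2000, n_mirnas = 0,
                  frac_de_homo_only = 0.10)
  tr <- simulate_dataset(p)$truth$gene_table
  expect_equal(sum(tr$class == "HOMO_only"), 200)
  expect_equal(sum(tr$class == "KO_only"), round(0.015 * 2000))
  expect_false(anyDuplicated(tr$feature_id) > 0)
  # class sets disjoint by construction; planted scores within range
  p2 <- small_params(seed = 6)
  tru <- simulate_dataset(p2)$truth
  expect_true(all(tru$planted_edges$score >= 0.7 & tru$planted_edges$score <= 1))
  expect_true(all(tru$bound_genes %in%
                    sprintf("gene_%05d", seq_len(p2$n_genes))))
})

genotype_cols <- function(cm, g) which(cm$sample_meta$genotype == g)

test_that("a planted +1 log2 fold change doubles the affected genotype mean", {
  ratios <- vapply(1:50, function(s) {
    p <- sim_params(seed = 100 + s, n_genes = 60, n_mirnas = 0,
                    lfc_magnitude = 1, frac_up = 1,
                    frac_de_ko_only = 0, frac_de_shared = 0,
                    frac_de_homo_only = 0.2)
    ds <- simulate_dataset(p)
    g <- ds$truth$gene_table$feature_id[1]
    cm <- ds$gene_counts
    mean(cm$counts[g, genotype_cols(cm, "HOMO")]) /
      mean(cm$counts[g, genotype_cols(cm, "WT")])
  }, numeric(1))
  expect_gte(mean(ratios), 1.6)
  expect_lte(mean(ratios), 2.5)
})

test_that("null features show the NB mean-variance relationship", {
  p <- sim_params(seed = 7, n_genes = 1500, n_mirnas = 0,
                  frac_de_ko_only = 0, frac_de_shared = 0,
                  frac_de_homo_only = 0, dispersion_shape = 0.15)
  ds <- simulate_dataset(p)
  m <- ds$gene_counts$counts
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  phi_hat <- (v - mu) / mu^2
  # median of the moment estimates tracks the median planted dispersion
  expect_gte(median(phi_hat), 0.5 * 0.15)
  expect_lte(median(phi_hat), 2 * 0.15)
  expect_gte(mean(v > mu), 0.9)  # overdispersed throughout
})

test_that("locus structure and binding asymmetry match their targets", {
  p <- sim_params(seed = 8, n_genes = 3000, n_mirnas = 2000,
                  locus_size = 180, frac_locus_in_up = 0.9,
                  frac_targeted = 0.5)
  ds <- simulate_dataset(p)
  tr <- ds$truth
  up_both <- tr$mirna_table$feature_id[tr$mirna_table$class == "shared" &
                                         tr$mirna_table$direction == "up"]
  expect_equal(length(tr$locus_members), 180)
  f <- sum(up_both %in% tr$locus_members) / length(up_both)
  expect_equal(f, 0.9, tolerance = 0.01)
  expect_true(all(tr$locus_members %in% up_both))  # completeness by construction
  # P(bound | targeted) / P(bound | untargeted) ~ 3
  genes <- sprintf("gene_%05d", seq_len(p$n_genes))
  targeted <- tr$targeted_genes
  pt <- mean(targeted %in% tr$bound_genes)
  pu <- mean(setdiff(genes, targeted) %in% tr$bound_genes)
  expect_gte(pt / pu, 2.3)
  expect_lte(pt / pu, 3.8)
  # locus members sit consecutively on one chromosome
  ann <- ds$mirna_anno[ds$mirna_anno$mirna_id %in% tr$locus_members, ]
  expect_equal(unique(ann$chrom), "chr12")
})

test_that("datasets round-trip losslessly through the writers and readers", {
  p <- small_params(seed = 9)
  ds <- simulate_dataset(p)
  dir <- file.path(tempdir(), "mircross-roundtrip")
  unlink(dir, recursive = TRUE)
  paths <- write_dataset(ds, dir)
  expect_error(write_dataset(ds, dir), "overwrite")
  back <- read_dataset(dir)
  expect_equal(back$gene_counts$counts, ds$gene_counts$counts)
  expect_equal(back$mirna_counts$counts, ds$mirna_counts$counts)
  expect_equal(back$predictions$score, ds$predictions$score, tolerance = 1e-12)
  expect_identical(back$utr_seqs, ds$utr_seqs)
  expect_identical(back$mirna_seqs, ds$mirna_seqs)
  expect_equal(back$utrs[, c("chrom", "start", "end", "gene_id")],
               ds$utrs[, c("chrom", "start", "end", "gene_id")])
  # FASTA headers match annotation ids
  expect_identical(names(back$utr_seqs), ds$gene_anno$gene_id)
  # BED is 0-based half-open: a length-1 interval at the first base
  bed <- tempfile(fileext = ".bed")
  df <- data.frame(chrom = "chr1", start = 0L, end = 1L, strand = "+",
                   gene_id = "g1")
  mircross:::write_bed6(df, df$gene_id, bed)
  expect_equal(readLines(bed), "chr1\t0\t1\tg1\t0\t+")
  unlink(dir, recursive = TRUE)
})
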