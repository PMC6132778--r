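toy_de <- function(ids, dirs, contrast = "HOMO:WT") {
  data.frame(feature_id = ids, contrast = contrast,
             log2fc = ifelse(dirs == "up", 1, ifelse(dirs == "down", -1, 0)),
             pvalue = 0.01, qvalue = 0.01, mean_expr = 10,
             direction = dirs, stringsAsFactors = FALSE)
}

test_that("network keeps anti-correlated pairs at score >= 0.7 inclusive", {
  dg <- toy_de(c("g1", "g2"), c("down", "up"))
  dm <- toy_de(c("m1", "m2"), c("up", "none"))
  pred <- data.frame(
    mirna_id = c("m1", "m1", "m2"), gene_id = c("g1", "g2", "g1"),
    score = c(0.7, 0.9, 0.95), stringsAsFactors = FALSE)
  net <- build_network(dg, dm, pred)
  expect_equal(net$edges$gene_id, "g1")       # exactly the 0.7 edge survives
  expect_equal(net$edges$pattern, "up-miR/down-gene")
  below <- pred; below$score[1] <- 0.699
  expect_equal(nrow(build_network(dg, dm, below)$edges), 0)
  # no significant miRNAs -> empty network
  dm0 <- toy_de(c("m1", "m2"), c("none", "none"))
  expect_equal(nrow(build_network(dg, dm0, pred)$edges), 0)
  # unknown features warn and are dropped, counted
  predu <- rbind(pred, data.frame(mirna_id = "mX", gene_id = "g1", score = 0.8))
  expect_warning(netu <- build_network(dg, dm, predu), "unknown")
  expect_equal(netu$n_dropped_predictions, 1L)
})

test_that("edge set equals the triple-loop brute force and is order-invariant", {
  set.seed(71)
  for (i in 1:10) {
    genes <- sprintf("g%02d", 1:20); mirs <- sprintf("m%02d", 1:8)
    dg <- random_de_table(genes)
    dm <- random_de_table(mirs)
    pred <- expand.grid(mirna_id = mirs, gene_id = genes,
                        stringsAsFactors = FALSE)
    pred <- pred[sample(nrow(pred), 60), ]
    pred$score <- runif(60)
    net <- build_network(dg, dm, pred, min_score = 0.5)
    oracle <- oracle_network_edges(dg, dm, pred, 0.5)
    expect_equal(net$edges[, c("mirna_id", "gene_id", "score")], oracle,
                 ignore_attr = TRUE)
    shuf <- pred[sample(nrow(pred)), ]
    net2 <- build_network(dg, dm, shuf, min_score = 0.5)
    expect_equal(net2$edges, net$edges)
    # raising min_score never adds edges
    net_hi <- build_network(dg, dm, pred, min_score = 0.8)
    expect_true(all(paste(net_hi$edges$mirna_id, net_hi$edges$gene_id) %in%
                      paste(net$edges$mirna_id, net$edges$gene_id)))
  }
})

test_that("pattern labels are consistent with node directions", {
  set.seed(72)
  dg <- random_de_table(sprintf("g%02d", 1:30))
  dm <- random_de_table(sprintf("m%02d", 1:10))
  pred <- data.frame(mirna_id = sample(dm$feature_id, 50, replace = TRUE),
                     gene_id = sample(dg$feature_id, 50, replace = TRUE),
                     score = runif(50))
  pred <- pred[!duplicated(pred[, 1:2]), ]
  net <- build_network(dg, dm, pred, min_score = 0)
  for (k in seq_len(nrow(net$edges))) {
    dmk <- dm$direction[dm$feature_id == net$edges$mirna_id[k]]
    dgk <- dg$direction[dg$feature_id == net$edges$gene_id[k]]
    expect_equal(net$edges$pattern[k],
                 if (dmk == "up") "up-miR/down-gene" else "down-miR/up-gene")
    expect_true(dmk != dgk && dmk != "none" && dgk != "none")
  }
})

test_that("UTR/peak intersection honors half-open coordinates and strand", {
  utr <- data.frame(chrom = "chr1", start = c(50, 0), end = c(200, 100),
                    strand = "+", gene_id = c("gA", "gB"))
  pk_in <- data.frame(chrom = "chr1", start = 100, end = 150, strand = "+")
  expect_setequal(intersect_utr_peaks(utr[1, ], pk_in), "gA")
  # half-open adjacency: [0,100) vs [100,150) do not touch
  expect_equal(intersect_utr_peaks(utr[2, ], pk_in), character(0))
  pk_rev <- transform(pk_in, strand = "-")
  expect_equal(intersect_utr_peaks(utr[1, ], pk_rev), character(0))
  expect_setequal(intersect_utr_peaks(utr[1, ], pk_rev, same_strand = FALSE), "gA")
  bad <- data.frame(chrom = "chr1", start = 10, end = 10, strand = "+",
                    gene_id = "gX")
  expect_error(intersect_utr_peaks(bad, pk_in), "malformed")
})

test_that("intersection equals all-pairs brute force on random intervals", {
  set.seed(73)
  utr <- data.frame(
    chrom = sample(c("chr1", "chr2"), 200, TRUE),
    start = sample(0:5000, 200, TRUE), strand = sample(c("+", "-"), 200, TRUE),
    gene_id = sprintf("g%03d", 1:200))
  utr$end <- utr$start + sample(10:300, 200, TRUE)
  pk <- data.frame(
    chrom = sample(c("chr1", "chr2"), 150, TRUE),
    start = sample(0:5000, 150, TRUE), strand = sample(c("+", "-"), 150, TRUE))
  pk$end <- pk$start + sample(5:200, 150, TRUE)
  for (mo in c(1, 25)) {
    for (ss in c(TRUE, FALSE)) {
      expect_identical(intersect_utr_peaks(utr, pk, mo, ss),
                       oracle_overlap(utr, pk, mo, ss))
    }
  }
})

test_that("network export round-trips and carries node attributes", {
  set.seed(74)
  dg <- random_de_table(sprintf("g%02d", 1:15))
  dm <- random_de_table(sprintf("m%02d", 1:5))
  pred <- expand.grid(mirna_id = dm$feature_id, gene_id = dg$feature_id,
                      stringsAsFactors = FALSE)
  pred$score <- runif(nrow(pred))
  net <- build_network(dg, dm, pred, min_score = 0.3)
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read_network_edges(tsv)
  expect_equal(back$mirna_id, net$edges$mirna_id)
  expect_equal(back$score, net$edges$score, tolerance = 1e-9)
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml",
                 bound_genes = dg$feature_id[1],
                 gene_class = c(g02 = "HOMO_only"))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$mirna_nodes) + nrow(net$gene_nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  # empty network still exports a valid zero-edge file
  net0 <- build_network(toy_de("g1", "none"), toy_de("m1", "none"),
                        data.frame(mirna_id = "m1", gene_id = "g1", score = 1))
  export_network(net0, tsv, "tsv")
  expect_equal(nrow(read_network_edges(tsv)), 0)
  expect_error(export_network(net, tsv, "dot"), "arg")
})

test_that("planted targeted-down genes are recovered from strong simulations", {
  p <- sim_params(seed = 75, n_genes = 1500, n_mirnas = 300,
                  dispersion_shape = 0.05, lfc_magnitude = 4,
                  frac_up = 0.2, frac_targeted = 0.8)
  ds <- simulate_dataset(p)
  dg <- run_de(ds$gene_counts, c("HOMO", "WT"))
  dm <- run_de(ds$mirna_counts, c("HOMO", "WT"))
  net <- build_network(dg, dm, ds$predictions)
  recovered <- unique(net$edges$gene_id[net$edges$pattern == "up-miR/down-gene"])
  tr <- ds$truth
  planted_homo <- tr$planted_edges$gene_id[
    tr$planted_edges$gene_id %in% tr$gene_table$feature_id[
      tr$gene_table$class %in% c("shared", "HOMO_only")]]
  expect_gte(length(intersect(recovered, planted_homo)) /
               max(1, length(recovered)), 0.8)
  expect_gte(length(intersect(recovered, planted_homo)) /
               max(1, length(planted_homo)), 0.8)
})
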