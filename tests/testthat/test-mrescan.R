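let7 <- c(let7 = "UGAGGUAGUAGGUUGUAUAGUU")

test_that("scanner finds the canonical let-7 8mer and classifies it", {
  expect_equal(nrow(scan_seed_sites("", let7)), 0)
  hits <- scan_seed_sites("AAACTACCTCAAAA", let7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_class, "8mer")
  expect_equal(hits$site_seq, "CTACCTCA")
  expect_equal(c(hits$start, hits$end), c(4L, 11L))
  # dropping the A1 adenine demotes the site to 7mer-m8
  h7 <- scan_seed_sites("AAACTACCTCTTTT", let7)
  expect_equal(h7$site_class, "7mer-m8")
  # class filter
  expect_equal(nrow(scan_seed_sites("AAACTACCTCAAAA", let7, classes = "6mer")), 0)
  # TSS-relative reporting
  ho <- scan_seed_sites("AAACTACCTCAAAA", let7, tss_offset = 1000)
  expect_equal(ho$start_tss, 1004L)
  expect_error(scan_seed_sites("ACGTN", let7), "offset 5")
  expect_error(scan_seed_sites("ACGT", c(x = "ACGU")), "shorter")
})

test_that("scanner equals the sliding-window oracle on random UTRs", {
  set.seed(91)
  mirs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""), character(1))
  names(mirs) <- sprintf("mir%d", 1:5)
  for (i in 1:50) {
    utr <- paste(sample(c("A", "C", "G", "T"), sample(50:300, 1), TRUE),
                 collapse = "")
    # embed a site for one miRNA half the time so hits are not vanishing
    if (i %% 2 == 0) {
      m <- chartr("U", "T", mirs[[1]])
      site <- paste0(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(m, 2, 8)))), "A")
      pos <- sample(nchar(utr) - 8, 1)
      substr(utr, pos, pos + 7) <- site
    }
    got <- scan_seed_sites(utr, mirs)[, c("mirna_id", "site_class", "start", "end")]
    want <- do.call(rbind, lapply(names(mirs), function(id)
      oracle_seed_scan(utr, id, mirs[[id]])))
    want <- want[order(want$start, want$mirna_id), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("scanner is idempotent and invariant to miRNA order", {
  set.seed(92)
  mirs <- c(a = "UGAGGUAGUAGGUUGUAUAGUU", b = "UUCAAGUAAUCCAGGAUAGGCU")
  utr <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  h1 <- scan_seed_sites(utr, mirs)
  h2 <- scan_seed_sites(utr, rev(mirs))
  ord <- function(d) {
    d <- d[order(d$mirna_id, d$start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(h1), ord(h2))
  expect_equal(scan_seed_sites(utr, mirs), h1)
  # reverse-complementing the core span reproduces seed positions 2-7
  for (k in seq_len(nrow(h1))) {
    core_start <- if (h1$site_class[k] %in% c("8mer", "7mer-m8"))
      h1$start[k] + 1L else h1$start[k]
    core <- substr(utr, core_start, core_start + 5L)
    seed27 <- chartr("U", "T", substr(mirs[[h1$mirna_id[k]]], 2, 7))
    expect_equal(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(core))), seed27)
  }
})

test_that("mutating a site removes it and leaves the rest untouched", {
  utr <- "GGGCTACCTCAGGGGGGGGGGGGGGGGGG"
  hits <- scan_seed_sites(utr, let7)
  expect_equal(nrow(hits), 1)
  mut <- mutate_mres(utr, hits, let7)
  expect_equal(nrow(scan_seed_sites(mut$sequence, let7)), 0)
  expect_equal(nchar(mut$sequence), nchar(utr))
  expect_equal(nrow(mut$changes), 3)
  # all non-site positions identical
  touched <- mut$changes$position
  same <- setdiff(seq_len(nchar(utr)), touched)
  expect_equal(strsplit(mut$sequence, "")[[1]][same],
               strsplit(utr, "")[[1]][same])
  # empty selection is the identity
  id <- mutate_mres(utr, hits[0, ], let7)
  expect_equal(id$sequence, utr)
})

test_that("double mutants clear both miRNAs; disjoint sites are preserved", {
  set.seed(93)
  mirs <- c(a = "UGAGGUAGUAGGUUGUAUAGUU", b = "UUCAAGUAAUCCAGGAUAGGCU")
  mk_site <- function(m) paste0(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", substr(m, 2, 8))))), "A")
  utr <- paste0(
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), mk_site(mirs["a"]),
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""), mk_site(mirs["b"]),
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
  base <- scan_seed_sites(utr, mirs)
  expect_true(all(c("a", "b") %in% base$mirna_id))
  # mutate only a's sites: b's disjoint site list must be unchanged
  mut_a <- mutate_mres(utr, base[base$mirna_id == "a", ], mirs)
  after <- scan_seed_sites(mut_a$sequence, mirs)
  expect_equal(nrow(after[after$mirna_id == "a", ]), 0)
  expect_equal(after[after$mirna_id == "b", ], base[base$mirna_id == "b", ],
               ignore_attr = TRUE)
  # double mutant clears both
  mut_ab <- mutate_mres(utr, base, mirs)
  expect_equal(nrow(scan_seed_sites(mut_ab$sequence, mirs)), 0)
})
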