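#' Canonical miRNA seed-match site classes
#'
#' The scanner reports the four canonical site classes defined by which
#' seed positions (miRNA nucleotides 2-8) pair with the UTR and whether an
#' adenine faces miRNA position 1:
#' \itemize{
#'   \item \code{6mer}: Watson-Crick match to seed positions 2-7;
#'   \item \code{7mer-m8}: match to positions 2-8;
#'   \item \code{7mer-A1}: match to 2-7 plus an A opposite position 1;
#'   \item \code{8mer}: match to 2-8 plus an A opposite position 1.
#' }
#' The A opposite position 1 is required to be an adenine in the UTR
#' regardless of the identity of miRNA position 1 (the A1 convention).
#' @name seed_site_classes
#' @keywords internal
NULL

SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

# Normalize a nucleotide string to DNA uppercase; reject invalid characters
# reporting the first bad offset.
normalize_seq <- function(seq, what = "sequence") {
  s <- toupper(as.character(seq))
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0)
    stop("invalid character in ", what, " at offset ", bad)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a 3'-UTR for canonical miRNA seed-match sites (MREs)
#'
#' Finds all occurrences of each miRNA's seed-complementary site on a UTR
#' sequence and classifies each occurrence into the strongest applicable
#' canonical class (8mer > 7mer-m8 > 7mer-A1 > 6mer). Coordinates are
#' 1-based inclusive on the UTR; when \code{tss_offset} is given (the UTR
#' start position relative to the transcription start site), positions are
#' additionally reported TSS-relative.
#'
#' @param utr_seq UTR sequence, DNA or RNA (T/U interchangeable), 5'-3'.
#' @param mirnas named character vector of miRNA sequences (RNA or DNA,
#'   5'-3', length >= 8), names = miRNA ids; or a data.frame with columns
#'   \code{mirna_id}, \code{sequence}.
#' @param classes site classes to report (default all four).
#' @param tss_offset optional integer added to positions for TSS-relative
#'   reporting (columns \code{start_tss}, \code{end_tss}).
#' @return data.frame: \code{mirna_id}, \code{site_class}, \code{start},
#'   \code{end}, \code{site_seq} (and TSS columns when offset supplied),
#'   sorted by position then miRNA id.
#' @export
scan_seed_sites <- function(utr_seq, mirnas, classes = SITE_CLASSES,
                            tss_offset = NULL) {
  classes <- match.arg(classes, SITE_CLASSES, several.ok = TRUE)
  utr <- normalize_seq(utr_seq, "UTR")
  mir <- as_mirna_vector(mirnas)
  out <- list()
  for (id in names(mir)) {
    m <- normalize_seq(mir[[id]], paste0("miRNA ", id))
    if (nchar(m) < 8) stop("miRNA ", id, " shorter than 8 nt")
    core6 <- revcomp(substr(m, 2, 7))   # site match to seed positions 2-7
    m8 <- revcomp(substr(m, 8, 8))      # base pairing miRNA position 8
    hits <- all_occurrences(utr, core6)
    for (s in hits) {
      # site layout 5'-3' on the UTR: [m8][core6][A1]
      has_m8 <- s > 1 && substr(utr, s - 1, s - 1) == m8
      has_a1 <- s + 6 <= nchar(utr) && substr(utr, s + 6, s + 6) == "A"
      cls <- if (has_m8 && has_a1) "8mer"
      else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1"
      else "6mer"
      if (!cls %in% classes) next
      st <- if (has_m8) s - 1L else s
      en <- if (has_a1) s + 6L else s + 5L
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = id, site_class = cls, start = st, end = en,
        site_seq = substr(utr, st, en), stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out) == 0) {
    data.frame(mirna_id = character(0), site_class = character(0),
               start = integer(0), end = integer(0),
               site_seq = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  res <- res[order(res$start, res$mirna_id), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(tss_offset)) {
    res$start_tss <- res$start + as.integer(tss_offset)
    res$end_tss <- res$end + as.integer(tss_offset)
  }
  res
}

as_mirna_vector <- function(mirnas) {
  if (is.data.frame(mirnas)) {
    stopifnot(all(c("mirna_id", "sequence") %in% names(mirnas)))
    stats::setNames(as.list(mirnas$sequence), mirnas$mirna_id)
  } else {
    if (is.null(names(mirnas))) stop("mirnas must be named by miRNA id")
    as.list(mirnas)
  }
}

all_occurrences <- function(text, pattern) {
  hits <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(text, from, nchar(text)), fixed = TRUE)
    if (i < 0) break
    hits <- c(hits, from + i - 1L)
    from <- from + i  # overlapping occurrences allowed
  }
  hits
}

# transversion maps tried in order during mutagenesis
TRANSVERSION_MAPS <- list(
  c(A = "C", C = "A", G = "T", T = "G"),
  c(A = "T", C = "G", G = "C", T = "A")
)

#' Disrupt selected MREs by targeted substitution
#'
#' In-silico analogue of site-directed MRE mutagenesis of a reporter
#' 3'-UTR: each selected site receives \code{n_subs} deterministic
#' transversions at fixed seed-pairing offsets (positions opposite miRNA
#' seed positions 2, 4 and 6 by default), chosen so that re-scanning the
#' mutated sequence finds no site of the mutated miRNA at those loci and
#' the site lists of miRNAs with disjoint sites are unchanged. Positions
#' outside the selected sites are untouched.
#'
#' If the default substitutions would create a new seed match of any
#' supplied miRNA in the changed windows, alternative deterministic
#' substitution choices are tried in fixed order.
#'
#' @param utr_seq the UTR sequence (DNA or RNA).
#' @param sites data.frame of sites to disrupt, as returned by
#'   \code{\link{scan_seed_sites}} (rows may be a subset). Sites must be
#'   non-overlapping, and must not overlap a site of a different
#'   (protected) miRNA present in \code{mirnas}.
#' @param mirnas all miRNAs in play (same form as in
#'   \code{\link{scan_seed_sites}}): used to verify the postcondition for
#'   both mutated and protected miRNAs.
#' @param n_subs substitutions per site (default 3).
#' @return list \code{sequence} (mutated), \code{changes} (data.frame
#'   \code{position}, \code{ref}, \code{alt}, \code{mirna_id}).
#' @export
mutate_mres <- function(utr_seq, sites, mirnas, n_subs = 3) {
  utr <- normalize_seq(utr_seq, "UTR")
  mir <- as_mirna_vector(mirnas)
  if (nrow(sites) == 0) {
    return(list(sequence = utr,
                changes = data.frame(position = integer(0), ref = character(0),
                                     alt = character(0), mirna_id = character(0),
                                     stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("mirna_id", "start", "end") %in% names(sites)))
  if (any(sites$start < 1 | sites$end > nchar(utr)))
    stop("site out of sequence bounds")
  ord <- order(sites$start)
  s <- sites[ord, , drop = FALSE]
  if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
    stop("selected sites overlap; disrupt them one at a time")
  # protected-site overlap check: a site of another miRNA sharing bases with
  # a selected site cannot be preserved
  target_ids <- unique(s$mirna_id)
  all_sites <- scan_seed_sites(utr, mir)
  other <- all_sites[!all_sites$mirna_id %in% target_ids, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    clash <- other$start <= s$end[i] & other$end >= s$start[i]
    if (any(clash))
      stop("selected site of ", s$mirna_id[i], " overlaps protected site of ",
           other$mirna_id[which(clash)[1]])
  }
  baseline_other <- other[, c("mirna_id", "site_class", "start", "end")]
  self_keys <- site_keys(all_sites[all_sites$mirna_id %in% target_ids, ,
                                   drop = FALSE])
  # seed-pairing offset sets tried in order (positions within the 6mer core,
  # counted from the core 5' end; core position c+5 faces miRNA position 2)
  offset_sets <- list(c(5L, 3L, 1L), c(4L, 2L, 0L), c(5L, 2L, 0L))
  chars <- strsplit(utr, "")[[1]]
  changes <- NULL
  for (i in seq_len(nrow(s))) {
    core_start <- if (s$end[i] - s$start[i] + 1L >= 7L &&
                      s$site_class[i] %in% c("8mer", "7mer-m8")) s$start[i] + 1L
    else s$start[i]
    done <- FALSE
    for (map in TRANSVERSION_MAPS) {
      for (offs in offset_sets) {
        pos <- core_start + offs[seq_len(min(n_subs, length(offs)))]
        trial <- chars
        trial[pos] <- map[trial[pos]]
        trial_seq <- paste(trial, collapse = "")
        # the disrupted locus must be clean for its miRNA, no novel
        # target-miRNA site may appear near the changed bases, and
        # protected miRNAs must keep their exact site lists
        win_lo <- s$start[i] - 8L; win_hi <- s$end[i] + 8L
        resc <- scan_seed_sites(trial_seq, mir)
        tg <- resc[resc$mirna_id %in% target_ids, , drop = FALSE]
        still_there <- tg$mirna_id == s$mirna_id[i] &
          tg$start <= s$end[i] & tg$end >= s$start[i]
        novel <- !(site_keys(tg) %in% self_keys) &
          tg$start <= win_hi & tg$end >= win_lo
        oth <- resc[!resc$mirna_id %in% target_ids,
                    c("mirna_id", "site_class", "start", "end"), drop = FALSE]
        if (!any(still_there) && !any(novel) &&
            identical_sites(oth, baseline_other)) {
          changes <- rbind(changes, data.frame(
            position = pos, ref = chars[pos], alt = unname(map[chars[pos]]),
            mirna_id = s$mirna_id[i], stringsAsFactors = FALSE
          ))
          chars <- trial
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done)
      stop("could not disrupt site of ", s$mirna_id[i],
           " without side effects on other sites")
  }
  changes <- changes[order(changes$position), , drop = FALSE]
  rownames(changes) <- NULL
  list(sequence = paste(chars, collapse = ""), changes = changes)
}

site_keys <- function(x) paste(x$mirna_id, x$start, x$end)

identical_sites <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(sort(paste(a$mirna_id, a$site_class, a$start, a$end)) ==
          sort(paste(b$mirna_id, b$site_class, b$start, b$end)))
}
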