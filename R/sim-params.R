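#' Simulation parameters
#'
#' Defaults emulate the study conditions the downstream analysis assumes:
#' three replicates of WT, HOMO (point-mutant) and KO genotypes; NB counts
#' with per-feature log-normal dispersion; planted fold changes
#' concentrated in three contrast classes (KO-only / shared / HOMO-only);
#' a single genomic locus carrying most upregulated miRNAs; a
#' target-prediction score table whose planted anti-correlated edges score
#' at least 0.7; and CLIP peaks preferentially overlapping the 3'-UTRs of
#' targeted deregulated genes (relative risk
#' \code{p_bound_targeted / p_bound_untargeted}, 3 by default).
#'
#' @param seed RNG seed; identical seed gives bit-identical datasets.
#' @param n_genes,n_mirnas numbers of gene and miRNA features.
#' @param genotypes ordered genotype labels; must contain \code{"WT"}
#'   (the reference). \code{"HET"} may be appended for the dose-effect
#'   scenario and is off by default.
#' @param n_reps replicates per genotype.
#' @param libsize_range range of per-sample library sizes (total reads).
#' @param baseline_mean_log_range range of per-feature log mean expression
#'   (natural log of expected counts at the reference library size).
#' @param dispersion_shape median of the log-normal per-feature NB2
#'   dispersion distribution (sdlog fixed at 0.4).
#' @param frac_de_ko_only,frac_de_shared,frac_de_homo_only fractions of
#'   features planted in each contrast class (must sum to <= 1).
#' @param lfc_magnitude planted |log2 fold change|.
#' @param frac_up fraction of planted DE genes that are upregulated.
#' @param mirna_frac_up fraction of planted exclusive-class miRNAs that are
#'   upregulated (shared-up miRNAs are locus-driven; see Details).
#' @param locus_id label of the co-regulated miRNA locus.
#' @param locus_size number of miRNAs in the locus; all are planted
#'   shared-upregulated.
#' @param frac_locus_in_up target fraction of upregulated-in-both miRNAs
#'   that belong to the locus.
#' @param pred_score_range score range of background predictions.
#' @param frac_targeted fraction of planted-down genes given an
#'   anti-correlated planted-up miRNA edge with score >= 0.7.
#' @param p_bound_targeted,p_bound_untargeted probabilities that a
#'   targeted / untargeted gene's 3'-UTR overlaps a CLIP peak.
#' @param het_effect_fraction scaling of the HOMO log2 effect applied to
#'   HET columns when \code{"HET"} is simulated.
#'
#' @details For miRNAs the shared-upregulated set is generated locus-first:
#' all \code{locus_size} locus members are planted shared-up, plus
#' \code{round(locus_size / frac_locus_in_up) - locus_size} non-locus
#' shared-up miRNAs, so the expected locus fraction among up-in-both
#' miRNAs equals \code{frac_locus_in_up} and locus completeness is 1 by
#' construction. \code{frac_de_shared} consequently plants shared-down
#' miRNAs only.
#'
#' @return A validated \code{sim_params} list.
#' @export
sim_params <- function(seed = 1L,
                       n_genes = 10000L,
                       n_mirnas = 600L,
                       genotypes = c("WT", "HOMO", "KO"),
                       n_reps = 3L,
                       libsize_range = c(1e6, 2e6),
                       baseline_mean_log_range = log(c(5, 500)),
                       dispersion_shape = 0.15,
                       frac_de_ko_only = 0.015,
                       frac_de_shared = 0.005,
                       frac_de_homo_only = 0.03,
                       lfc_magnitude = 2,
                       frac_up = 0.3,
                       mirna_frac_up = 0.7,
                       locus_id = "mir-locus-1",
                       locus_size = 40L,
                       frac_locus_in_up = 0.9,
                       pred_score_range = c(0.3, 1),
                       frac_targeted = 0.6,
                       p_bound_targeted = 0.6,
                       p_bound_untargeted = 0.2,
                       het_effect_fraction = 0.5) {
  p <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_mirnas = as.integer(n_mirnas), genotypes = as.character(genotypes),
    n_reps = as.integer(n_reps), libsize_range = as.numeric(libsize_range),
    baseline_mean_log_range = as.numeric(baseline_mean_log_range),
    dispersion_shape = dispersion_shape,
    frac_de_ko_only = frac_de_ko_only, frac_de_shared = frac_de_shared,
    frac_de_homo_only = frac_de_homo_only, lfc_magnitude = lfc_magnitude,
    frac_up = frac_up, mirna_frac_up = mirna_frac_up,
    locus_id = locus_id, locus_size = as.integer(locus_size),
    frac_locus_in_up = frac_locus_in_up,
    pred_score_range = as.numeric(pred_score_range),
    frac_targeted = frac_targeted,
    p_bound_targeted = p_bound_targeted,
    p_bound_untargeted = p_bound_untargeted,
    het_effect_fraction = het_effect_fraction
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fr <- c(p$frac_de_ko_only, p$frac_de_shared, p$frac_de_homo_only,
          p$frac_up, p$mirna_frac_up, p$frac_locus_in_up, p$frac_targeted,
          p$p_bound_targeted, p$p_bound_untargeted, p$het_effect_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (p$frac_de_ko_only + p$frac_de_shared + p$frac_de_homo_only > 1)
    stop("frac_de_* must sum to <= 1")
  if (!"WT" %in% p$genotypes) stop("genotypes must include WT (the reference)")
  if (p$n_genes < 0 || p$n_mirnas < 0) stop("feature counts must be >= 0")
  if (p$n_reps < 2) stop("n_reps must be >= 2 for any tested contrast")
  if (p$dispersion_shape <= 0) stop("dispersion_shape must be positive")
  if (p$lfc_magnitude <= 0) stop("lfc_magnitude must be positive")
  if (any(p$libsize_range <= 0) || p$libsize_range[1] > p$libsize_range[2])
    stop("invalid libsize_range")
  if (any(p$pred_score_range < 0 | p$pred_score_range > 1) ||
      p$pred_score_range[1] > p$pred_score_range[2])
    stop("pred_score_range must be an increasing pair in [0, 1]")
  if (p$frac_locus_in_up <= 0) stop("frac_locus_in_up must be > 0")
  invisible(p)
}
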