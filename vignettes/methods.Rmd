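---
title: "Methods: integrative miRNA-mRNA cross-analysis across genotypes"
author: "mircross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA-mRNA cross-analysis across genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`mircross` implements an integrative cross-analysis of bulk gene and miRNA
read counts across three genotypes of the same cellular system: a
wild-type reference (WT), a point-mutant homozygote (HOMO), and a knockout
(KO). The design question it serves is the classic loss-vs-gain-of-function
dissection: features deregulated only in the knockout reflect loss of the
protein, features deregulated only in the mutant reflect a gained
(e.g. mislocalization-driven) activity, and features deregulated in both
are dose-sensitive to the normal function. On top of the per-arm
differential calls, the package joins the two arms through target
prediction scores into an anti-correlation network (upregulated miRNAs
against downregulated predicted targets and vice versa), asks whether an
RNA-binding protein's CLIP peaks concentrate on the 3'-UTRs of targeted
deregulated mRNAs, and maps/disrupts canonical miRNA seed sites (MREs) on
candidate UTRs.

Every stage is exercised end to end on a synthetic-data generator that
plants known effects, so the statistical behaviour of the chain (error
control, power, recovery of planted structure) is testable without any
external sequencing data.

## Differential expression model

Counts are modelled as negative binomial in the NB2 parameterization,
`Var = mu + phi * mu^2`. The engine is deliberately a single,
fully specified conditional exact test applied to both the gene and the
miRNA arm (published analyses of this design typically use two different
tools for the two arms; a single engine makes the chain reproducible and
testable at every step):

1. **Size factors** (`size_factors`): median ratio of each sample to the
   geometric-mean reference over features expressed in all samples,
   rescaled to geometric mean 1.
2. **Dispersion** (`estimate_dispersion`): tagwise method-of-moments from
   pooled within-group means/variances, shrunk toward the common
   (all-feature) estimate with weight
   `w = n_features / (n_features + 20 * df)` on the common value, floored
   at `phi_floor = 1e-4`. At three replicates per group the residual df is
   small, so the tagwise values lean heavily on the common dispersion —
   the stabilization small-replicate designs need.
3. **Conditional exact test** (`nb_exact_test`): counts are divided by
   their size factors and rounded half-to-even (deterministic
   pseudo-counts on a common library scale); group sums are formed; the
   null conditional distribution of the group-A sum given the pooled sum
   `S` is proportional to
   `dnbinom(a; size = nA/phi, mu = nA*mu) * dnbinom(S-a; size = nB/phi, mu = nB*mu)`
   with `mu = S/(nA+nB)`. The two-sided p-value sums the probabilities of
   all splits no more probable than the observed one. At `phi = 0` the
   kernel degenerates to Poisson and the test reduces exactly to the
   conditional binomial test. The full support `0..S` is enumerated; for
   `S > 20000` the enumeration is restricted to a window excluding total
   tail mass below 1e-12.
4. **FDR**: Benjamini-Hochberg across the tested features
   (`stats::p.adjust`); a feature is called `up`/`down` at `q < 0.05`
   (and `|log2FC|` above an optional threshold, default 0, with 0.5
   exposed as the stricter candidate-selection filter).

The tests verify the exact test against an independently coded exhaustive
enumeration (all pooled sums <= 30), against the conditional binomial test
in the `phi -> 0` limit, and against `edgeR::exactTestDoubleTail` as an
external cross-check; calibration on null simulations holds the nominal
5% level within [0.035, 0.065] at `phi` of 0.05 and 0.2, and a planted
simulation (10% DE, |log2FC| = 2) keeps empirical FDR at `q < 0.05` below
0.10 with sensitivity above 0.6.

## Normalization and expression filters

* **FPKM** (`compute_fpkm`) uses supplied per-feature effective lengths —
  the package does not model transcript-level effective length, because
  FPKM is used only for the "expressed" (FPKM > 0.1) and "robust"
  (FPKM > 1 in at least `n_reps` samples) filters, both strict
  inequalities.
* **CPM** (`compute_cpm`) backs the miRNA expression floor of at least
  one read per million (implemented as CPM >= 1 in at least `n_reps`
  samples).
* **Full-quantile normalization** (`full_quantile_normalize`) replaces the
  value at within-sample rank *r* by the mean across samples of the *r*-th
  order statistics. Ties within a sample receive the mean of the values
  assigned to their tied ranks; this keeps the transform deterministic and
  preserves per-sample sums exactly. On tie-free data every column becomes
  an exact permutation of the reference vector, so the per-sample sorted
  vectors coincide exactly; with ties, tie groups collapse to their group
  mean (the group-mean convention differs from interpolation-based tie
  handling in some other implementations, which is why the cross-check
  against `limma::normalizeQuantiles` is run on tie-free data).

## Contrast classes, locus co-regulation

`classify_features` partitions the union of significant features into
`KO_only`, `shared`, `HOMO_only`. Membership in `shared` requires
significance in both contrasts but **not** concordant direction; the
`concordant` flag recovers the concordant subset, which is the reading
used for miRNAs. The Venn summary reports per-class up/down counts using
the contrast in which the class is significant (HOMO for shared features —
immaterial for concordant ones).

`locus_fraction` and `locus_completeness` quantify the concentration of
upregulated-in-both miRNAs in one annotated genomic locus (the
imprinted-cluster observation). Locus membership is an annotation input;
no coordinate-window inference is attempted, because the motivating
analysis used known cluster membership. The denominator for the fraction
is the set of shared, concordant, upregulated miRNAs — the
"upregulated in both" reading. An empty upregulated set yields an
explicitly flagged undefined fraction rather than 0.

## Anti-correlation network and CLIP-binding enrichment

`build_network` retains a (miRNA, gene) edge iff the prediction score
passes the threshold (default 0.7, **inclusive**, following the
"threshold equal to 0.7" convention) and both endpoints are significant
with opposite directions. Anti-correlation is defined as opposite
significant directions, not a correlation coefficient — at three
replicates per genotype a per-feature correlation would be meaningless.
Export is an edge-list TSV or GraphML with node attributes (direction,
class, bound flag, functional-category passthrough) via `igraph`.

`intersect_utr_peaks` is strand-aware (CLIP peaks are strand-specific;
disable with `same_strand = FALSE`) and uses BED 0-based half-open
coordinates throughout, delegating the sweep to
`GenomicRanges::findOverlaps`; tests pin its behaviour to an all-pairs
brute-force oracle, including half-open adjacency.

`binding_contingency` builds, within one condition's deregulated genes,
the 2x2 table {targeted, non-targeted} x {bound, unbound} and applies the
Pearson chi-squared test (closed form `N(ad-bc)^2 / ...`, 1 df). The
Yates correction is off by default but exposed, and a two-sided Fisher
exact test (`fisher_exact_2x2`, hypergeometric enumeration) is provided
for small tables; the two pairwise class comparisons
(`targeting_contingency_pairs`) mirror the two reported targeting
contrasts. Zero-marginal tables are flagged and reported at p = 1 with a
warning rather than crashing the chain.

## The synthetic-data generator

`simulate_dataset` emulates the joint structure the analysis assumes:

* **Counts**: NB draws with per-feature dispersion
  `phi ~ Lognormal(log(dispersion_shape), sdlog = 0.4)` — the
  `dispersion_shape` parameter is the median dispersion, 0.15 by default;
  replicate variability was a free choice since no variability parameters
  are available to copy, and 0.1-0.2 is the range typical of small bulk
  RNA-seq designs. Per-sample library sizes are drawn uniformly from
  `libsize_range` and applied multiplicatively, so normalization genuinely
  matters downstream.
* **Planted classes**: fractions `frac_de_*` of features are assigned to
  `KO_only` / `shared` / `HOMO_only` with |log2FC| = `lfc_magnitude`
  applied to the stated genotypes only; shared effects are concordant by
  construction. Optional HET columns carry `het_effect_fraction` times the
  HOMO log2 effect (the dose-effect scenario; HET is off by default since
  the motivating design sequenced WT/HOMO/KO only).
* **Locus**: miRNA planting is locus-first — all `locus_size` members are
  planted shared-up, plus `round(locus_size/frac_locus_in_up) - locus_size`
  non-locus shared-up miRNAs, so the expected locus share among
  upregulated-in-both miRNAs equals `frac_locus_in_up` (0.9 by default)
  and locus completeness is 1 by construction. `frac_de_shared`
  consequently plants shared-down miRNAs only.
* **Targets and binding**: `frac_targeted` of planted-down genes receive
  one planted edge (score uniform in [0.7, 1]) from an upregulated miRNA
  active in the same condition; background predictions cover the full
  score range. Each gene's 3'-UTR is CLIP-bound with probability
  `p_bound_targeted` (0.6) if targeted, else `p_bound_untargeted` (0.2) —
  a planted relative risk of 3. An 8mer seed site of the planted miRNA is
  embedded in each targeted gene's UTR so the seed scanner finds coherent
  structure. Targeting is planted class-symmetrically, so the
  targeting-enrichment comparison between classes is null by design; only
  the binding asymmetry is planted.
* **Defaults as study conditions**: 10,000 genes (the coding universe of
  the motivating system is ~12,900; 10,000 keeps every run inside a few
  seconds while preserving the class sizes that give the enrichment tests
  their power), 600 miRNAs (~565 expressed in the motivating system),
  3 replicates x {WT, HOMO, KO}, class fractions 0.015/0.005/0.03
  (matching the observed ~200/40/420 split at that scale), gene
  `frac_up = 0.3` (most mutant-deregulated genes were down),
  miRNA planting dominated by ~44 shared-up features with 90% locus
  concentration (the observed structure), `frac_targeted = 0.6` so the
  recovered targeted share among deregulated genes approximates the
  observed ~40%.

What the generator does **not** emulate: raw reads and alignment
artifacts, isoform structure, unexpressed features (all baseline means
are drawn well above the expression filters, so the FPKM/CPM filters act
as structural guards rather than discarding features at defaults),
compositional coupling between features, batch effects, or RNA editing.
Passing tests therefore demonstrate the statistical correctness and
calibration of the chain under its own model assumptions — not robustness
to the full messiness of real libraries.

## MRE scanning and mutagenesis

`scan_seed_sites` reports canonical seed-match classes — 6mer (seed
positions 2-7), 7mer-m8 (2-8), 7mer-A1 (2-7 plus A opposite position 1),
8mer (2-8 plus A1) — assigning each core occurrence its strongest class.
The A1 convention requires an adenine in the UTR regardless of the
miRNA's position-1 identity. Positions are 1-based inclusive, optionally
offset to TSS-relative coordinates. Canonical seed matching replaces
proprietary target-prediction scoring deliberately: it is fully
specifiable and its oracle (a sliding window) is exact. Prediction
*scores* enter the analysis separately, as an input table.

`mutate_mres` models site-directed mutagenesis of reporter constructs:
three deterministic transversions per selected site at the positions
opposite miRNA seed positions 2, 4 and 6. After substitution the function
re-scans and verifies that (a) the mutated miRNA has no site left at the
disrupted locus, (b) no novel site of the mutated miRNA appeared near the
changed bases, and (c) protected miRNAs keep their exact site lists; if
the default substitutions violate any of these, alternative deterministic
choices are tried in fixed order. Selected sites that overlap a protected
site of another miRNA are rejected up front, since no substitution can
disrupt one without the other.

## Numerical and degenerate-input choices

* Exact-test p-values compare split probabilities with a relative
  tolerance of 1e-10 so ties at the observed probability are included
  robustly; p is clamped into (0, 1].
* Pseudo-count rounding is half-to-even (base R `round`), fixed for
  determinism.
* Empty feature sets propagate as flagged undefined results
  (`defined = FALSE`) rather than zeros; zero-marginal contingency tables
  warn and report p = 1.
* All simulation randomness flows from a single integer seed;
  identical seeds give bit-identical datasets.
* Problem sizes used by the test suite (2,000 features for calibration
  and FDR checks, 20-200 seeded runs for the power/uniformity and locus
  recovery properties, 3,000-10,000-gene simulations for the end-to-end
  checks) were chosen so the whole chain demonstrates its properties at
  desk scale in a few minutes.

## Known limitations

* The single exact-test engine is not the pair of tools a published
  analysis of this design would have used; headline counts from real
  data will differ from any specific published pipeline.
* Dispersion shrinkage uses fixed constants (`20 * df`, floor 1e-4)
  rather than empirical-Bayes estimation of the prior.
* The network is binary (edge/no edge at the score threshold); no
  edge weighting or multiple-miRNA synergy model.
* Locus membership must be supplied; no de novo cluster discovery.
* The full-quantile tie convention (group means) matches the stated
  rule exactly but differs from interpolation-based implementations on
  heavily tied data.
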