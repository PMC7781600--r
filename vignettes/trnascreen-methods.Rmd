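---
title: "Methods: family-aware analysis of pooled tRNA CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-aware analysis of pooled tRNA CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnascreen)
```

This vignette records the modelling choices behind `trnascreen`: the
assumptions each stage makes, the tunable parameters and their defaults, what
the simulator emulates, and the decisions taken where more than one
convention was defensible. No empirical claim is made here beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## Why families

tRNA genes occur as isodecoder families of near-identical copies. A 20-nt
protospacer designed against one family therefore usually matches several
members exactly and other families' members with 1–3 mismatches. Every
statistic in this package is computed at the family level, with the member
bookkeeping made explicit through *targeting profiles*: the fractions
(f₀, f₁, f₂, f₃) of a family's considered members at each mismatch level to
a given guide.

## Guide–target matching

`min_mismatch_hit()` scans every ungapped window on both strands and
returns the minimum Hamming distance. Choices:

- **Mismatch cap 3.** Sites at ≥4 mismatches carry no detectable expression
  penalty in this setting, so they collapse to an "untargeted" sentinel
  rather than a number. The penalty for them is 0 regardless.
- **PAM handling.** Cas9 requires an NGG adjacent to the protospacer; the
  default (`pam_mode = "NGG"`) only considers PAM-adjacent windows. Because
  published off-target tallies in this domain do not always state their PAM
  convention, `pam_mode = "none"` reproduces the unconstrained count. Both
  modes are verified against an exhaustive-scan oracle.
- **N counts as a mismatch** (conservative: an ambiguous base is never
  credited as a match).
- **Coordinates** are 0-based, half-open and local to the stored sequence on
  the top strand; minus-strand hits are reported by their top-strand window.
  Gene records include 10-nt flanks by default so a PAM falling just outside
  the gene body is still scannable.
- **Ties** (equal mismatch count) resolve to the plus strand, then the
  smallest offset, making results order-independent.
- **Score filter.** Family fractions consider only members with
  `trna_score > 50`, mirroring standard quality filtering of tRNA gene
  predictions; pseudogene families are exempt because all their members
  score low by construction. Members are counted equally — weighting members
  by expression was considered and rejected for the default because the
  family fractions feed a matrix whose penalties were themselves calibrated
  on equal-count fractions.

## The penalty scheme and its calibration

The shipped penalty vector is p = (1, 0.5, 0.2, 0): full knockdown at 0
mismatches, half at 1, a fifth at 2, none at ≥3. `fit_mismatch_regression()`
reproduces the calibration route — OLS of family expression log2
fold-change on mismatch count — and `penalties_from_means()` reconstructs a
penalty vector from mean linear reductions: normalize by the level-0
reduction, clip to [0, 1], project onto non-increasing sequences
(pool-adjacent-violators via `stats::isoreg`), and pin p₃ = 0. The
derivation is opt-in; the fixed vector is the default because it is the
established operating point of this analysis.

## Expression statistics

- Counts are scaled per sample to reads-per-million, then summed over family
  members; replicates stay separate until the fold-change step.
- Fold-changes use a symmetric pseudocount (default 0.5 RPM) and are
  computed per replicate pair, then averaged. Averaging counts before the
  ratio would weight replicates by depth; per-pair averaging matches the
  two-biological-repeats convention of this assay family.
- Edited-read fractions pool indel-supporting reads over members and divide
  by pooled maximum local coverage; a zero denominator yields `NA`, never 0.
  The "vicinity" windowing of indel calls happens upstream of this package
  (inputs arrive as per-gene counts); the conventional window is ±10 nt
  around the cut site 3 nt upstream of the PAM.

## Competition fitness

Frequencies use a 0.5 pseudocount so variants driven extinct (the strongest
phenotypes drop ~4000-fold) keep finite log frequencies. Relative fitness is
the replicate-averaged log2 frequency change versus day 0, read at **day 7**
by default: earlier days are dominated by incompletely edited cells, later
days by selection-driven extinction. Any day is selectable.

## Deconvolution: O = MᵀR

`build_reduction_matrix()` assembles coeff_ij = Σₛ pₛ·f_ij^s over the
targeted family set; absent pairs are 0. `deconvolve()` solves the additive
model. Decisions:

- **Orientation.** With one guide per family the matrix is square and the
  index convention of the written formula is ambiguous. The implemented
  contract is
  *guide-major*: the equation for variant j sums over families i,
  O_j = Σ_i coeff_ij·R_i, i.e. the system matrix is Mᵀ. The
  `orientation` flag exposes the transposed reading, and round-trip tests
  pin the convention.
- **Solver.** Direct solve while the condition number is below 10⁶
  (configurable); otherwise minimum-norm least squares via the SVD, with a
  warning and the solver recorded in the result.
- **Linearity scale.** The additive assumption is applied on the log2
  fitness scale, consistent with how the observed quantities are defined.

## Arrest-entry analysis

- `gate_top_bottom()` ranks events by mCherry/FSC (size-normalized reporter)
  and takes exact top/bottom fractions (default 5%), with stable tie order.
  An un-normalized mode exists because the fixed-threshold analysis
  (fraction of cells above 1700 fluorescence units) is conventionally run on
  raw mCherry.
- `bin_enrichment()` is the log2 frequency ratio of each guide in a sorted
  bin versus the matched ancestor sample, per replicate, then averaged; it
  is invariant to per-sample depth rescaling.
- `two_way_cluster()` defaults to average linkage with Euclidean distance
  for guide rows and correlation distance for sample columns — a standard
  choice when samples differ in scale but share shape; both metrics and the
  linkage are configurable and echoed in the output.
- `high_fraction_test()` uses Welch's unequal-variance t-test; the
  two-sample t-test convention in this assay does not specify the variance
  assumption, and Welch is the safer default at n = 3 replicates.
- `classify_essentiality()` makes the four-group summary reproducible by
  explicit thresholds: proliferation-essential if fitness ≤ −1 log2 in a
  majority of proliferative contexts, arrest-essential if high-bin depletion
  ≤ −1 log2, essential-everywhere if both, dispensable if neither. The
  published grouping is qualitative; −1 log2 (a twofold change) is the
  smallest effect this assay calls reliably, and the thresholds are
  configurable and surfaced in the output.

## The simulator and what it establishes

`sim_config()` defaults encode the study conditions: 20 families (9
proliferation, 10 differentiation, 1 pseudo), 4 members each, one guide per
family, sequencing depth 10⁶, 2 replicates over days 0/3/7/10/14 with the
day-7 readout, and a planted off-target spectrum (three 1-mismatch, two
2-mismatch and one 3-mismatch cross-family links at half-family coverage)
alongside partial own-family coverage (0.75/0.25) for every fifth family.
Requested fitness contributions span −6…−2 log2 for proliferation families,
−2.5…−0.25 for differentiation families, +0.5 for the pseudo family —
magnitudes matching a screen in which the strongest variants decline ~4000×
over 14 days while the pseudo-family guide drifts upward.

Mechanics worth knowing:

- **Exact spectra.** Substitutions are planted deterministically at
  PAM-distal protospacer positions, so measured profiles equal the planted
  spectrum *exactly* and the measured reduction matrix equals the generating
  one. This turns matrix construction into a checkable identity rather than
  an estimate.
- **Identifiability of fitness.** In a closed competition the observed log2
  frequency changes always satisfy Σ f_j(0)·2^{O_j} = 1 — relative fitness
  is identified only up to the population-mean growth. The simulator
  therefore centers the requested fitness vector onto this manifold (a
  common shift of the observed vector, absorbed through M⁻ᵀ) and reports
  the centered vector as `R_true`. Noise-free recovery to 1e-9 and the
  depth-10⁶ recovery criteria are stated against this identified truth.
- **Editing dynamics.** The edited fraction rises with saturating kinetics
  (rate 0.4/day toward a 0.85 plateau) and is then eroded by selection at
  the family's per-day fitness rate after a 4-day lag, reproducing the
  observed dip-then-recovery of targeted-family expression (≈ −1.5 log2 at
  day 4, back toward baseline by day 12). Family-share fold-changes are
  compositional: untargeted genes keep their relative proportions exactly,
  while their *shares* drift slightly as the targeted family loses mass —
  the analytic trajectories in the ground truth are computed on shares, as
  the pipeline measures them.
- **Arrest.** Responders and non-responders draw reporter intensity from
  high/low log-normals (medians 3000 and 300, σ_log 0.4) with shared
  log-normal FSC; treatment severity is encoded in responder probabilities
  (U 0.05, Q 0.7, S 0.85), and "arrest-required" families respond like
  untreated cells. The distributions are a modelling choice — FACS
  histograms are broad and right-skewed but make no distributional claim.

**Not emulated:** sequencing error and read-level artefacts, PCR jackpots,
genetic drift (growth is deterministic-exponential with multinomial sampling
only at sequencing), tRNA-modification-driven read truncation, and
genome-wide off-targets outside the supplied gene set. Passing recovery
tests therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to these real-data pathologies.

## Problem sizes used by the test suite

The suite exercises: 200+ random guide/gene pairs against the brute-force
scan oracle; 100 seeded well-conditioned linear systems for the 1e-9
round-trip; 10 seeded full competitions (20 families, depth 10⁶, 2
replicates) for truth recovery, where the deconvolved estimate must also sit
strictly closer to the truth in ℓ2 than the raw observation; and the
arrest/classification fixtures. These sizes were chosen as the smallest that
make the stochastic criteria sharp.

## Known limitations

- The deconvolution inherits the additive model's blind spots: epistasis
  between co-reduced families and nonlinear fitness–expression coupling fold
  into the residuals.
- One guide per family is assumed for the square system; libraries with
  multiple guides per family would need a least-squares formulation (the
  solver already supports non-square input).
- `edited_read_fraction()` trusts upstream indel counting; it does not
  re-examine alignments.
- The classifier's majority rule over proliferative contexts is coarse by
  design; borderline families should be inspected against the underlying
  scores, which the output table retains.
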