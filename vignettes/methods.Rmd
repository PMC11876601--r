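---
title: "Models and methods behind synergyMoA"
author: "synergyMoA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synergyMoA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyMoA)
```

This vignette explains the statistical models the package implements, the
defaults and why they were chosen, what the synthetic-data generators do
and do not emulate, and the numerical decisions that shape edge-case
behavior. Nothing here reports an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Dose–response model

All curve fitting uses a four-parameter log-logistic model in log10 dose,

$$R(d) = bottom + \frac{top - bottom}{1 + 10^{\,slope\,(\log_{10} d -
\log_{10} EC_{50})}},$$

with doses in molar throughout (`pEC50` is referenced to 1 M, so
`pEC50 > 6` means `EC50 < 1 µM`, matching the upper end of the usual
tested range). The slope is constrained positive; a *decreasing* response
has `top > bottom` and an increasing one simply has `bottom > top`, which
avoids a sign convention on the slope and lets the same machinery fit
viability curves, competition-binding curves and up- or down-going
phosphosite curves.

**Fitting.** `fit4PL()` runs multi-start bounded least squares: candidate
starts place the EC50 at every tested dose with slopes 0.5, 1 and 2,
starts are ranked by initial residual sum of squares, and the best six are
refined with Levenberg–Marquardt; the smallest final SSE wins and exact
ties go to the smaller EC50, making the result deterministic. The EC50 is
bounded to the tested range widened 100-fold on each side and the slope to
[0.01, 15]. `fixedSlope = 1` supports sparse designs (e.g. organoid
five-dose plates) where a free slope is poorly identified.

**Goodness of fit** is the squared Pearson correlation between fitted and
observed values — not $1 - SS_{res}/SS_{tot}$ — because the downstream
thresholds (0.8 for screens, 0.7 for competition curves) are calibrated on
that definition; it is set to 0 by convention when either side is
constant.

**Degenerate inputs.** All-identical responses give a *converged* flat fit
(`top == bottom`, EC50 undefined and flagged); optimizer failure on every
start gives a *non-converged* flat fallback at the mean response. Both
still yield a defined AUC so plates full of inactive drugs summarize
cleanly.

**AUC.** The curve summary is the normalized area under the clipped curve
over the tested log-dose range,

$$AUC = \frac{1}{\log_{10} d_{max} - \log_{10} d_{min}}
\int \mathrm{clip}(R(x), 0, 100)\, dx,$$

evaluated on a fixed 1000-point composite trapezoid grid. Responses are
*not* clipped before fitting — clipping only bounds the reported statistic
— so fit information from slightly negative or >100% wells is preserved.
The test suite checks the trapezoid evaluator against adaptive quadrature
to within $10^{-3}$ AUC points.

# Plate quality control

`zPrime()` implements
$Z' = 1 - (3\,SD_{pos} + 3\,SD_{neg}) / |mean_{pos} + mean_{neg}|$
with sample standard deviations. The default denominator uses the *sum* of
the control means, as printed in screening protocols of this design; the
textbook form with the difference is available via `mode = "standard"`.
For luminescence viability plates the positive (kill) controls read near
zero, where the two forms coincide, so the choice is immaterial in
practice but both are exposed rather than silently picking one.

# Bliss synergy scoring

For each anchor dose the hypothetical additive curve is the Bliss product
$E_{A+B}(d) = E_{lib}(d) \cdot E_{anchor}$, computed in fractional
viabilities (the module converts between percent and fractions at its
boundary). Two choices deserve comment:

* The anchor response entering the product is the *measured* single-agent
  viability at the anchor dose (mean over replicate wells); the fitted
  anchor curve is used only when no such wells exist. Measured values
  avoid propagating anchor-fit bias into every hypothetical curve.
* The hypothetical points are refitted with the same 4PL machinery before
  AUC computation, so experimental and hypothetical AUCs carry identical
  smoothing and clipping behavior and their difference is a fair
  comparison.

`AUC_Δ = AUC(hyp) − AUC(exp)` per anchor dose; `ΣAUC_Δ` sums the two. The
verdict requires `ΣAUC_Δ > 10`, at least one efficacious combination curve
(`AUC < 80`, `pEC50 > 6`), and `R² > 0.8` in both conditions — pairs
failing the R² gate are `not_evaluable` rather than `not_synergistic`,
since a bad fit says nothing about biology. All thresholds are strict
inequalities and configurable.

`selectAnchorDoses()` encodes the usual design rule: anchor-insensitive
lines (anchor EC50 ≥ 10 nM) get 10/30 nM anchors, sensitive lines 1/3 nM.

# Competition-pulldown target calling

Residual binding is the per-dose intensity ratio to the vehicle pulldown,
deliberately unclipped (noise can push it above 1). Before fitting, the
series is anchored with the vehicle point — residual binding exactly 1 at
a pseudo-dose 30-fold below the lowest tested dose — because for the most
potent binders nearly all tested doses lie beyond the midpoint and the
upper plateau is otherwise unidentifiable. The target criteria
(`R² > 0.7`, plateau fold change `bottom/top < 0.5`, `slope > 0.2`,
`pEC50 > 6`, ≥ 4 unique peptides) treat "fold change" as the fitted
*plateau ratio*, the natural reading for competition curves: it asks
whether the protein is at least half competed at saturation.

The apparent dissociation constant multiplies the fitted EC50 by a
depletion correction factor, the mean over experiments of the sequential
re-pulldown/first-pulldown intensity ratio. Proteins absent from the
re-pulldown receive the panel-median factor with a `cf_missing` flag. The
manual curation step used in practice (inspecting dose-dependent loss of
spectral counts) is approximated by an optional heuristic — Spearman ρ < 0
between dose and MS/MS count — off by default so that the automated
verdict is reproducible.

# Dose-resolved phosphoproteomics

**Aggregation.** Evidence rows are filtered to localization probability
strictly above 0.75, checked for window/site consistency (15-mer windows
centered on the stated residue), and summed per phosphosite *set*:
singly and multiply phosphorylated forms of the same position are distinct
analytes, matching how multiplexed PTM experiments count regulated
p-peptides.

**Normalization.** `normalizeChannels()` alternates two proportional
scalings to a fixed point: per batch, channels are scaled to median
intensity 1 (removing label/loading differences), and each site's row is
scaled within each batch so the mean of the two reference channels (chemo
only and vehicle) is 1 (removing per-site batch effects). Iterating to a
fixed point, rather than applying each step once, makes the operation
idempotent — re-normalizing normalized data is a no-op to below
$10^{-9}$ — which in turn makes pipeline stages safely re-runnable. The
alternation converges in a handful of iterations for positive data.

**Per-drug regulation.** Channels 1–9 are expressed as log2 ratios to the
chemo-only channel and fitted with the shared 4PL model. Significance is a
2D rule: an F-test of the 4PL against a flat model at α = 0.05 combined
with an absolute curve fold-change limit of 0.45 in log2 units. This is a
deliberate simplification of relevance-score curve classification used by
dedicated PTM curve tools; the F-test captures the same "is a sigmoid
warranted" question with standard distributional assumptions, and the
thresholds are configurable. The curve fold change is defined as the
saturating plateau minus the zero-dose baseline, so down-regulated sites
carry negative values and the direction is simply its sign. Regulated
calls additionally require `pEC50 > 5`, suppressing curves whose apparent
midpoint lies at the edge of the tested range. Sites with fewer than six
finite dose points are flagged `insufficient` rather than called.

**Chemo effect.** The chemo-only versus vehicle comparison is an
equal-variance two-sided t-test on log2 intensities across batches
(replicates), BH-adjusted across all tested sites, with calls at
`q < 0.01`, |log2FC| > 1 and at least three valid values per group. The
equal-variance variant (not Welch) is the default to match how such
volcano analyses are conventionally run; it is configurable.

**Consensus and reversal.** With four drugs sharing exactly one intended
target, sites regulated in the same direction by at least three of the
four are treated as bona fide target-pathway events (identical direction
is required — a mixed up/down quorum is no consensus). Reversal then
cross-references the chemo effect: *reverted* = chemo-induced and
consensus-suppressed, *restored* = chemo-suppressed and
consensus-re-established. pSQ/pTQ motif annotation (center S/T, +1 Q,
terminal padding counts as non-motif) and per-drug potency medians over
regulated motif sites complete the biomarker nomination readout.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* **Screen**: 11 library doses, 170 pM–10 µM in 1:3 steps; two anchor
  doses per cell line chosen by the sensitivity rule; 8 vehicle and 16
  kill-control wells per plate; raw signals are true viability times a
  plate scale of 2×10⁶ counts under multiplicative log-normal noise
  (default σ = 0.05, ~5% CV — typical for ATP-luminescence readouts).
  Interaction truth is *potency-shift* synergy: the combination follows
  the Bliss product with the library EC50 divided by φ (default 10),
  because real synergistic combinations of this kind manifest as order-of-
  magnitude EC50 improvements; Bliss-additive is the null. Kill controls
  have true signal 0, so their simulated SD is 0 and plate Z′ is governed
  by vehicle-well noise (≈ 0.85 at the default noise).
* **Competition panel**: 9 doses, 1 nM–30 µM; binder dissociation
  constants log-uniform 1–100 nM; depletion factors uniform 0.3–1. Curves
  are generated with midpoint at the *depletion-inflated* EC50
  $K_D / cf$, so that the correction-factor arithmetic is what recovers
  the truth. The vehicle intensity is the clean reference scale; dosed
  and re-pulldown intensities carry the noise. Four sequential-pulldown
  experiment pairs feed the averaged correction factor.
* **Phosphoproteome**: four 11-channel batches (one per drug), channels
  1–9 titrating 1 nM–10 µM, channel 10 chemo-only, channel 11 vehicle.
  Site categories are reverted (chemo up log2FC 1.5–4.5, all drugs down),
  restored (mirror image) and null; reverted sites carry the pSQ/pTQ
  motif with probability 0.8, restored sites never (matching the
  biological asymmetry the consensus logic is meant to resolve), null
  sites at a 0.1 background. Per-drug potencies center on drug-specific
  pEC50 means (8, 7.7, 6.9, 6.7) so potency summaries separate more and
  less potent compounds. Ambiguous (localization < 0.75) rows are emitted
  *in addition to* each site's confident evidence at the configured
  fraction, and per-batch scale factors 2^U(−1,1) exercise the
  normalization.

**What they do not emulate.** No spatial plate effects, no edge wells, no
drug-interaction mechanisms beyond potency shift (no efficacy-shift or
slope-change synergy), no heteroscedastic or intensity-dependent noise, no
peptide-level missingness structure (missingness is at random), no
retention-time or charge-state artifacts, and no correlated off-target
structure across drugs. Passing tests therefore demonstrate that the
statistical machinery recovers known truth under idealized but
realistically sized designs — not that any specific biological dataset
would yield the same counts.

# Problem sizes and determinism

The validation suite and `scripts/acceptance.R` use: 200 random curves for
EC50 recovery (plus 50 noiseless), 100 random parameter draws for the AUC
oracle, 200 drug×cell-line pairs each for the Bliss-null and detection
screens, a 50-protein competition panel, a 1,000-site phosphoproteome
(40 reverted / 60 restored), and a 10,000-site family with 500 true
chemo-effect sites for the power check. These sizes keep each check
statistically meaningful (binomial error on a 200-pair rate is ~±3%)
while completing in minutes on a laptop. Every stochastic step is seeded;
generators are byte-identical under a fixed seed, and `runPipeline()`
writes a manifest whose contents are diff-clean across reruns.

# Known limitations

* The F-test significance rule assumes i.i.d. Gaussian residuals on log2
  ratios; heavy-tailed reporter noise would inflate its false-positive
  rate relative to resampling-based curve classification.
* The Bliss machinery supports exactly two anchor doses per pair, as in
  anchored screen designs; dose-matrix (checkerboard) synergy surfaces
  and alternative null models (Loewe, ZIP, HSA) are out of scope.
* `K_D^app` correction assumes the sequential-pulldown ratio is
  dose-independent; saturation effects at very high bead occupancy are
  not modeled.
* Multi-site peptide windows are classified by their first window for
  motif purposes; a mixed SQ/non-SQ doubly phosphorylated peptide counts
  as motif-positive.
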