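---
title: "Methods: tilt-response scoring, topography, and filtered differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tilt-response scoring, topography, and filtered differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltseq)
```

`tiltseq` packages the quantitative analysis used to ask whether
vestibular projection neurons in the larval zebrafish tangential nucleus
develop normal sensory tuning, dorsoventral topography, and
transcriptional profiles after the loss of their nIII/nIV extraocular
motor partners (the *phox2a* null condition). This vignette documents the
models and procedures, the parameters that matter, the synthetic-data
generator that stands in for the imaging and sequencing data, and the
numerical choices made where the design was genuinely open.

## Stimulus schedules and response model

Two 65-s stimulus epochs are modelled, imaged at 3 frames/s by default:

* **Tonic:** 5 s horizontal baseline (0°), 15 s nose-down tilt (−19°),
  15 s horizontal, 15 s nose-up tilt (+19°), 15 s horizontal. The imaging
  system restores the animal to horizontal after each tilt, and the
  response is read out in the *first second of restoration* — at 3 frames/s
  that is exactly three frames (`ceiling(frame_rate)` frames in general).
* **Impulse:** 20 s baseline, a 10-ms impulse, 30 s horizontal, a second
  10-ms impulse, ~15 s horizontal. At 3 frames/s the first post-impulse
  frames are 61 and 151 (1-based).

The per-direction response is

$$\Delta F/F = \frac{\bar F_{\text{response}} - \bar F_{\text{baseline}}}{\bar F_{\text{baseline}}},$$

with the nose-down baseline taken from the initial 5-s window and the
nose-up baseline from the last 3 s of the horizontal segment following the
nose-down tilt, so each readout is referenced to the fluorescence level
immediately preceding its own tilt. The explicit ratio form is the
standard ΔF/F convention and matches the unit scale of reported values
(tonic responses of order 1–2).

**Significance.** A response is significant when it exceeds twice the
baseline standard deviation. The SD is computed on per-frame baseline
samples transformed to ΔF/F units (`sd(F_baseline / mean(F_baseline) - 1)`),
which makes the 2-SD criterion unit-consistent with the response.

**Selectivity and classification.** The directional selectivity index is
`(up − down)/(up + down)` with each ΔF/F clamped below at zero, giving a
±1 scale with positive values for nose-up preference. Clamping keeps the
index bounded when a direction shows suppression; how suppression was
handled upstream is not recoverable, so the clamp is the documented
convention here. When both clamped responses are zero the index is
undefined and the neuron is untuned. Classification requires both
`|index| >= 0.1` and a significant response in the preferred direction;
neurons significant in neither direction are untuned regardless of index.
Requiring preferred-direction significance is the stricter of the two
readings of the published criteria and is flagged in the output rather
than hidden.

**Repeats.** The three stimulus repeats are aggregated by averaging
per-repeat ΔF/F and baseline SDs, then recomputing significance and the
classification on the aggregate. Averaging is the simplest estimator that
uses all repeats; the test suite verifies it does not classify worse than
a single repeat on noisy data.

## Synthetic traces

The generator emulates the *structure* of tilt-in-place recordings, not
the biophysics:

* Fluorescence is `roi_size × (baseline_level × (1 + A·k(t)) + ε)`, with
  additive Gaussian noise `ε ~ N(0, baseline_sd²)` and a multiplicative
  ROI-area factor so the scoring module's ROI normalization is exercised.
* The indicator kernel `k(t)` is an instantaneous rise decaying as
  `exp(−Δt/τ)` with `τ = 1.8 s` by default (GCaMP6s-like). The single
  exponential is deliberately simple: its purpose is to put near-peak
  signal inside the 1-s readout window, which any realistic indicator
  model would also do.
* Nose-up neurons carry a transient at the restoration after the nose-up
  tilt, nose-down neurons after the nose-down tilt, and untuned neurons
  equal transients at both — so their index concentrates near 0.
  Impulse-responsive neurons carry equal transients after both impulses,
  matching the near-zero impulse selectivity observed in this system.
* Defaults: baseline 100 a.u., noise SD 5 a.u., response amplitude 1.5
  ΔF/F, subtype mix 46/47/7% (nose-up/nose-down/untuned), impulse
  responder fraction 0.6 — all chosen to echo the published control
  proportions and response scale. No published noise magnitude or
  indicator kinetics exist for this preparation; these are configurable
  defaults, not claims about the real data.

What the generator does **not** emulate: motion artifacts, neuropil
contamination, bleaching, plane-to-plane laser-power differences,
correlated noise, or fish-level response heterogeneity. Passing tests
therefore demonstrate that the scoring pipeline recovers ground truth
under clean, independent noise — not that it is robust to every artifact
of real recordings.

## Topography

Coordinates are standardized by subtracting an anatomical origin (the
dorsomedial-most point of the nucleus, or the box-corner convention used
for the motor nuclei), making all downstream statistics translation
invariant. Dorsoventral depth is binned into eight sections with
half-open intervals `[b_i, b_{i+1})`: a soma exactly on an internal
boundary goes to the deeper section. The original sectioning used
anatomical landmarks that are not recoverable; equal-width sections over
the configured extent are the default.

Bootstrap distributions resample the coordinate sample with replacement
(100 iterations by default, per the published procedure) and report
per-bin mean and SD of densities over 20 equal-width bins spanning the
pooled range; each iteration's density integrates to 1. The bin count is
a display/summary choice, configurable, with no effect on the KS or
MANOVA statistics, which operate on the raw coordinates.

Group comparisons use `stats::ks.test` (two-sided, asymptotic),
`stats::manova` with Wilks' Λ (Pillai's trace as an option — the original
report names only "multivariate analysis of variance", and Wilks is the
conventional default), and `stats::wilcox.test` for per-fish counts,
exact when both groups have ≤ 10 fish without ties and tie-corrected
normal otherwise. In the synthetic positions, nose-up somata occupy a
dorsal band and nose-down somata a ventral band of a 40-µm extent with
25% overlap by default (`dv_overlap` spans fully disjoint to fully
shared), and a `topographic = FALSE` switch provides the spatial null
used for calibration tests. Differences of ~2 µm are at the scale of
registration error in the original workflow and should not be
over-interpreted even when nominally significant.

## Differential expression and the reference filter

The bulk test is a from-scratch two-group negative-binomial Wald test
(the full shrinkage machinery of established DE packages is intentionally
out of scope; where such a package is available it serves as an
independent cross-check in the tests, never as the implementation):

1. **Normalization:** median-of-ratios size factors over genes expressed
   in every sample.
2. **Dispersion:** per-gene method of moments on normalized counts,
   pooled across the two groups with df weights:
   `α = (s² − μ)/μ²`. With 3 replicates per group this estimator is very
   noisy, and its low tail makes the plug-in Wald test anti-conservative
   (empirical type-I error ≈ 0.12 at nominal 0.05). Each gene's dispersion
   is therefore bounded below by the across-gene median dispersion (and by
   a numerical floor of 1e-8) — a conservative max rule in the spirit of
   early DE methods — which restores calibration (≈ 0.05) while leaving
   power for |log2FC| = 4 effects above 95%.
3. **Effect size:** `log2FC = log2(μ̂₁ + 0.5) − log2(μ̂₂ + 0.5)` from
   normalized group means with pseudocount 0.5; the contrast defaults to
   null vs sibling.
4. **Inference:** delta-method SE,
   `Var(log2(μ̂ + c)) ≈ Var(μ̂)/((μ̂ + c) ln 2)²` with the NB variance
   function, and a two-sided normal p-value. All-zero genes are excluded
   and flagged.

Benjamini–Hochberg adjustment is applied over the current gene universe.
Candidates require adjusted p < 0.05 **and** |log2FC| > 2. The reference
filter keeps genes detected (count > 0, the common single-cell
convention) in at least 0/1/3/5/10/30/50% of atlas projection-neuron
cluster cells; analyses are performed separately per threshold, so the
adjustment — and by default the whole test, including size factors and
dispersions (`retest = TRUE`; `retest = FALSE` only re-adjusts) — is
recomputed on each reduced universe. Per-universe re-adjustment is why
gene counts per threshold are not a simple subset of one adjusted list.
Genes absent from the atlas get detection 0 and are excluded at any
positive threshold, with a message.

The synthetic counts use log-normal baseline means (median 100, log-SD 1),
fixed or log-normally drawn dispersions (default 0.05), and a configurable
fraction of genes carrying a planted ±log2FC. The atlas draws per-gene
detection rates from Beta(0.6, 1.4) (mean ≈ 0.3, matching the detection
scale of highly expressed genes in the reference cluster) across 1,468
cells of which 32% form the projection cluster — the published atlas
dimensions. A `planted_detection_rate` override ties planted genes to a
known detection level for filter-ladder tests. The generator does not
emulate sample-level quality failures (the published analysis excluded one
sequencing repeat by PCA variance); a variance-based QC decision is left
to the analyst rather than fixed to a numeric cutoff.

## Genotype comparisons

`anova_multcomp` runs one-way ANOVA with Tukey HSD pairwise comparisons —
the published analysis states "multiple comparisons" without naming the
procedure, and Tukey is the standard post-ANOVA choice; Bonferroni is
available by option, and the procedure used is always part of the output
rather than implicit. Cohen's d uses the pooled-SD form. `summarize_groups`
emits the mean ± SD, n table shaped like the published genotype
comparison. Fish-level nesting is not modelled (neurons are pooled, as in
the original analysis).

## Determinism and seeding

Every generator is a pure function of `(seed, config)`: RNG state is
saved, seeded from the configured seed plus a fixed per-module offset, and
restored, so stages are independently reproducible and the end-to-end
JSON summary is byte-identical across reruns of the same configuration.
The pipeline driver fans one explicit seed out to the modules; nothing
seeds from the wall clock.

## Problem sizes in the test suite

The test and acceptance runs use deliberately modest sizes chosen to make
the statistical assertions stable: 600 neurons (three repeats each) for
subtype recovery at a response amplitude 10× the baseline noise SD; 2,000
genes at 3 vs 3 samples for null calibration of the NB test; four 500-gene
datasets for power; 50 datasets for filter-ladder monotonicity; 100–200
observations for bootstrap and calibration checks. These sizes keep
Monte-Carlo standard errors well inside the asserted bounds.

## Known limitations

* The NB test is a documented stand-in with moderated moment estimators;
  its p-values are calibrated but less powerful than full
  empirical-Bayes shrinkage at small effect sizes, and are never compared
  numerically against published DESeq2 output.
* The untuned class requires no significant response *or* a sub-threshold
  index; whether the original classification also demanded significance
  for tuned neurons is ambiguous, and the stricter reading used here can
  label weakly responding tuned neurons untuned at low SNR.
* The impulse selectivity index fixes impulse 1 as numerator; the original
  pairing is unstated. With equal default amplitudes the index is
  symmetric around zero either way.
* Synthetic positions use uniform bands rather than empirical soma
  densities; KS/MANOVA calibration results transfer, but effect sizes on
  synthetic data are not predictions about anatomy.
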