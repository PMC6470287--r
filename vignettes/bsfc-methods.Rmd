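---
title: "Burst-suppression coupling and functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-suppression coupling and functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsfc)
```

## The problem

Burst suppression (BS) is the EEG signature of deep anesthesia: the cortex
alternates between high-voltage bursts and near-isoelectric suppression
epochs, and it does so in near-global synchrony. In simultaneous EEG-fMRI,
that synchrony shows up as a strong shared component in the BOLD signal of
most brain regions, time-locked to the hemodynamically filtered BS pattern.
Because functional connectivity (FC) is a correlation of regional time
courses, a shared component inflates almost every edge of the connectivity
matrix — a *non-specific* effect that rides on top of, and obscures, any
*specific* reorganization of networks between anesthetic depths.

`bsfc` implements the chain that separates the two: detect suppression
epochs in the EEG, build a hemodynamic regressor from the binary BS
pattern, remove its contribution (together with conventional nuisance
signals) from parcel-level BOLD, and only then compare whole-brain,
edgewise and seed-based connectivity between deep-anesthesia (BS) and
moderate-anesthesia slow-wave (SW) runs. A synthetic cohort generator with
recorded ground truth backs every stage with recovery tests.

## Suppression detection

Model: suppression is a drop of broadband EEG amplitude that is shared
across channels. The detector (`detect_suppressions()`) works on amplitude
envelopes only:

1. Per channel, a moving-RMS envelope with window `envelope_window`
   (default 0.25 s).
2. Per-channel normalization by the 90th percentile of the envelope — a
   robust estimate of burst-level amplitude. This makes the detector
   invariant to global gain and to inter-channel differences.
3. The normalized envelopes are averaged across channels and thresholded at
   `threshold_fraction` (default 0.25): samples below threshold are
   suppression candidates.
4. Candidate runs shorter than `min_suppression` (0.5 s) are discarded and
   non-suppression gaps shorter than `min_burst_gap` (0.2 s) merged, in
   that order.

Two refinements correct the known biases of a windowed-RMS detector.
First, the coarse envelope crosses the threshold only once the burst
fraction of the window falls below `threshold_fraction^2` in power, which
*shrinks* every suppression run by approximately
`w (1/2 − threshold_fraction^2)` per edge; the candidate mask is therefore
dilated by exactly that amount before the duration filters, so they see
unbiased epoch lengths. Second, each retained onset and offset is
re-localized on a five-times-finer envelope by a step fit around the
mid-power level between the local burst and suppression amplitudes; the
mid-power crossing is unbiased to first order, and the step fit (minimum
misclassified samples) is robust to the higher variance of the fine
envelope. On the default synthetic regime (20:1 amplitude ratio) this
yields epoch edges accurate to a few tens of milliseconds and a temporal
Jaccard overlap with ground truth above 0.95 over full 400 s runs.

A run with no amplitude contrast (flat recording) is an error; a recording
that is all burst simply yields no intervals.

## From pattern to regressor

The binary pattern (0 = suppression, 1 = non-suppression) lives on the EEG
sample grid, with sample *i* covering `[i/fs, (i+1)/fs)` seconds. The BOLD
regressor (`build_bs_regressor()`) is the causal convolution of this series
with the canonical double-gamma HRF,

`h(t) = g(t; 6, 1) − g(t; 16, 1) / 6`,

evaluated on a 32 s support and peak-normalized (`canonical_hrf()`;
`g` is the gamma density parameterized by delay and dispersion). The
convolution runs at the pattern's own rate — preserving sub-TR timing of
suppression onsets — and is then sampled at volume onsets `t = k·TR`, the
first `n_drop` volumes (default 10, the pre-steady-state scans) removed,
and the result mean-centered. Construction is linear in the pattern and is
checked in the tests against a brute-force convolution loop.

## Preprocessing: order matters twice

`preprocess()` applies, per parcel: linear detrend; OLS nuisance regression;
zero-phase band-pass (4th-order Butterworth, forward-backward, 0.01–0.1 Hz,
after demeaning). Two ordering subtleties are deliberate design points:

* **Regression before filtering.** Filtering first and regressing raw
  nuisance afterwards leaves the out-of-band mismatch between filtered data
  and unfiltered regressors in the residuals. The package's default order
  is regression first; the alternative is kept (`filter_then_regress`) and
  the paired comparison — residual correlation with the run's true filtered
  nuisance component, available from generator ground truth — favors
  regression-first on every seeded run in the test suite.
* **A drift column inside the regression design.** The design is
  `[1, t, motion(6), WM, CSF (, BS regressor)]`. The trend term is not
  redundant with the detrend stage: detrending the *data* but not the
  *regressors* would re-introduce each regressor's own trend component into
  the residuals. For the BS regressor this is not cosmetic — a pattern whose
  suppression density drifts over the run has a substantial trend, and
  without the drift column a visible fraction of the coupling survives
  "removal". With it, removal of the injected coupling is exact up to
  numerical precision, which the suite verifies by comparing BS-regressed
  runs against no-coupling twins generated from the same random stream.

The Butterworth band edges are `0 < low < high < 1/(2 TR)`; at TR = 2 s the
default band retains a 0.05 Hz sinusoid at ≥ 0.97 gain and attenuates
0.005 Hz drift and 0.2 Hz noise by ≥ 99%. The filter type and order are a
package choice — only the band is externally fixed — so bit-level agreement
with any specific legacy pipeline is not claimed.

## Coupling statistics

Per run, `fit_coupling_glm()` regresses each parcel on
`[1, BS regressor]`; the slope is the coupling strength in signal units per
regressor unit. At the group level (`group_coupling_test()`), per-parcel
betas across runs are modelled on `[1, subject indicators]` (dummy coding,
one reference subject) and the intercept is tested, two-tailed, Bonferroni-
corrected across the 94 parcels — the parcel-level stand-in for voxelwise
family-wise-error correction. Parameter recovery on synthetic cohorts
(correlation of mean estimated betas with the generating betas) exceeds
0.98 at the default study geometry.

## Whole-brain statistics

FC matrices are Pearson correlations of preprocessed parcel time courses.
Edgewise group models run on Fisher-z values (variance stabilization);
Hedges' g is computed on the raw correlation samples so it remains a plain
two-group effect size. The group design is
`[1, group (BS = 1), subject indicators]`.

**Network-based statistic.** Edges with `|t|` above the two-sided
`edge_alpha = 0.001` critical value form a graph; family-wise error is
controlled over connected components by their extent (edge count). The
permutation scheme respects the covariate structure: group labels are
permuted *within subject strata*, so subjects contribute their own runs to
both pseudo-groups and subject effects are preserved under the null; a
subject observed in only one state keeps its labels fixed. Component
p-values use the `(1 + exceedances)/(1 + n_perm)` convention. On 200
pure-noise cohorts the empirical family-wise error is below the nominal
0.05; a planted 8-region clique is recovered completely at `n_perm = 1000`.

**Lobe-block residuals.** Significant ("disrupted") edges are summarized
over unordered lobe pairs: `O` observed, `E = D·m_b/M` expected under a
uniform spread of the `D` disrupted edges over all `M` possible edges
(`m_b` = possible edges in the block), `Z = (O − E)/√E`. Conservation
`ΣO = ΣE = D` holds by construction. The permutation test reassigns the
`D` edges uniformly without replacement and reports the fraction of
reassignments with `Z` at least the observed value — deliberately *without*
the `+1` correction, matching the statistic's literal definition — with
Bonferroni correction over evaluated blocks. The packaged 94-region
parcellation (82 Regional-Map-style cortical areas, 12 subcortical) carries
a nine-lobe partition and is fully user-replaceable.

## Seed-based connectivity

`seed_connectivity()` uses the mean time course over the seed regions
(bilateral PCC or bilateral thalamus by default) as the regressor; the
per-target slope equals `cov(target, seed)/var(seed)`. Within-group maps
are tested by the covariate-adjusted one-sample model, between groups by
the same two-group linear model as the edges. With only two groups the
repeated-measures comparison collapses algebraically to that
covariate-adjusted model, so one code path serves both descriptions.

## The synthetic cohort generator

The generator is the package's testbed and defines its study conditions:

* **Alternation** — an alternating renewal process, exponential durations
  by default (gamma optional for more regular cycling). Defaults are 15 s
  bursts and 5 s suppressions: a stable, slowly alternating BS regime whose
  ~0.05 Hz alternation lies inside the 0.01–0.1 Hz analysis band, as it
  must for the coupling to be detectable in band-passed BOLD at all.
  Published recordings do not constrain the duration law further; this is a
  declared choice. The long-run BSR is
  `mean_supp/(mean_burst + mean_supp)`.
* **Targeted BSR** — cohort simulation maps a per-run target BSR onto the
  20 s cycle (flooring either state at 0.8 s) and re-draws the pattern, up
  to 50 seeded attempts, until the realized BSR is within 2 points of
  target: a finite 400 s run realizes the renewal expectation only up to a
  sampling noise of several points, and the cohort's BSR column is meant to
  be an experimental condition, not a random outcome.
* **EEG** — band-limited (1–30 Hz) oscillation with regime-dependent RMS
  (50 µV bursts, 2.5 µV suppression, 20:1) plus 1 µV white channel noise,
  identical pattern across channels. No MR-gradient or ballistocardiogram
  artifacts are simulated — detection operates on clean two-regime signals,
  so passing tests bound detector bias and variance, not artifact
  robustness.
* **BOLD** — `Y[p,] = β_p s + Σ_b L[p,b] f_b + (W G N')[p,] + ε[p,]`:
  the HRF-convolved pattern `s` scaled by per-parcel coupling betas
  (N(1, 0.25) by default — predominantly positive, as observed in vivo);
  latent block factors whose loadings rise by `delta` in BS runs, giving
  analytically known edge effects (`cov = l_i l_j`, so block-mate
  correlation `l²/(l²+σ²)`); eight AR(1) nuisance series (lag-1
  coefficient 0.9, unit variance) entering through per-parcel weights
  `W ~ N(1, 0.3)` and gains `G`; white noise. Default blocks emulate a
  DMN-like network persisting in both states and strengthening slightly
  under BS, a thalamocortical block that recovers under BS, and an
  orbitofrontal block carrying the largest effect. Ground truth (betas,
  loadings, injected series, nuisance contribution) is recorded on the run.

What the generator does *not* emulate — hemodynamic nonlinearity,
spatially structured noise, motion spikes, physiological (cardiac or
respiratory) aliasing, imperfect parcellation — bounds what green tests
mean: they certify the statistical machinery under the stated model, not
robustness to every failure mode of real acquisitions.

## Numerical choices and degenerate inputs

* Time is in seconds; intervals are half-open `[onset, offset)`; volume
  *k*'s onset is `k·TR`; sample *i* covers `[i/fs, (i+1)/fs)`.
* Rounding for display of the physiology table is half-away-from-zero at
  the printed precision (banker's rounding would misprint a mean ending in
  5); p-values below 0.0005 render as `"<0.000"`.
* The pooled two-sample t-test with zero pooled variance returns `p = 1`
  for equal means and errors otherwise; Fisher z refuses `|r| = 1` edges
  naming the edge; zero-variance parcels, flat EEG, constant seed series,
  rank-deficient designs and degenerate (zero-variance) BS regressors all
  raise typed errors naming the offending object.
* All permutation procedures take explicit seeds; identical seeds give
  byte-identical results, including the full pipeline bundle.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at deliberately compact
geometries chosen to exercise every code path at full statistical fidelity:
detection on 400 s runs at 500 Hz with 4 channels (21 channels in the
worked example); coupling recovery over 10–20 BS runs of 94 parcels × 200
volumes at a 100 Hz pattern rate; NBS calibration on 200 null cohorts of 12
runs × 30 regions at 500 permutations, power on 20 runs × 94 regions at
1000; lobe-block calibration on 60-region configurations. These sizes are
the package's own validation design; all scale linearly if enlarged.

## Known limitations

* Parcel-level only: voxel-to-parcel averaging is assumed upstream, and
  voxelwise random-field inference is intentionally out of scope
  (Bonferroni over parcels replaces it).
* The detector's free parameters are declared defaults, not estimates from
  any reference recording; real EEG with residual MR artifacts will need
  parameter review.
* No global-signal regression and no scrubbing — both debated steps are
  excluded rather than half-supported.
* The two-group, two-subject covariate model treats runs as exchangeable
  within subject; richer repeated-measures error strata are not modelled.
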