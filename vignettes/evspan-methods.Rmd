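---
title: "Methods: simulation and analysis of the temporal eye-voice span"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of the temporal eye-voice span}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measures and their algebra

For an item *N* read aloud from a list, three times define everything:
the first valid eye entry into the item's AOI, the end of first-pass
reading (entry plus first-pass gaze time *GT*), and the naming onset.
The package computes

* onset EVS (= processing time *PT*) = naming onset − first entry,
* offset EVS = onset EVS − *GT*,
* GT/PT = *GT* / onset EVS (defined only for onset EVS > 0).

These are linked by exact identities — offset EVS = PT·(1 − GT/PT), and
sign(offset EVS) = sign(1 − GT/PT) — which the test suite asserts on
every record the pipeline emits, not just on examples. A record whose
naming onset precedes its first entry has onset EVS ≤ 0; it is kept,
flagged `invalid_onset`, and removed by the exclusion cascade rather than
silently dropped.

The sign convention is: positive offset EVS (GT/PT < 1) means the eyes
moved on before articulation began (eye-voice span); negative offset EVS
(GT/PT > 1) means voice-eye span. One sentence in the source literature
states the opposite pairing for GT/PT; it is inconsistent with the same
source's own tables and figure captions, and the package follows the
tables.

## The generative model

`sim_config()` fixes the study conditions. Per familiarity × length
condition the generator draws item-level timing in one of two modes:

* **offset mode** — gaze time *G* and offset EVS *E* from independent
  normals; the per-condition offset-EVS means/SDs default to the reported
  condition table (258.9/134.8 … −63.1/185 ms).
* **ratio mode** — processing time *P* and ratio *R* from independent
  normals (GT/PT means/SDs 0.59/0.18 … 1.15/0.36); then *G* = *R·P*,
  *E* = *P*(1 − *R*).

Two modes exist because the offset-EVS row and the GT/PT row of the
condition table cannot both be matched in mean and SD by a single
independent-sampling scheme; recovery targets are therefore stated per
mode.

Per-condition gaze-time means are not reported in the source; they are
derived from the identity *G* = *E·R*/(1 − *R*) applied to the condition
table (372.6, 468.6, 446.7, 654.5, 559.0, 483.8 ms). Their grand mean
(~497 ms) agrees with the reported overall first-pass gaze time (494 ms),
which is the consistency check that justifies the derivation. Gaze SD
(120 ms) and *P* SD (150 ms) are unreported and set once to values
realistic for oral reading; they matter only for Monte-Carlo standard
errors, not for the recovered means.

Gaussian condition distributions are an explicit approximation: the
source's empirical crossing percentiles imply right-skewed distributions.
Consequently only the *ordering* of crossing percentiles across
conditions is treated as reproducible, never their printed values.

### Truncation-aware calibration

Draws implying onset EVS ≤ 0 are rejected and resampled (a naming onset
cannot precede the eye entry it is measured from), as are gaze times
below the 50 ms detectability floor. Rejection truncates the marginals:
at the long-pseudoword parameters the raw bias on the offset-EVS mean
would be ≈ +10 ms, well outside the recovery tolerances. The sampler
therefore moment-matches: latent normal parameters are solved so that the
distribution *after* rejection has the configured mean and SD. The
truncated moments are computed exactly — the inner (truncated-normal)
moments in closed form, the outer integral by adaptive quadrature
(`rel.tol` 1e-9) — inside a fixed-point iteration that stops at 1e-6 on
all four moments. Calibration results are memoized per condition. With
any SD set to 0 the calibration is a no-op, so degenerate configurations
return the configured constants exactly.

### Scanpath synthesis

Trials start on a neutral fixation left of the grid, visit each AOI in
row-major reading order, and end below the grid. Each visited AOI
receives a run of fixation samples realizing the drawn gaze time,
quantized to the sample grid (0.8 ms at 1250 Hz); ground truth records
the *realized* times, so the round-trip identity is exact by
construction. Voice onset of item *N* is placed at entry(*N*) +
gaze(*N*) + *E(N)* on the same clock as the gaze stream; a configurable
constant (`voice_sync_offset_ms`) models recorder desynchronization.

Saccades use the speed profile v(τ) = v₀ + (v_peak − v₀)·16τ²(1−τ)² — a
minimum-jerk-like bump riding on a floor v₀ (default 60°/s, twice the
detection threshold) with peak 200°/s. The floor is a deliberate
departure from a plain minimum-jerk profile: a smooth profile spends
~6 ms per flank below a 30°/s threshold, which would make I-VT event
boundaries irrecoverable at the sample level. With the floor, detected
fixation boundaries match ground truth within ±2 samples and recovered
offset EVS within one inter-sample interval, which the acceptance suite
asserts. Fixation jitter defaults to 0.01° SD per sample — small enough
that windowed velocity noise (≈ 5°/s) stays far below the threshold.

### Artifacts

Injected artifacts with ground-truth labels: blinks (invalid runs inside
a first-pass fixation, placed with ≥ 55 ms valid margins so both
fragments survive the minimum-fixation criterion and the blink falls
inside the visit), signal loss (a contiguous invalid run covering 30 % of
the trial, which trips the strict > 25 % contamination rule), skips (AOI
never fixated; the item still receives a voice onset, anchored on the
time the eyes pass by), regressions (a second-pass revisit inserted after
the next fixated item's first pass), accidental entries (a brief
out-of-order fixation at list onset), and misarticulations (accuracy
flags in the voice annotations). At most one eye artifact is injected
per item, so injected classes are disjoint and the exclusion cascade's
reason counts can be compared label-for-label against ground truth. The
default rates (blink .05, skip .05, regression .10, misarticulation .03,
accidental entry .02, signal loss .05 per trial) are unreported in the
source and were chosen once as realistic for oral multi-item naming,
where roughly a quarter of item × subject cells are typically lost.

Subject and item random intercepts for the stream generator default to
variance 0: the per-condition SDs are *marginal* SDs and already contain
subject and item variance, so adding the mixed-model variance components
on top would double-count. Those components (item 8323, subject 6093,
residual 16684 ms²) are instead the defaults of `simulate_lmm_dataset()`,
the balanced model-level simulator used for fitter validation, whose
unprinted intercept defaults to the HF-long condition mean (191.4 ms).

## Event detection and AOI parsing

Velocity is a central difference over a 5-sample window (4 ms at
1250 Hz), computed within runs of valid samples only — coordinates during
blinks are meaningless, so windows never straddle invalid samples; edge
samples of a run take the nearest interior estimate. The detection
threshold is 30°/s: the source omits the per-second unit, and 30°/s is
the conventional I-VT value at this sampling rate. Samples strictly
above threshold form saccades; complementary runs form fixations;
fixations shorter than 50 ms are *rejected* (re-labelled `discarded`),
not merged into neighbours, matching the wording of the source. Invalid
runs of at most 500 ms bracketed by valid data are blinks, anything else
is signal loss; the source does not define this boundary, so it is a
configurable package choice. Events are half-open [start, end) intervals
on the sample grid and partition the trial duration exactly.

Fixation-to-AOI membership uses the fixation centroid — deterministic
and standard; whether the original analysis used centroid or sample
majority is unknowable from the text. Consecutive same-AOI fixations
form one visit (a blink or a discarded micro-fixation between them does
not split the visit); any fixation landing elsewhere ends it, and
re-entry opens a new pass. First-pass gaze time sums fixation durations
only (intra-pass saccade and blink time excluded), the conventional
gaze-duration definition.

"Accidental eye entries at the onset of the list" is operationalized as:
the item's first visit begins within 1000 ms of trial onset *and* before
the first visit of some item earlier in reading order. The window is
configurable; the source gives no definition beyond the phrase.

## Exclusion cascade

Removals happen in a fixed order — excluded subject, contaminated trial,
misarticulation, blink, skip, accidental entry, second pass, invalid
onset, outlier — and each record is attributed to exactly its first
matching reason, giving the accounting identity input = retained +
Σ reasons that the report renders and the tests assert. The order only
affects attribution, not the retained set. The outlier rule (unspecified
in the source) is a per-condition z-score at 3 SD, applied separately to
offset EVS and GT/PT — hence different retained counts per measure, the
behaviour the source's differing data-point counts imply. Group
statistics can be frozen so re-application is idempotent; degenerate
groups (SD 0) flag nothing.

`crossing_percentile()` implements the literal rule: the smallest integer
percentile whose empirical quantile (linear interpolation, type 7) lies
past the boundary (0 from above for offset EVS, 1 from below for GT/PT),
100 if none does. For the offset direction this statistic saturates near
1 as soon as more than ~1 % of mass is negative; the GT/PT direction
carries the ordering information across conditions and is the one used
in the report.

## Mixed models

`fit_evs_lmm()` fits the Gaussian crossed random-intercepts model by
ordinary ML (never REML) through `lme4::lmer`, so nested fits are
comparable by likelihood ratio: chi² = 2Δlog-likelihood against the χ²
reference with df equal to the added parameter count (familiarity 2,
length 1, interaction 2), no boundary correction. Treatment contrasts
with HF and long as reference levels reproduce the conventional LF−HF,
PW−HF and short−long coefficient labels. The additive and interaction
fits are reported side by side because the two coefficient blocks of the
source's tables belong to different fits. Singular fixed-effect designs
error naming the aliased coefficient; a variance component estimated on
the zero boundary is a legitimate ML optimum and is not treated as a
failure. The |t| > 2 rule is strict at the boundary. The
reading-velocity regression is an ML linear model per subject summary
with a df-1 LRT against the intercept-only model; the source's two
statements about the *direction* of the GT/PT–velocity association
contradict each other, so the package reports the fitted sign and takes
no side.

## Problem sizes and numerical tolerances

Recovery tests run ≥ 1000 items per condition, at which three
Monte-Carlo standard errors are ≈ 12–16 ms for offset EVS and ≈ 0.03 for
GT/PT; the acceptance script uses 3000–8000 items per target (a few
minutes end to end on one CPU). Fitter validation uses the full balanced
36 × 240 design. The OLS-collapse check of the mixed-model fitter is
asserted at 1e-6; quantization of gaze times to the 0.8 ms sample grid
bounds all round-trip comparisons. Single balanced 36 × 240 datasets
carry item-level sampling noise of roughly one printed SE on the
fixed-effect contrasts, so single-fit recoveries are checked at two
printed SEs, while averaged recoveries (over repeated simulations)
converge to the generating values.

## What passing tests do and do not show

The generator produces Gaussian condition distributions, stationary
fixations with small isotropic jitter, ballistic supra-threshold
saccades, perfectly synchronized voice onsets, and artifact classes that
are disjoint by construction. Real recordings have skewed latency
distributions, drift and smooth pursuit-like segments, tracker-specific
noise spectra, co-occurring artifacts, and audio/gaze clock slack. A
green suite therefore certifies the *pipeline* — definitions, algebra,
detection logic, bookkeeping, estimator implementation — under the
study's stated design; it does not certify that the source's empirical
values would be reproduced from new human data. Quantities that depend
on the undeposited human recordings (printed chi² values, crossing
percentiles, retained-record counts) are deliberately checked only for
structure (df, ordering, accounting identities).

## Known limitations

Voice onsets are consumed as annotations; no acoustic segmentation.
No parafoveal-preview or word-skipping model beyond the skip artifact;
no microsaccades, no binocular fusion, no dispersion-based (I-DT)
detection, no random slopes (the source's models converged only without
them), no spatial (character-based) EVS.
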