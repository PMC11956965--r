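---
title: "Methods: sequence-cell and trajectory analysis for a cued-delay working-memory task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-cell and trajectory analysis for a cued-delay working-memory task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The task and the data model

`seqtime` analyzes deconvolved two-photon calcium-imaging recordings from a
differential delayed-non-match-to-sample (dDNMS) olfactory task. Two odors
(A, B) are presented for 1 s each, separated by a delay whose duration is
cued by the identity of the first odor: 2.5 s after the "short" cue, 5.0 s
after the "long" cue. Animals lick during a 3-s response window starting at
second-odor onset; non-match trials are rewarded. Sessions consist of 7
blocks of 20 trials with the four odor pairs balanced within each block, and
20% of trials are *reverse* trials on which the cue-delay contingency is
swapped — the probe for implicit timing: on a reverse trial the delay the
animal experiences contradicts the delay its cue predicted.

All analyses operate downstream of segmentation and deconvolution: the input
is a nonnegative neurons x frames matrix at 30.9 Hz, a trial-event table, and
a 1-D locomotion trace. Times are seconds from session start; frame *i*
(0-based) covers `[i/fr, (i+1)/fr)`. Because 30.9 Hz frames do not divide
seconds evenly, the frame containing time *t* is always `floor(t * fr)` —
one convention used everywhere, so alignment is unambiguous.

The on-disk session container is a directory of plain-text files
(`meta.json`, `activity.tsv`, `locomotion.tsv`, `trials.csv`). The design
brief for this format family is usually HDF5; we chose text because the
toolchain this package must run on has no HDF5 R bindings, and because
`%.17g` formatting makes double-precision round trips exact — a property the
round-trip tests assert byte-for-byte.

## Signal conditioning

Deconvolved traces are smoothed by a rolling mean of 10 frames (0.32 s),
z-scored per neuron over the whole session, and floored: values below 2 are
set to zero. The result is kept on the z-score scale ("firing rate (STD)")
and is the substrate for every downstream stage.

Numerical choices the source convention leaves open:

* **Edge handling and centering.** The rolling mean is centered with edge
  shrinkage (the mean of the available frames near the edges). Whether the
  original chain used a centered or causal window is not documented; a
  centered window avoids a systematic half-window shift of every recovered
  peak time, which matters because peak times are the detection statistic.
* **Z-score scope.** Mean and SD are taken over the whole session per
  neuron, the convention of the antecedent sequence-detection work. A
  zero-variance neuron maps to an all-zero row, never an error.
* Flooring is idempotent: re-flooring conditioned output changes nothing
  (z-scoring is not reapplied).

## Alignment

Activity is aligned to first-odor onset over a `[-2, +11]` s window — the
union of the trajectory baseline window (`[-2, 0]` s) and the
mutual-information display range (`[-1, 11]` s) — and averaged in 5-frame
bins (0.1618 s, printed as 0.16 s). A partial trailing bin is dropped,
never padded: padding would dilute exactly the late-delay bins that carry
the anticipatory effects of interest. At 30.9 Hz the window spans
`floor(13 x 30.9) = 401` frames, i.e. 80 bins.

## Sequence-cell detection

Detection follows the circular-shuffle construction:

1. **Preferred type.** Standard trials starting with each odor are averaged
   separately; the odor with the larger average peak within its analysis
   window (odor + standard delay: 3.5 s or 6 s) is the preferred one. Ties —
   including silent neurons — resolve to the short type and fail downstream.
2. **Shuffle test.** The observed statistic is the maximum of the
   trial-averaged trace in the analysis window. Each of 2000 shuffles
   independently rotates every trial's within-window trace by a uniform
   circular offset (preserving per-trial marginals, destroying trial-locked
   timing), re-averages, and takes the window maximum. The threshold is the
   95th percentile (linear interpolation) of the shuffle maxima; the test
   passes iff observed > threshold, strictly, so shift-invariant activity
   always fails.
3. **Reliability.** The fraction of preferred trials with a >= 2 STD event
   within 0.5 s of the peak (closed interval) must reach 20%. The two
   reliability clauses in the source description are read as this single
   combined criterion, with both thresholds exposed as parameters.

One seeded RNG stream is consumed in neuron order, so detection is
reproducible byte-for-byte.

**Calibration and the selection effect.** On stimulus-independent neurons
the shuffle test on a *given* trial-type slice is exactly calibrated: the
null pass rate is the percentile complement (5%), which the acceptance
suite verifies on 1000 synthetic noise neurons. Step 1, however, selects
the larger of two peaks before testing, and testing a selected maximum
against its own marginal null roughly doubles the null pass rate (to ~10%
empirically). This selection effect is inherent to the published procedure,
not an implementation artifact; the reliability filter removes most of the
surviving null cells (the pipeline-level false-positive rate on pure-noise
sessions is near zero in the tests). Users comparing significant-cell
fractions across datasets should be aware that the shuffle p-value alone is
not selection-corrected.

Peak-distribution analyses compare the two sequences over the shared first
3.5 s (two-sample KS on pooled peak times) and per-session fractions of
peaks in 0.5-s bins, compared with paired t-tests across sessions and
Benjamini-Hochberg adjustment across bins.

## Trajectory geometry

Condition-averaged population trajectories use the significant cells
preferring the condition's first odor (short-trial cells for cued-short
conditions, long-trial cells for cued-long conditions; the union is
available behind a flag but off by default). Whenever a reverse condition
is compared against a standard one, trial counts are balanced first by
nearest-neighbor matching: each reverse trial takes the unused eligible
standard trial with the smallest trial-index distance, ties toward the
earlier trial. Index distance is used because the trial index is the only
ordering the session record preserves.

*Distance from baseline* is the Euclidean distance, in full dimensional
space, between the population vector at a bin and the mean pre-odor
(`[-2, 0]` s) vector; *speed* is the distance between neighboring bins.
Both are divided by the square root of the number of cells used, making
them invariant to duplicating the cell set and comparable across sessions.
PCA is fit on the concatenated condition means for visualization only;
no statistic is computed in the reduced space.

Per-bin condition comparisons across sessions test the per-session
difference with animal and day as categorical factors. The original
description ("two-way ANOVA animal and day") underdetermines the model —
whether condition entered as a third factor or differences were tested is
not stated. We test the intercept of `difference ~ animal + day` under
sum-to-zero contrasts: the condition effect adjusted for both factors.
BH adjustment runs across bins with a rejection mask at adjusted p < 0.01.

## Odor information and time decoding

**Mutual information.** Activity is discretized per neuron into 20 uniform
levels of `[0, max]` (`level = min(floor(v / max * 20), 19)`; the boundary
convention is ours, the source states only "based on the maximal value").
For each neuron and target bin, MI is computed between bin identity
(baseline bin at -1.5 s vs target) and activity level with the plug-in
estimator, no bias correction, then averaged across neurons. Since the bin
identity is binary, MI is bounded by 1 bit. The baseline at -1.5 s sits
outside the displayed `[-1, 11]` s range; both defaults are preserved
as-is rather than reconciled. Balancing trial counts between compared
conditions mitigates the count-asymmetry bias of the plug-in estimator.

**Time decoding.** Elapsed time within the short delay is decoded from
population vectors between the 1.1 and 3.4 s time points as 7 classes of
1/3 s (the printed window and bin width divide only "within rounding";
the class count is `round(2.3 / (1/3)) = 7`). The published scheme is a
multiclass SVM with one-vs-one error-correcting output codes; the
toolchain here ships no SVM, so the package implements the same
construction directly — a linear max-margin classifier (primal
squared-hinge objective, deterministic L-BFGS fit) per class pair with
vote-count aggregation. The cross-validation scheme is unstated in the
source; we use stratified 5-fold CV over *trials*, keeping all time bins
of a trial in one fold, because splitting a trial's bins across folds
leaks within-trial correlation and inflates scores — the standard pitfall
in time decoding. The score is the Pearson correlation of actual and
predicted class indices (0 chance, 1 perfect), defined as 0 when the
predictions are constant.

## Behavior and locomotion

A non-match trial is correct iff a lick falls in `[onset2, onset2 + 3)`
(half-open; boundary inclusion is not documented in the source, so the
choice is ours and tested); a match trial is correct iff no lick does.
Latency is the first in-window lick minus second-odor onset, summarized as
the per-session median per category (all responded trials by default, a
flag restricts to correct trials). Locomotion is binned to 5-frame means,
z-scored over the session, floored below 1; running bouts are maximal runs
above 1 lasting at least 1 s (closed threshold), and a trial is "running"
iff a bout intersects its delay period.

## The synthetic world

The generator emits the conditions the analyses assume, with ground truth
retained, so every stage has a parameter-recovery test:

* **Schedule.** 7 blocks x 20 trials, pairs balanced within block, exactly
  `round(0.2 x 140) = 28` reverse trials — enforced by count, not sampled,
  because the rate is fixed by design and is an exact test target. The
  inter-trial interval is not documented anywhere; the default is a fixed
  10 s, configurable, and claimed only to be plausible. Tests use 2 s to
  cut frame counts — all analyses are within-trial, so the ITI is compute,
  not statistics.
* **Cells.** Sequence cells have Gaussian temporal fields (SD 0.25 s,
  amplitude 6 raw units against a half-normal noise floor of SD 0.3)
  centered uniformly over odor + standard delay of their preferred cue,
  expressed on each preferred trial with probability 0.6 (trial
  reliability), and clipped at second-odor onset — so reverse-short trials
  truncate late long-cue fields, as in the recordings. A configurable
  over-representation weight moves field centers into the last 0.5 s of
  the short delay (default 0.1); second-odor-responsive cells (8 per odor)
  give the MI curves their second peak; noise cells carry background only
  (Poisson impulses at 0.05 events/s everywhere). Calcium-indicator
  dynamics are *not* simulated: all analyses operate post-deconvolution,
  so the generator emits deconvolved-like transients directly.
* **Scale.** The default session has 400 neurons with ~14% planted
  sequence cells, matching the published per-day scale (405 +/- 187 active
  neurons, 13.9 +/- 12.1% significant). Tests and the acceptance report
  use smaller cell counts where the criterion does not fix them; planted
  effect sizes, rates and thresholds are never scaled.
* **Behavior.** Category accuracies default to the published means
  (87.5 / 86.5 / 86.8 / 80.8% for standard-short / standard-long /
  reverse-short / reverse-long), latency is normal with mean 563 ms and
  SD 243 ms plus a +21 ms reverse shift, truncated into the response
  window with a warning. Locomotion is low-amplitude noise, 0.2-s twitches
  at odor onsets, and 1-2.5-s delay bouts in 15% of trials.

What a green test does *not* establish: the generator has no imaging noise,
no drift, no correlated (shared-variability) noise across neurons, no
lapse structure in behavior beyond per-category Bernoulli outcomes, and no
relationship between locomotion and neural activity. Recovery results on
this world bound implementation correctness, not in-vivo effect sizes.

The planted-effect acceptance runs use an over-representation weight of
0.3 — chosen once, before measuring, as the "planted effect present"
condition (the criterion requires only weight > 0; the generator default
stays 0.1, which mimics the modest published asymmetry). The
trajectory-speed recovery uses 12 synthetic sessions (6 animals x 2 days),
mirroring the published 22-session layout at reduced scale.

## Known limitations

* The shuffle-test selection effect described above: per-neuron p-values
  are not corrected for the preferred-type selection, matching the
  published procedure.
* The ANOVA reading for per-bin comparisons is one of several defensible
  interpretations; it is applied uniformly, never mixed.
* The decoder's regularization (unit cost) and the squared-hinge loss are
  implementation choices within "linear max-margin"; scores are not
  guaranteed to match any particular SVM library to the third decimal,
  only the construction and its calibration (chance at 0, separable at 1)
  are contractual.
* MI uses the uncorrected plug-in estimator; with 20 levels and tens of
  trials it is biased upward by a few hundredths of a bit, visibly so at
  baseline. The balancing step equalizes this bias between compared
  conditions rather than removing it.
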