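---
title: "Methods: oculomotor analysis of visual associative memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oculomotor analysis of visual associative memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gazemem` implements an end-to-end analysis of eye-tracking behaviour during
a visual associative-memory task, from raw gaze/pupil streams to oculomotor
events, per-trial scanning features, event-locked pupillometry,
nonparametric condition statistics, and trial-level decoding. Because no
public dataset exists for this paradigm, the package also contains a
first-class synthetic-data generator that emulates the task and the cohort
structure; every stage of the pipeline is validated against that
generator's ground truth. This vignette explains the models, the defaults
and their units, the numerical choices, and what the synthetic validation
does and does not establish about real recordings.

## The task and the cohort model

The paradigm is a cue-target-lure object-association test. After an
exposure block (pairs of objects shown for exactly 1 s each), each
retrieval trial shows a cue object on the top row and two candidate
associates on the bottom row; the subject clicks the associate that was
paired with the cue (the *target*) rather than the foil (the *lure*).
Retrieval is untimed: a trial lasts until the response. There are 60
exposure trials and 90 retrieval trials per subject — two blocks of 30
*direct* associations and one block of 30 *indirect* associations
(inference across episodes), with chance performance at 50%.

The default cohort is 14 healthy controls (HC) and 30 temporal-lobe
epilepsy (TLE) patients. TLE is associated with hippocampal dysfunction and
impaired relational memory, which surfaces in this task as lower accuracy
and a less organised visual search even on correct trials. The behavioural
defaults of `sim_config()` encode the conditions the package is built
around:

| parameter | HC | TLE | units |
|---|---|---|---|
| direct-retrieval accuracy (mean, SD) | 0.90, 0.07 | 0.83, 0.11 | proportion |
| saccades per correct trial | 9.86 | 13.38 | count |
| first fixation on target, correct trials | 0.76 | 1.12 | s |
| fixation-scatter SD (entropy mechanism) | 35 | 60 | px |

and per condition (identical for both groups, as the condition effect):

| parameter | correct | incorrect | units |
|---|---|---|---|
| trial duration (mean, SD) | 3.83, 1.12 | 4.79, 1.75 | s |
| late-bin AOI weights (cue/target/lure) | .25/.50/.25 | .25/.30/.45 | probability |

Indirect-trial accuracy defaults to the subject's direct accuracy minus
0.15. Incorrect-trial saccade counts scale the correct-trial means by the
duration ratio (more scanning in longer trials).

## The trial generator

A retrieval trial is assembled in schedule space and then rendered into
samples:

1. **Duration** `D` is drawn from the condition's truncated normal
   (lower bound 0.8 s — a fast mouse response).
2. **First-target latency** `L` comes from the group's distribution,
   truncated to `[0.2 s, 0.6 D]`. Truncating the latency rather than
   stretching the trial keeps the realised duration distribution unbiased
   at its configured mean; the cost is a slight (\<2%) downward pull on the
   realised latency for very short trials.
3. **Saccade count** is negative-binomial (dispersion 30) with mean scaled
   by `sqrt(D / E[D])`: longer trials accumulate more saccades. The
   square-root coupling preserves the configured marginal mean to first
   order while making count/duration combinations jointly feasible — the
   printed count, duration, and inter-saccade-interval statistics are not
   mutually consistent under any independent generator, and we deliberately
   do not force the pooled 0.26 s inter-saccade interval.
4. **The AOI schedule** starts on the cue, first lands on the target at
   `L`, and afterwards hops between AOIs under a time-inhomogeneous
   categorical rule driven by per-250-ms bin weights: on correct trials the
   target weight rises through the 750–1000 ms bins and dominates
   afterwards; on incorrect trials the lure takes over. Fixation landing
   points scatter around box centres with the group's spatial-jitter SD
   (clipped inside the box); consecutive same-AOI fixations are forced at
   least 200 px apart so that every rendered saccade has a resolvable
   amplitude (≈3° at the default geometry).
5. **Kinematics.** Saccades are sigmoidal position ramps obeying the main
   sequence `duration = 21 ms + 2.2 ms/deg × amplitude`; fixation durations
   are gamma-distributed shares of the remaining schedule time with a 60 ms
   floor. Pixel-to-degree conversion uses a pinhole model: 1920×1080 px on
   a 34.5×19.4 cm panel viewed at 64 cm (≈0.016°/px).
6. **Pupil.** Diameter is a 3.5 mm baseline plus a slow random-walk drift
   plus one biphasic kernel per saccade: a Gaussian constriction lobe
   (−0.04 mm at 0.25 s, width 0.09 s) followed by a gamma-shaped dilation
   lobe (+0.06 mm peaking at 0.8 s). Saccades landing on the target in
   correct trials multiply the dilation lobe by 1.6 — the generator's
   encoding of retrieval-success pupillometry.
7. **Signal loss.** Blinks (Poisson 0.1 Hz, 0.1–0.3 s) are placed inside
   fixation intervals — lids close during fixations, not mid-saccade — and
   invalidate gaze and pupil. A separate tracker-dropout event (probability
   0.065 per trial, covering 30–60% of it) models the head movements and
   tracking losses that make whole trials unusable; it is what produces the
   ~5–10% trial-exclusion rate, since blinks alone cannot push a
   several-second trial past the 30% invalid threshold.

Exposure trials are exactly 1 s, alternate between the two object boxes,
and carry no group or condition effect.

Between-subject heterogeneity enters as log-normal multipliers (SD 0.08 on
the log scale) on each subject's count and duration means. This is smaller
than the between-subject spread the task shows in practice; it is chosen so
that a 44-subject cohort estimates the configured group means to ~1–3%,
which is what makes parameter-recovery testing meaningful at desk scale.

## Event detection

Velocity is the two-sided five-sample finite difference
`v_i = (p_{i+1} + p_{i+2} - p_{i-1} - p_{i-2}) / (6 dt)` in deg/s; the
stencil doubles as the smoothing filter, so no separate low-pass is applied
(a second smoother at 90 Hz would smear saccade onsets). Saccades are
detected with an adaptive elliptic threshold at `lambda = 6` times the
per-trial median-based robust SD `sqrt(median(v^2) - median(v)^2)` per
axis; supra-threshold runs of at least 3 samples are candidates, candidates
separated by less than 20 ms merge, and inter-saccade intervals of at least
50 ms become fixations labelled by centroid containment in the AOI boxes
(half-open `[x0,x1)×[y0,y1)` pixel rectangles, so edge points are
unambiguous). All four constants are exposed in `event_params()`. On
generated kinematics the detector recovers the injected per-trial count
within ±1 on ≥95% of trials and the group means within a few percent; the
residual misses are saccades adjacent to residual invalid spans.

## Features

Dwell ratios are computed from raw valid samples (time in AOI over valid
trial time), not from fixation sums — this makes them robust to detector
settings; fixation-based timing enters separately as mean fixation duration
and first-target-fixation latency. A between-object saccade is one whose
endpoints lie in two different stimulus AOIs. Scanpath entropy is the
Shannon entropy of the gaze occupancy map on a 48×27 grid (40 px cells at
the default screen) smoothed with a 1-cell Gaussian; absolute entropies
depend on the grid and smoothing, which the source studies do not publish,
so the package asserts only orderings (TLE above HC, incorrect above
correct), never absolute bit values. Trials that never fixate the target
have an undefined latency; for decoding it is imputed with the trial
duration (the longest latency the trial could exhibit), and the imputation
happens before fold-wise median imputation so it is identical in every
fold. Windowed features recompute everything on `[0, T)` with events
truncated at `T`.

## Pupillometry

Pupil diameter is z-scored across each subject's entire session — not
per-epoch baselined, because the pre-saccade diameter is itself shaped by
the previous saccade's response at these inter-saccade intervals. Epochs
are cut from −0.25 to +1.25 s around saccade initiation (or fixation
onset), linearly resampled to a 100 Hz grid, dropped when more than 30% of
the window is undefined (mirroring the trial-level rule), and averaged
pointwise; the mean is reported only where at least half the epochs are
defined. The window and rate are configurable; nothing in the analysis is
sensitive to them beyond the visible support of the kernel.

## Statistics

Group and condition contrasts use midrank Wilcoxon rank-sum tests on
subject-level means (the exchangeable unit is the subject, never the trial,
to avoid pseudo-replication). The implementation reports a z statistic from
the tie-corrected normal approximation with continuity correction and
switches to the exact enumerated distribution for small tie-free samples.
Binned dwell time courses (250 ms bins) are compared bin-wise and corrected
with Benjamini–Hochberg FDR. Pupil traces are compared with a
cluster-corrected permutation test: pointwise rank-sum z, clusters formed
at two-sided p \< 0.05, observed cluster mass (sum of |z|; extent is
available) referred to the permutation distribution of the maximum cluster
mass under random relabelling of subject traces, with
`p = (1 + #{perm ≥ obs}) / (n_perm + 1)` so p can never fall below
`1/(n_perm+1)`. The permutation loop reuses one precomputed per-timepoint
rank matrix, so a 1000-permutation test on 44 subject traces runs in
milliseconds.

## Decoding

Both protocols use a linear-kernel soft-margin SVC (`e1071`, cost 1) inside
stratified 5-fold cross-validation: per fold, training-median imputation,
training-set z-scoring applied to the test fold, and class weights
inversely proportional to training-class frequency. Out-of-fold decision
scores are pooled into one rank-based (Mann–Whitney) AUC. The *accuracy*
protocol decodes correct vs incorrect on direct trials only (indirect
trials are systematically longer and would leak duration into the label);
folds are trial-wise. The *diagnosis* protocol decodes HC vs TLE on correct
trials with subject-grouped folds by default, because trial-wise folds let
the model recognise subjects rather than diagnoses; the trial-wise variant
remains available as a config switch. Permutation feature importance
shuffles one feature column 100 times, rescores the frozen fold models
without refitting (the wording "keeping all other features unchanged"
describes score-time permutation), and reports the mean increase in loss
`1 − AUC`. A linear model keeps these importances interpretable as
direction-free effect sizes.

## What the synthetic validation shows — and does not

Passing tests establish that the measurement chain is unbiased and
calibrated *on data generated by this package's own model*: configured
durations, counts and latencies are recovered through cleaning, detection
and feature extraction; null simulations put the rank-sum type-I error and
the cluster-test family-wise error at their nominal 5%; null decoders sit
at AUC 0.5 and separable ones at 1.0. They do not establish that real
recordings satisfy the model: real saccade kinematics, drift, microsaccades,
pupil foreshortening, luminance responses, and calibration error are all
absent or simplified (jitter stands in for the entire entropy mechanism),
and absolute entropy values are grid-dependent by construction. Orderings
and calibration transfer; absolute synthetic AUCs do not.

## Numerical choices and degenerate inputs

Robust velocity SDs are floored at 0.1 deg/s so that noise-free traces do
not produce a zero threshold; a constant pupil is a zero-variance error
rather than a silent NaN; empty trials are excluded with a reason;
permutation p-values are floored at `1/(n_perm+1)`; exclusion decisions are
computed on raw pre-interpolation counts and are therefore invariant to
sample order; gap interpolation (off by default for feature counting, on
for pupillometry) never alters valid samples and refuses gaps longer than
75 ms — blinks longer than that are data actually missing, not data to
invent.

## Problem sizes

The validation suite runs the full 44-subject default cohort once
(~4000 retrieval trials at 120 Hz) and reuses it across checks; null
calibration uses 2000 rank-sum replicates and 400 cluster-test replicates
at 199 permutations; the detector-recovery property uses 150 generated
trials; decoding nulls use 1000 trials × 10 features. These sizes give
standard errors several times smaller than every tolerance they are tested
against.
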