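---
title: "Methods and design choices in pawtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in pawtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pawtrack)
```

pawtrack analyzes per-frame body-part coordinates from markerless pose
estimation. This vignette documents the models and conventions the package
commits to, why its defaults are what they are, and what its synthetic-data
tests do and do not demonstrate about real recordings.

## Coordinate and indexing conventions

Everything downstream depends on a handful of conventions, so they are
fixed once, here:

* **Image coordinates.** The origin is the top-left pixel; x grows
  rightwards and y grows *downwards*, matching pose-estimation output.
  Consequently `orientation()` angles of +π/2 point "down" on screen;
  `to_math_angle()` converts to the y-up convention, and the plot helpers
  reverse the y axis so figures match the video.
* **0-based, contiguous frames.** Frame indices run 0..n−1 after loading;
  `select_time_window()` keeps `[floor(start·fps), floor(end·fps))` —
  half-open, so adjacent windows tile a session without overlap — and
  re-zeroes the index while recording the original offset.
* **Half-open boundaries throughout.** Rectangular areas contain a point
  iff origin ≤ p < origin + size (circles are closed, ‖p − c‖ ≤ r);
  occupancy bins are half-open with the last edge closed; signal epochs
  cover samples `[round((start−t0)·rate), round((end−t0)·rate))`. These
  rules make every count and every event list bit-reproducible.

## Conditioning tracked points

Pose estimators attach a likelihood to each point; points below a cutoff
(0.9 is a common operating point) are unreliable. The estimator's output
does not say what to *do* with them, and the options differ materially:
dropping frames corrupts speed estimates (a dropped frame doubles the
apparent step of its neighbor), and forward-filling freezes the animal.
`apply_likelihood_cutoff()` therefore replaces sub-cutoff runs by **linear
interpolation** between the nearest reliable frames (boundary runs take the
nearest reliable value). This keeps the kinematic series continuous, is
idempotent at a fixed cutoff, and the per-part count of conditioned frames
is attached to the result so silent repair is impossible. A body part with
no reliable frames at all is an error, not a guess.

## Kinematics

With positions p₀…pₙ₋₁ and frame rate `fps`, displacement is
dᵢ = ‖pᵢ − pᵢ₋₁‖, speed vᵢ = dᵢ·fps, acceleration aᵢ = (vᵢ − vᵢ₋₁)·fps,
with v₀ = a₀ = 0: first-order backward differences, **no smoothing by
default**. Raw pose jitter inflates speed, so a centered moving-average
smoother (odd window) is available but off — reported metrics should never
be silently filtered. `mean_speed` averages the n−1 realized steps, which
equals total distance divided by elapsed time. Calibration is a single
isotropic scale from one known physical reference (cm per pixel); lens
distortion and homographies are out of scope, so distances and speeds scale
exactly linearly with the calibration factor.

## Areas and interaction events

An interaction is point-in-region of a *single chosen body part* (the
snout, for object exploration), not a proximity threshold: maximal runs of
consecutive in-area frames become events with inclusive frame bounds and
duration (end − start + 1)/fps. No minimum-duration debounce is applied by
default (a `min_frames` parameter exists), because debouncing changes
interaction counts and belongs in the analyst's hands. The legacy
8-element positional area vectors of other toolkits are importable via
`import_positional_fields()`, which interprets the last four entries as
x, y, width, height; that importer is a compatibility heuristic — the
first four entries have no documented meaning — and new code should use
`area_rect()`/`area_circle()`.

## Unsupervised behavior classification

### Features

Frame t is described by the distances between all unordered pairs of the
chosen body parts (k parts → k(k−1)/2 columns, lexicographic pair order).
Pairwise distances are invariant to the animal's position and heading, so
only posture differentiates frames. Distances are **not z-scored by
default**: raw distances weight long body segments (snout–tail) more than
short ones (ear–ear), which concentrates the clustering on gross posture.
A `standardize` flag equalizes the columns for users who want fine posture
to count equally; switching it changes the meaning of the cut threshold.

### Ward clustering and the cut threshold

Frames are agglomerated with Ward linkage on Euclidean feature distances
(`stats::hclust`, method `ward.D2`, whose merge heights equal the
√(2·ΔESS) criterion — the test suite verifies this against an O(n³)
brute-force agglomeration that recomputes the criterion for every candidate
pair at every step). Clusters are the connected components after undoing
every merge higher than `distance_threshold`. The threshold is in merge-
height units **of the feature space**: the same number cuts pixel-space
and cm-space features at different granularity, so the units are echoed in
the result and the choice is deliberately user-facing. Labels are
re-indexed by decreasing cluster size (ties broken by first-occurring
frame), so cluster 0 is always the dominant behavior and output is
deterministic. Frames are classified independently; an optional sliding
mode filter (`mode_filter()`, default off) suppresses single-frame label
flickers for users who want temporally smoothed ethograms.

### t-SNE and its hyperparameters

The 2-D behavior map uses an exact (dense) t-SNE implemented in the
package: Gaussian input similarities with per-point bandwidths bisected to
the target perplexity, Student-t output kernel, gradient descent with
momentum (0.5 → 0.8 at iteration 250), adaptive gains, and 12× early
exaggeration for the first 250 of 750 iterations. Three heuristics
known to stabilize embeddings of large frame sets are applied:

1. **PCA initialization** — the first two principal components scaled to
   a standard deviation of 10⁻⁴, which preserves the global arrangement
   and, being deterministic, makes the whole embedding a pure function of
   the input;
2. **learning rate η = n/12** — followed exactly as stated by its source;
   η is a step size, so small n merely converges more slowly, and no lower
   clamp is imposed;
3. **perplexity = n/100, clamped below at 5** — unlike the learning rate,
   a perplexity below ~5 degenerates (the effective neighborhood
   collapses to nothing), so the clamp engages for n < 500. A hard
   floor of n ≥ 30 guards the perplexity validity constraint
   perplexity < (n−1)/3.

### Embedding-quality scores

* **KNN** (local): mean fraction of each point's k nearest feature-space
  neighbors preserved among its k nearest embedding neighbors; k = 10 by
  default. Under a random embedding its expectation is k/(n−1).
* **KNC** (mesoscale): same preservation computed on class centroids;
  classes are the Ward clusters themselves, since no external labels exist
  in an unsupervised setting. k_class defaults to min(4, C−1).
* **CPD** (global): Spearman correlation of pairwise distances in feature
  space vs the embedding over a seeded subsample (default 1000 points,
  keeping the O(m²) pair count bounded).

All three depend only on distance ranks, hence are invariant to rotation,
translation and uniform scaling of the embedding. An identity embedding
scores (1, 1, 1) up to ties; the test suite calibrates the permutation
null against the k/(n−1) expectation.

## Neural coupling

Synchronization is an explicit contract: sample 0 of a `signal_record`
occurs at `t0_s` seconds relative to video frame 0, supplied by the user
(no sync-pulse detection). Epochs cut at behavior or interaction
boundaries use the half-open round-to-nearest sample rule above, so a
partition of the session reconcatenates to the original signal
sample-for-sample. `spatial_activity()` expects one activity value per
frame — spike counts within the frame's duration, or a continuous signal
already averaged per frame (the reduction is the user's choice and is not
implied) — and returns the per-bin mean alongside the visit counts, so the
visit-weighted mean recovers the global mean exactly and empty bins are
`NA`, never 0. Spectrogram rendering of extracted epochs is left to
standard signal-processing tools; the epoch matrices are ordinary numeric
matrices.

## Synthetic data: what it shows and what it does not

The generators emit ground truth next to every fixture:

* `make_trajectory()` — constant-velocity (exact closed-form distance,
  using duration·fps + 1 frames so distance = speed·duration exactly),
  circular (chord-sum closed form, converging to 2πr), and bounded random
  walks (reflected at the arena walls so occupancy stays well defined).
  Optional seeded dropouts with corrupted coordinates exercise the
  likelihood conditioning.
* `make_behavior_frames()` — per-cluster body-part geometry templates
  drawn in a body-centric frame and placed each frame by a seeded random
  rotation + translation before coordinate noise. Absolute position
  carries no class information *by construction*, which is what makes the
  translation/rotation-invariance of the feature matrix a meaningful test.
  Templates are redrawn until mutually separated in feature space
  (default: separation ≥ the 60 px template scale, noise 2 px, giving
  separation/within-spread ratios around 8–10, comfortably above the 5×
  regime where recovery is expected); the achieved ratio is reported, not
  assumed.
* `make_event_signal()` — a sinusoidal carrier in Gaussian noise whose
  amplitude is multiplied by a gain inside event windows; in/out-of-event
  variances have the analytic form (g·a)²/2 + σ² vs a²/2 + σ².

Passing these tests shows the *computations* are correct — distances sum,
events match a per-frame oracle, Ward trees match brute force, generative
labels are recovered when clusters are genuinely separated. It does not
show that real behavior forms well-separated posture clusters, that a
given cut threshold yields meaningful ethological classes, or that pose
jitter resembles Gaussian noise; naming clusters still requires inspecting
representative frames (`representative_frames()` ranks frames by distance
to the cluster medoid for exactly that purpose).

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data at
deliberately modest sizes — behavior scenes of 80–240 frames, t-SNE at
n ≤ 200 with 300–750 iterations, 200 randomized interaction scenarios,
50 brute-force Ward trees at n ≤ 40, 60 s of 1 kHz signal — sizes at which
the exact O(n²) t-SNE and O(n³) oracles are fast while still exercising
every code path; real sessions (10⁴–10⁵ frames) use the same code with
proportionally longer runtimes. Other numerical commitments: Ward heights
are compared to oracles at 10⁻⁸ relative tolerance (pure floating-point
noise); perplexity bisection runs 50 iterations to tolerance 10⁻⁵;
coincident body parts yield `NA` orientation rather than an arbitrary 0;
degenerate zero-variance PCA columns fall back to a zero second component;
exact distance ties in `representative_frames()` are broken by a seeded
shuffle so output never depends on sort stability.

## Known limitations

Single-animal only (no identity tracking); 2-D top-down geometry (no 3-D
kinematics or gait); isotropic calibration (no lens correction); rectangle
and circle areas only (no polygons); cluster naming is human inspection by
design; vendor acquisition formats must be converted to the CSV + JSON
sidecar layout upstream; and the exact t-SNE is O(n²) per iteration —
embedding very long sessions benefits from windowing or frame subsampling
before `tsne_embed()`.
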