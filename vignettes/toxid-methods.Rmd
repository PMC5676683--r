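---
title: "Methods: occlusion-robust identity tracking by fragment linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occlusion-robust identity tracking by fragment linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxid)
```

## Overview

`toxid` tracks multiple visually similar animals in grayscale video and
preserves each individual's identity across occlusions. The design premise
is that per-frame data association cannot be trusted through a crossing, so
the tracker *cuts* trajectories whenever two tracks converge on one
detection and defers the identity question to a later linking stage that
compares whole fragments by appearance. Everything up to the linking stage
is strictly online: frame `k` is processed using only frames `≤ k`, and the
linker needs only the stored per-detection features, never the pixels.

This vignette documents the model, the tunable parameters, the synthetic
scenes used for validation, and the numerical and design decisions taken at
points where the procedure is genuinely open.

## Detection model

Animals are dark bodies on a bright, constant background (a configuration
flag inverts the polarity). A frame is thresholded, 8-connected components
are extracted and filtered to `[min_size, max_size]` pixels, and each blob
becomes a detection carrying:

* the **center of mass** (unweighted mean of pixel centers; coordinates are
  0-based, `x` = column, `y` = row),
* the **size** in pixels,
* the **ROI histogram**: the rectangle enclosing the blob is min–max
  contrast-stretched to `[0, 255]` and binned into `kn` (default 32) equal
  half-open bins, with 255 itself counted in the top bin so mass is
  conserved; a constant rectangle maps to all zeros,
* the **seven Hu moment invariants** of the blob's normalized intensities
  (background pixels of the rectangle are zeroed first, so arena texture
  does not leak into the shape descriptor; a flag switches to the binary
  silhouette, which is also the automatic fallback for a perfectly uniform
  body whose masked intensities are all zero),
* the detection **time** `frame / fps`.

The histogram is computed over the whole enclosing rectangle, background
included. The rectangle was preferred to the masked blob as the default
because the normalization anchor (background ≈ max) makes histograms
comparable across body orientations; a masked variant would be a one-line
change and both carry the same information on the synthetic scenes.

8-connectivity was chosen over 4-connectivity because thin diagonal bodies
(tails, antennae) otherwise shatter into multiple components.

## Fragment creation

Each open fragment maintains a constant-velocity Kalman filter (state
`(x, y, vx, vy)`, position-only measurements, process noise `1e-2`,
measurement noise `1.0`; time is measured in frames). Detections of a frame
are matched to the fragments' one-step-ahead predictions by Hungarian
assignment over Euclidean distances; rectangular cases are padded internally
with a large sentinel.

Gates are applied **after** the global assignment; a rejected pair
deactivates the fragment and the detection starts a new fragment (the
assignment is not re-run). The rules, in the order applied per frame:

1. **Occlusion cut** (before matching): if two or more fragment predictions
   lie within `proximity_limit` of one detection, all of them are closed
   (`proximity`) and the detection starts a fresh fragment. Both fragments
   are cut — at that point there is no evidence which of them the surviving
   blob continues.
2. **Cost gate**: matched cost above `cost_limit` closes the fragment
   (`cost_gate`).
3. **Size gate**: symmetric relative size change above `size_change_limit`
   (default 1.0) closes the fragment (`size_gate`). The symmetric form
   `(S_big − S_small) / S_small` is zero only at equality and treats growth
   and shrinkage alike.
4. **Loss**: a fragment unmatched for more than `max_missed_frames`
   (default 10) consecutive frames is closed (`lost`).

`cost_limit` and `proximity_limit` default to `NULL` and are then estimated
from the first frame with detections as 4× and 1.5× the median blob
diameter `2·sqrt(S/π)` — the only data-dependent defaults, both
config-exposed in pixels.

The same stepping function drives batch and streaming use
(`tracker_new()` / `tracker_step()`), so the two are bit-identical by
construction, and the test suite asserts it.

## Fragment similarity and the IdMatrix

For two fragments the detection cross product (capped at `max_pairs` =
10,000 by a seeded, order-independent subsample) is filtered to pairs of
similar shape and size, and each surviving pair contributes the Pearson
correlation of its two ROI histograms. The similarity is

$$\mathrm{Sim}(f_R, f_C) = A \sum_{L=0}^{L_n - 1} w_L\, r_L,$$

with `A` the maximum correlation (clamped to 0 if negative), `r_L` the
fraction of correlations falling in level `L` of `[0, 1)` (`Ln` = 10
levels; exactly 1 goes to the top level; negative correlations count in the
denominator but in no level), and `w_L` the **unnormalized** Gaussian
`exp(−(m_L − μ)² / 2σ²)` at the level midpoint, `μ = 1`, `σ = 0.05`. The
unnormalized kernel (maximum 1 at `μ`) keeps `Sim` on a comparable scale
across `σ` choices; a probability density would rescale it by an arbitrary
constant. With `σ = 0.05` essentially only the top level carries weight
(`w = e^{−1/2} ≈ 0.61` at midpoint 0.95, `e^{−4.5} ≈ 0.01` one level
down), which is what makes the statistic discriminative even when a shared
background component inflates all correlations.

The shape filter deserves a note. The per-pair shape distance is the sum of
absolute differences of reciprocal Hu components. Raw Hu invariants span
some ten orders of magnitude (`h1 ≈ 0.2`, `h7 ≈ 1e−10`), so raw
reciprocal differences are dominated by the smallest components and no fixed
threshold separates anything. The filter therefore compares reciprocals of
`sign(h)·log10|h|` — the convention long used for contour matching — which
keeps the sum O(1) and makes the default `shape_diff_limit = 2.0`
meaningful. `shape_diff()` exposes both modes; the raw form follows the
printed formula exactly and is the exported default, the log form is what
the pipeline's filter uses. Reciprocals are floored at `hu_epsilon`
(`1e-8`, and `1e-4` on the log scale) so near-zero components cannot
produce infinities.

The `IdMatrix` entry for fragments `R, C` is 1 on the diagonal, exactly 0
when the fragments' inclusive frame intervals overlap (coexisting fragments
are different animals by definition; fragments that merely abut are
compatible), and otherwise the Pearson correlation of the two fragments'
`Sim` profiles against all *other* fragments, clamped to `[0, 1]`. The
self-entries `J ∈ {R, C}` are excluded from the profiles — including the
diagonal 1s would inflate every correlation. Negative profile correlations
are clamped to 0 because the entry is used as a likelihood-like weight.
When the profile correlation is undefined — fewer than two other fragments,
or a constant profile (a fragment similar to nothing else) — the entry
falls back to the pairwise similarity normalized by the largest off-diagonal
similarity.

## Identity assignment

Fragments with fewer than `min_fragment_samples` (25) samples are discarded;
the rest split into long (≥ `long_limit` = 50 samples) and short pools.

1. **Anchoring.** Among long fragments, *complete groups* — sets of exactly
   `n_animals` fragments all simultaneously alive at some frame — are found
   by an interval sweep. The first group's members receive identities
   `1..n` in start-frame order: the first detected fragments define what
   "identity k" means, which is also how the evaluation's reference
   identities are chosen.
2. **Group matching.** Each later group is matched to the labeled set by
   Hungarian maximization of the best IdMatrix value against each identity;
   a candidate pairing that would make two coexisting fragments share an
   identity is forbidden, and a member whose best achievable score is zero
   stays unassigned.
3. **Greedy completion.** Remaining fragments are assigned one at a time by
   the largest IdMatrix entry linking an unassigned fragment to any labeled
   one — exhausting the long pool before the short pool — until the best
   value falls below `min_correlation` (default 0.5). Ties break by earlier
   start frame, then lower fragment id. After each assignment the working
   matrix is updated: entries that would now pair a fragment with an
   identity one of whose members it coexists with are zeroed, as are the new
   member's entries toward other identities. These two zeroing rules encode
   exactly the hard constraints a new label creates, and they propagate —
   each assignment sharpens the matrix for the next choice.

If no complete group exists, identities are anchored on the **largest
simultaneously coexisting set** of long fragments (reported with a message).
Coexisting fragments are provably distinct animals, which is what an anchor
set must guarantee; anchoring on non-coexisting fragments (e.g. simply the
longest ones) could seed two identities with the same animal and poison the
whole assignment.

## Evaluation protocol

Each fragment's true animal is the majority ground-truth label of its
detections (detections match the nearest truth center within 30 px;
majority, rather than unanimity, tolerates the odd mislabeled sample at a
crossing). For every identity label the *reference animal* is the true
animal of the first-starting fragment with that label; an assigned fragment
is correct only if its true animal equals that reference. This definition
deliberately propagates errors: after a single swap, every later fragment of
both identities counts as incorrect, which is the stricter of the two
conventions in use for crossing-resolution metrics.

Fragments under 25 samples are discarded from all sets (they vanish from
numerators and denominators alike); for the IER, incorrect fragments
shorter than one second are additionally discounted. `Minutes` in the IER
denominator is the total video duration, not the tracked duration. CSR
equals CFR whenever all fragments carry the same number of samples — a
useful identity the tests exercise.

## Synthetic scenes

The generator renders textured ellipses (default semi-axes 14 × 8 px) on a
bright arena (background 240, animal texture ≤ 200, Gaussian pixel noise
sd 2 — so a threshold of 220 separates them by ≥ 10 σ), moving as a
bounce-off-walls random walk (speed 3 px/frame, heading noise sd 0.15 rad)
with soft collision avoidance between non-crossing pairs. Textures are
**rigid**: each animal's striped pattern is defined in body coordinates and
rotates with the heading, mimicking real markings, so histograms and Hu
invariants are genuinely informative rather than artifacts of orientation.
`texture_distinctness` interpolates the per-animal stripe levels and widths
between one common pattern (0) and maximally separated patterns (1); the
shared darkest/brightest anchor levels keep contrast normalization
comparable across animals.

Scheduled crossings steer a pair onto a straight-line collision so that
their masks first overlap at the scheduled frame, pass through each other,
and resume the random walk; an event that would require more than 3× the
nominal speed raises an error as an impossible schedule. Every frame is a
pure function of the seed and the frame index (per-frame private RNG
streams), so lazily streamed and batch-rendered frames are bit-identical
and memory use is constant in video length.

The canonical presets used throughout the tests: a 1-animal null scene
(300 frames, 200×200), a 2-animal single-crossing scene (400 frames,
300×300), a 5-animal 10-crossing distinct-texture scene (2,000 frames,
400×400 — the main validation load, about a minute end to end on one CPU)
and a 5-animal identical-texture stress scene. These sizes are large enough
that every mechanism (cuts, merged-blob fragments, group anchoring, greedy
completion) is exercised many times, and small enough for routine re-runs.

What the scenes do *not* emulate: body deformation (real fish bend; the
ellipses are rigid), lighting gradients and shadows, water-surface
refraction, partial occlusions by arena features, and appearance drift over
time. Passing on these scenes therefore demonstrates the correctness of the
machinery and the discriminative power of the features under rigid,
well-lit conditions — not performance on any particular species or setup,
for which thresholds and limits will need per-dataset adjustment.

## Numerical choices and degenerate inputs

* Value 255 joins the top histogram bin; a constant ROI normalizes to all
  zeros; a perfectly uniform blob falls back to silhouette Hu invariants.
* Pearson correlation of a constant vector is defined as 0 (flagged), never
  `NaN`; empty correlation lists give amplitude 0 and similarity 0.
* The Hungarian solver pads rectangular matrices with the sentinel
  `(max|cost| + 1) · n`, large enough that padded pairings never displace a
  real one; the solver is deterministic, so equal-cost optima resolve
  reproducibly.
* Subsampling of detection pairs uses a seed derived from the two fragment
  ids with the arguments in canonical order, so `Sim` is exactly symmetric
  and independent of evaluation order; the global RNG stream is saved and
  restored around every internal draw, so package calls never perturb user
  code's randomness.
* All assignment ties break by start frame, then fragment id.

## Known limitations

* Appearance is used only at the fragment level; a crossing between two
  animals with genuinely identical appearance (texture_distinctness = 0) is
  unresolvable in principle — the package then guarantees only consistency
  (no two coexisting fragments share an identity), not correctness.
* The greedy completion is not a global optimum over all fusions; a
  network-flow formulation could do better on pathological cases at the
  cost of the online, constant-memory property.
* The evaluation matches detections to truth by nearest center within a
  fixed radius; scenes with animals packed tighter than that radius would
  need a proper per-frame assignment of detections to truth.
* Frame input is PNG sequences (or in-memory frames); video containers
  should be exploded to frames with standard tooling first.
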