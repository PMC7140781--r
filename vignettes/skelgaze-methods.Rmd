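---
title: "Methods: skeleton-based analysis of gaze on animated characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton-based analysis of gaze on animated characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelgaze)
```

skelgaze quantifies where viewers look while watching an animated character
— a video of a performer with a hand-annotated 2D skeleton, or a
motion-captured 3D character — and turns raw eye-tracker samples into
body-part statistics: per-joint fixation time, heat-mesh colorings,
per-viewer timelines and synchronization measures. This vignette documents
the model behind each stage, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## From samples to fixations

An eye tracker delivers timestamped screen coordinates (pixels, origin
top-left, y down, times in ms from media start). Only fixations — pauses
of the gaze over informative regions — carry the attentional signal; the
samples recorded during saccades are discarded. `detect_fixations()`
implements dispersion-threshold identification (I-DT): a window of
consecutive samples is a fixation when its spatial dispersion stays within
a threshold and it lasts strictly longer than a minimum duration.

Two conventions needed fixing:

* **Dispersion metric.** Dispersion is `(max x − min x) + (max y − min y)`
  over the window — the sum-of-extents variant of I-DT. The defaults are
  1 degree of visual angle and 100 ms (strict: a window spanning exactly
  100 ms is not a fixation).
* **Angular units.** Thresholds are stated in degrees, but the data are in
  pixels and the viewing geometry (screen size, viewing distance) varies
  per setup. All conversions go through one user-supplied scalar,
  `px_per_deg`. There is no default hidden in the algorithms; analyses
  must state it.

Windows are grown greedily: the smallest window spanning the minimum
duration is tested; if it passes the dispersion bound it is extended
sample by sample until the bound would break, then emitted. If a passing
window spans *exactly* the minimum duration it is not emitted and the
start slides by one sample — a longer window may begin one sample later.
The fixation's centroid is the mean of its member samples. A brute-force
re-implementation that regrows each window from scratch serves as an
independent oracle in the tests; the two agree exactly on randomized
traces.

## Mapping gaze to body parts

Dynamic areas of interest are the bones of an articulated skeleton, so a
sample's label moves with the character.

**2D (annotated video).** Joint positions are keyframed (typically every
fourth frame) and linearly interpolated in image space between keyframes;
queries outside the keyframed range clamp. Each bone carries a drawn
width and an integer depth level (smaller = nearer the camera). A sample
maps to a bone when its point-to-segment distance is at most
`half_width + exclusion`, where the exclusion radius (default 0.5°,
sensible range 0.25–0.5° depending on tracker accuracy) absorbs tracker
error; among candidate bones the smallest depth level wins (front plane
masks back plane), then the smallest distance. Samples beyond every band
get the empty label — gaze off the character is a value, not an error.
A bone's **owning joint is its child (distal) joint**; this one
convention is applied everywhere, including skinning weights. Each sample
is evaluated at the pose of its video frame, `floor(t · fps / 1000)`.

**3D (rendered scene).** A pinhole camera back-projects the screen
coordinate into a scene ray (`project_gaze_ray()`); the ray is tested
against capsules wrapped around each bone (`bone_capsules()`, radius
defaulting to 0.15 × bone length — engine colliders are scene-specific,
so the radius is configurable) and the first intersection's owning joint
wins. Forward kinematics (`fk_positions()`) produces world joint
positions from per-joint local quaternions and rest offsets. The analytic
ray–capsule solution is checked against a dense ray-marching oracle.

**Fixation → AOI.** A fixation inherits the majority label among its
member samples' non-empty labels; ties break toward the label occurring
earliest within the fixation; all-empty fixations get no joint. Per-joint
fixation time T(j) is then the sum of assigned durations within an
analysis interval; a fixation straddling an interval boundary contributes
its inside part only (proportional clipping by time; its joint is not
re-evaluated per part). Because saccades and off-character fixations are
excluded, `sum_j T(j)` never exceeds the interval length.

## Heat mesh

The character mesh is bound to the skeleton by linear-blend skinning
weights `w(v, j) ≥ 0`, `Σ_j w(v, j) = 1`. The same weights shade the mesh:

```
v_c = Σ_j w(v, j) · T(j) / T_MAX,   clipped to [0, 1]
```

so colors blend smoothly across body-part boundaries. Three
normalizations are offered: (1) the interval duration — absolute share
including saccades and off-body gaze; (2) the on-character total
`Σ_j T(j)` — relative distribution on the body; (3) the per-joint maximum
— full contrast. By construction metric 3 ≤ metric 2 ≤ metric 1, under
metric 2 the shares sum to exactly 1, and colors are invariant when all
T(j) and T_MAX rescale together. Metrics 2 and 3 are undefined on an
all-zero map and raise an error (the per-interval driver falls back to
metric 1 with a warning so an empty movement phase renders as an all-zero
mesh). Multi-viewer meshes average the per-viewer T(j) maps joint-wise,
with missing joints counted as zero. The clip to [0, 1] guards rounding
only; mathematically all three metrics already bound the color by 1.

The canonical skinning layout has 51 joints (5 trunk, neck + head, 4 per
leg, 3 per arm, 15 per hand); lower-resolution annotation skeletons
(e.g. 26 joints for video work) map into it through the shipped
nomenclature table, which also translates MotionBuilder-, Mixamo-, Unity-
and Kinect-style names. Unknown names pass through with a warning rather
than failing, since AOI vocabularies vary.

## Timelines and synchronization

A single-mode timeline discretizes one capture into binary steps: 1 when
a fixation on the joint covers any part of the step. The step defaults to
the media frame period — the finest grid at which the 2D stimulus
changes; nothing in the data supports a finer timeline resolution. Two
percentages summarize a block: time on the joint over the interval
length, and over the on-character total only (the latter sums to 100
across joints whenever any on-body fixation exists).

Aggregated mode averages several binary traces per step (occurrences of
the same motion, or — after `remap_time()` — semantically equivalent
motions on the reference time base) and normalizes by the maximum mean
among all displayed body parts for the interval, so the most-watched
joint peaks at 1.

The synchronization statistic, `overlap_duration()`, is the total time
during which at least a fraction of viewers (default one third) watch the
joint simultaneously. The viewer count threshold is `ceil(fraction · n)`:
"at least a third of 9" means 3. `rare_aois()` selects joints holding
less than 1% of pooled scanning time — fixations there tend to mark
events (e.g. execution errors) rather than sustained attention, which is
what makes their cross-viewer overlap interesting.

## Temporal alignment (DTW)

Semantically equivalent gestures differ in dynamics, so timelines cannot
be compared frame-by-frame. `dtw_align()` computes the full matrix of
posture distances between two sequences and the optimal monotone warping
path with steps (1,0), (0,1), (1,1) — plain dynamic time warping, no step
weights, no band. The posture distance is the unweighted sum over joints
of the quaternion geodesic `‖Log(q_a⁻¹ q_b)‖`, with these conventions:

* half-angle magnitude (a 90° relative rotation is π/4 apart);
* the antipodal double cover is collapsed by flipping to the hemisphere
  with non-negative scalar part, so `q` and `−q` are the same rotation
  and distances live in `[0, π/2]`;
* root translation is excluded — the distance compares joint angles only;
* an optional per-joint weight vector is accepted for sensitivity
  analyses but defaults to all ones.

Any consistent log convention rescales the whole cost matrix uniformly
and leaves the optimal path unchanged, which is why the choice is safe to
make once. Ties during backtracking prefer the diagonal step. On pairs
small enough to enumerate every monotone path exhaustively, the dynamic
program matches the enumeration exactly.

`remap_time()` converts a time in the target sequence to the reference
time base: each target frame maps to the mean of its matched reference
frame times, with linear interpolation between frame centers. The first
and last target frames are pinned to the reference's first and last frame
times — without pinning, an end frame matched by several reference frames
would map to their mean and the remap would not cover the reference's
full range; with it the remap is monotone *and* surjective onto the
endpoints. Out-of-range queries clamp.

## Statistics from group summaries

`welch_t()` computes the unequal-variance t statistic, Welch–Satterthwaite
degrees of freedom and two-sided p directly from (mean, sd, n) triples,
so published comparisons can be recomputed without raw data. Degenerate
input (both sds zero) yields t = 0 for equal means and an error
otherwise. Recomputing from printed summaries inherits their rounding:
the goalkeeper error-rate comparison (38 ± 9.3 vs 38.5 ± 8.9, n = 5/5)
gives |t| = 0.0869 on df 7.98, and the judge overlap comparison
(83 ± 78 vs 76 ± 49 ms, n = 9/9) gives t = 0.228 on df 13.5 — agreement
with the published t values to within the precision the inputs carry.
`rank_sum()` wraps the base-R rank-sum test for cases where raw vectors
are available.

## The synthetic-data generator

Real eye-tracking recordings of viewers watching annotated characters are
not redistributable, so every stage is validated against generated
fixtures with planted ground truth.

* `make_skeleton_walk_2d()` emulates the video-annotation setting: a
  chain skeleton keyframed every fourth frame at 30 fps (matching common
  annotation practice and video rates), joints spaced 100 px apart with
  slow sinusoidal wiggle (amplitude ≤ 15 px), widths 8–16 px, random
  depth levels. The wide spacing and slow motion are deliberate: planted
  gaze on one bone must stay unambiguous under the 0.5° exclusion radius
  at the emulated 40 px/°.
* `make_motion_3d()` produces smooth per-joint quaternion curves (fixed
  random axis, sinusoidal angle), unit-normalized.
* `planted_schedule()` + `make_gaze_trace()` lay a gaze trace over the
  animation at 1000 Hz (a typical research-grade tracker rate): during
  each planted segment, samples cluster around the midpoint of the target
  bone anchored at the segment's first frame; between segments, samples
  sweep a screen band far above the skeleton in jumps of several degrees
  per sample, so no dispersion window can absorb them.

One parameter deserves its rationale: the planted jitter amplitude,
`jitter_deg = 0.4`, is defined as the **worst-case dispersion
contribution** of a planted cluster. Offsets are drawn uniformly in the
square of half-side `jitter_deg / 4` per axis, so the cluster's
sum-of-extents dispersion never exceeds 0.4° — safely below the 1°
detection threshold. (A naive "uniform in a 0.4°-radius disc" would allow
a worst-case dispersion of 1.6° under the sum-of-extents metric and make
detection ambiguous, defeating the generator's purpose.)

With integer-millisecond segment boundaries and 1000 Hz sampling, the
recovered per-joint time differs from the planted total by at most one
sample period per planted fixation; the recovery tests and the acceptance
script assert exactly that bound over 20 seeds.

What the generator does **not** emulate: smooth pursuit of a moving body
part within a fixation (planted clusters are anchored), blinks and
dropouts, autocorrelated tracker noise, mislabelled samples, and
skeletons with crossing limbs. Passing the recovery tests therefore shows
the pipeline is correct under clean conditions; it does not certify
behavior on noisy real recordings, where the exclusion radius and
dispersion threshold interact with tracker quality.

Every generator is a pure function of its seed: reruns are bitwise
identical and never disturb the caller's RNG state.

## Numerical choices and degenerate inputs

* Strict inequalities where the definitions demand them: fixation
  duration > 100 ms; rarity share < 1%.
* Validation is total and typed: malformed XML, overlapping intervals,
  unsorted timestamps, non-unit weights, zero-norm quaternions and
  degenerate intervals raise classed conditions
  (`skelgaze_schema_error` / `skelgaze_validation_error`), never crashes
  or silent defaults.
* Quaternion dot products are clamped to [−1, 1] before `acos`; a
  self-alignment cost is therefore zero only to ~1e−7 and tests compare
  with tolerance.
* Interval partitioning keeps interval arithmetic in milliseconds
  throughout; timeline step grids are generated by index
  (`start + k · step`), not by `seq()` on endpoints, to avoid
  floating-point fuzz adding a step.
* Figures are cosmetic: the blue→red colormap is fixed but every figure
  has a CSV twin carrying the exact plotted numbers, and the CSVs — not
  the figures — are what reruns are compared on.

## Problem sizes

The test suite and acceptance script run: 50 random traces of 700–1200
samples for the I-DT oracle sweep; exhaustive DTW path enumeration on
7 × 8-frame pairs (≈10⁴–10⁵ monotone paths); 1000 random samples for the
mapping oracle; 20 seeds of 5-fixation schedules over 120-frame skeletons
for end-to-end recovery; 100-draw sweeps for the statistical identities.
These sizes keep the full suite in a few minutes while leaving every
oracle comparison exact rather than sampled.

## Known limitations

* 2D keyframe interpolation is linear in image space; fast rotations
  between sparse keyframes can cut corners relative to the true limb
  trajectory.
* The 3D path assumes a static pinhole camera per capture; head-mounted
  or moving cameras would need per-sample extrinsics.
* `aggregate_timelines()` requires a shared step grid; remapping is the
  caller's responsibility when sources differ.
* The rank-sum comparison needs raw per-trial values; only the Welch test
  is recomputable from published summaries.
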