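# skelgaze

Skeleton-based analysis of oculomotor behavior on animated characters.

When viewers watch the movements of an animated character — a filmed
gymnast with a hand-annotated 2D skeleton, or a motion-captured 3D
penalty taker rendered in virtual reality — the interesting areas of
interest (AOIs) are *body parts that move*. skelgaze maps raw
eye-tracking samples onto these dynamic skeleton-attached AOIs and turns
them into quantitative, comparable descriptions of gaze behavior:

- **Fixation detection** with the dispersion-threshold (I-DT) algorithm:
  a fixation is a window of samples with dispersion
  `(Δx + Δy) ≤ 1°` lasting `> 100 ms`.
- **Sample–joint mapping**: in 2D by nearest bone band with an exclusion
  radius and front-plane depth masking over an interpolated keyframed
  skeleton; in 3D by pinhole ray casting against bone capsules.
- **Per-joint fixation time** `T(j)` and the **heat mesh**: each mesh
  vertex is colored `v_c = Σ_j w(v, j) · T(j) / T_MAX` through the
  linear-blend skinning weights `w(v, j)`, with three `T_MAX`
  normalizations (interval duration, on-body total, per-joint maximum).
- **Viewer timelines** (binary single-viewer traces and normalized
  aggregated traces) with per-block fixation percentages, and the
  **overlap duration**: the total time at least a third of viewers watch
  a body part simultaneously.
- **Temporal alignment** of semantically equivalent motions by dynamic
  time warping on the posture distance
  `D(i, j) = Σ_joints ‖Log(q_A⁻¹ q_B)‖` (quaternion geodesic, antipodal
  double cover collapsed), plus time remapping onto a reference sequence.
- **Statistics**: per-AOI fixation counts and merged adjacent-fixation
  runs, rare-AOI selection (< 1 % of pooled scanning time), Welch's
  t-test directly from group summaries, CSV export of every table.

All user-facing functions take and return tibbles and chain with the
pipe; result objects support `tidy()`, `glance()` and `autoplot()`. A
synthetic-data generator plants known per-joint fixation schedules over
generated skeleton animations so the whole pipeline is testable without
any recorded data.

## Worked example

Simulate a 4-second annotated skeleton animation with a planted gaze
schedule, then recover the planted fixation times through the full
pipeline:

```r
library(skelgaze)

sk      <- make_skeleton_walk_2d(n_joints = 6, n_frames = 120, seed = 42)
sched   <- random_schedule(sk, n_fixations = 5, seed = 42)
trace   <- make_gaze_trace(sched, sk, px_per_deg = 40)

samples <- map_samples_2d(trace$samples, sk, exclusion_deg = 0.5, px_per_deg = 40)
fx      <- detect_fixations(samples, px_per_deg = 40) |>
  assign_fixation_joints(samples)
fx[, c("start_ms", "end_ms", "duration_ms", "joint")]
#> # A tibble: 5 × 4
#>   start_ms end_ms duration_ms joint
#>      <dbl>  <dbl>       <dbl> <chr>
#> 1      133    694         561 chest
#> 2      858   1429         571 spine
#> 3     1509   1787         278 neck
#> 4     1940   2463         523 chest
#> 5     2623   3061         438 spine1

joint_time_map(fx, c(0, trace$duration_ms))
#> # A tibble: 4 × 2
#>   joint   t_ms
#>   <chr>  <dbl>
#> 1 chest   1084
#> 2 neck     278
#> 3 spine    571
#> 4 spine1   438
```

The recovered `T(j)` match the planted ground truth (`trace$truth`:
chest 1086, neck 279, spine 572, spine1 439 ms) to within one sample
period per planted fixation — the 1000 Hz trace quantizes each planted
segment by at most 1 ms.

Timelines and summary statistics follow the same grammar:

```r
single_timeline(fx, "chest", c(0, trace$duration_ms), step_ms = 1000 / 30)
#> <skel_timeline single> joint chest, 120 steps of 33.3333 ms,
#>   timeline 27.1%, block 45.7%

welch_t(group_summary(38, 9.3, 5), group_summary(38.5, 8.9, 5))
#> Welch two-sample t-test from summaries: t(7.985) = -0.08685, p = 0.9329
```

The timeline percentages read: the chest was watched 27.1 % of the
interval, and held 45.7 % of the on-character fixation time. The Welch
call recomputes a goalkeeper-vs-field-player error-rate comparison from
its published group summaries alone.

For 3D material, `dtw_align()` aligns two motion sequences and
`remap_time()` replays any capture on the reference time base;
`autoplot()` on the alignment draws the cost matrix with the optimal
warping path.

A command-line front end ships at `inst/cli/skelgaze` with verbs
`analyze`, `align`, `simulate` and `stats`; `run_simulate()` /
`run_analyze()` are the equivalent R entry points and write CSV tables, a
manifest and figure files (every figure has a CSV twin with the exact
plotted numbers).

## Package layout

| Area | Files |
|---|---|
| Domain types and validation | `R/data-model.R`, `R/nomenclature.R` |
| XML / CSV / OBJ / motion-text I/O | `R/io.R` (DTDs in `inst/extdata/`) |
| Fixations and T(j) | `R/fixation.R` |
| 2D / 3D gaze-to-skeleton mapping | `R/skeleton-mapping.R` |
| DTW alignment and remapping | `R/alignment.R` |
| Heat mesh and timelines | `R/heat-timeline.R` |
| Synchronization statistics | `R/sync-stats.R` |
| Synthetic data with planted truth | `R/synthetic-data.R` |
| Run drivers and CLI | `R/cli.R`, `inst/cli/skelgaze` |

The methods vignette (`vignettes/skelgaze-methods.Rmd`) documents the
model, parameter defaults, numerical choices and limitations in detail.
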