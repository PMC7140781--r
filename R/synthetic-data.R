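# Run code under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a keyframed 2D chain skeleton with smooth motion
#'
#' Emulates the manual video-annotation setting: a chain skeleton whose
#' joints follow smooth sinusoidal trajectories, annotated only every
#' `keyframe_stride` frames (the rest of the animation is recovered by
#' interpolation). Joints are laid out with wide horizontal spacing and
#' slow, small-amplitude motion so the bones stay well separated — gaze
#' planted on one bone is never ambiguous. Bone widths and depth levels
#' are drawn at random; everything is a pure function of the seed.
#'
#' @param n_joints Number of joints (>= 2); names come from the canonical
#'   joint list.
#' @param n_frames Number of video frames.
#' @param keyframe_stride Annotate every k-th frame (default 4).
#' @param fps Video frame rate (default 30).
#' @param seed Integer seed.
#' @return A `skel_skeleton2d`.
#' @export
make_skeleton_walk_2d <- function(n_joints, n_frames, keyframe_stride = 4,
                                  fps = 30, seed = 1) {
  stopifnot(n_joints >= 2, n_frames >= 2)
  with_local_seed(seed, {
    names_j <- canonical_joints()[seq_len(n_joints)]
    joints <- tibble(name = names_j,
                     parent = c(NA_character_, names_j[-n_joints]))
    bones <- tibble(joint_a = names_j[-n_joints], joint_b = names_j[-1],
                    width_px = stats::runif(n_joints - 1, 8, 16),
                    depth_level = sample(1:3, n_joints - 1, replace = TRUE))
    kf <- sort(unique(c(seq(0, n_frames - 1, by = keyframe_stride),
                        n_frames - 1)))
    phase <- stats::runif(n_joints, 0, 2 * pi)
    freq <- stats::runif(n_joints, 0.5, 1.5)
    amp <- stats::runif(n_joints, 5, 15)
    keyframes <- tidyr::expand_grid(frame = kf, k = seq_len(n_joints)) |>
      dplyr::mutate(
        joint = names_j[k],
        x = 100 + 100 * (k - 1) +
          3 * sin(2 * pi * freq[k] * frame / n_frames + phase[k]),
        y = 300 + amp[k] * sin(2 * pi * freq[k] * frame / n_frames + phase[k] / 2)
      ) |>
      dplyr::select(frame, joint, x, y)
    skeleton2d(joints, bones, keyframes, fps)
  })
}

#' Generate a smooth 3D motion sequence
#'
#' Per-joint quaternion curves: each joint rotates about a fixed random
#' axis with a smoothly varying angle, normalized to unit quaternions.
#' Deterministic per seed.
#'
#' @param n_joints Number of joints (default 51, the canonical layout).
#' @param n_frames Number of frames (>= 2).
#' @param fps Frame rate.
#' @param seed Integer seed.
#' @return A `skel_motion3d`.
#' @export
make_motion_3d <- function(n_joints = 51, n_frames = 60, fps = 30, seed = 1) {
  stopifnot(n_frames >= 2, n_joints >= 1)
  with_local_seed(seed, {
    joint_names <- canonical_joints()[seq_len(min(n_joints, 51))]
    if (n_joints > 51) {
      joint_names <- c(joint_names, paste0("extra", seq_len(n_joints - 51)))
    }
    rot <- array(NA_real_, dim = c(n_frames, n_joints, 4))
    tgrid <- seq(0, 1, length.out = n_frames)
    for (j in seq_len(n_joints)) {
      axis <- stats::rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      amp <- stats::runif(1, 0.2, 1.2)
      freq <- stats::runif(1, 0.5, 2)
      phase <- stats::runif(1, 0, 2 * pi)
      angle <- amp * sin(2 * pi * freq * tgrid + phase)
      rot[, j, 1] <- cos(angle / 2)
      rot[, j, 2] <- sin(angle / 2) * axis[1]
      rot[, j, 3] <- sin(angle / 2) * axis[2]
      rot[, j, 4] <- sin(angle / 2) * axis[3]
    }
    root <- cbind(tgrid * 100, rep(0, n_frames), rep(0, n_frames))
    motion3d(joint_names, rot, root, fps)
  })
}

#' Planted fixation schedule
#'
#' Ground-truth plan for a synthetic gaze trace: ordered, non-overlapping
#' fixation segments (each strictly longer than 100 ms so detection is
#' unambiguous), each targeting one joint; the gaps between segments are
#' filled with saccades. `jitter_deg` is the worst-case dispersion
#' contribution of a planted cluster: sample offsets are drawn uniformly
#' in the square of half-side `jitter_deg / 4` per axis, so the cluster's
#' `(max x - min x) + (max y - min y)` dispersion never exceeds
#' `jitter_deg` and stays far below the 1 degree detection threshold.
#'
#' @param segments Tibble `joint`, `start_ms`, `end_ms`.
#' @param jitter_deg Worst-case planted dispersion in degrees.
#' @param rate_hz Eye-tracker sample rate (default 1000 Hz).
#' @param seed Integer seed.
#' @return Object of class `skel_schedule`.
#' @export
planted_schedule <- function(segments, jitter_deg = 0.4, rate_hz = 1000,
                             seed = 1) {
  seg <- as_tibble(segments)
  if (nrow(seg)) {
    stopifnot(all(c("joint", "start_ms", "end_ms") %in% names(seg)))
    if (is.unsorted(seg$start_ms, strictly = TRUE) ||
        any(seg$start_ms[-1] < seg$end_ms[-nrow(seg)])) {
      abort("schedule segments must be sorted and non-overlapping.",
            class = "skelgaze_validation_error")
    }
    if (any(seg$end_ms - seg$start_ms <= 0)) {
      abort("schedule segments must have positive length.",
            class = "skelgaze_validation_error")
    }
    if (any(seg$end_ms - seg$start_ms <= 100)) {
      warn("segment(s) of 100 ms or less are below the fixation duration threshold and will not be recovered.",
           class = "skelgaze_short_segment")
    }
  }
  structure(list(segments = seg, jitter_deg = jitter_deg,
                 rate_hz = rate_hz, seed = seed),
            class = "skel_schedule")
}

#' Synthesize a gaze capture with known ground truth
#'
#' Lays a gaze trace over an animated 2D skeleton: during each planted
#' segment, samples cluster (with sub-threshold jitter) around the
#' midpoint of the target joint's bone, anchored at the segment's first
#' frame; between segments, samples sweep a screen band far from the
#' skeleton in large per-sample jumps, emulating saccades that no
#' dispersion window can absorb. The returned ground truth equals the
#' planted per-joint totals, so the full detect → map → T(j) pipeline can
#' be validated end to end.
#'
#' @param schedule A `skel_schedule`.
#' @param skeleton A `skel_skeleton2d` (from [make_skeleton_walk_2d()]).
#' @param px_per_deg Pixels per degree of the emulated setup (default 40).
#' @return List with `samples` (tibble `t`, `x`, `y`), `truth` (tibble
#'   `joint`, `t_ms` of planted totals) and `duration_ms`.
#' @export
make_gaze_trace <- function(schedule, skeleton, px_per_deg = 40) {
  stopifnot(inherits(schedule, "skel_schedule"),
            inherits(skeleton, "skel_skeleton2d"))
  n_frames <- max(skeleton$kf_frames) + 1
  duration_ms <- n_frames * 1000 / skeleton$fps
  period <- 1000 / schedule$rate_hz
  tt <- seq(0, duration_ms - period, by = period)
  seg <- schedule$segments
  with_local_seed(schedule$seed, {
    x <- numeric(length(tt)); y <- numeric(length(tt))
    seg_idx <- rep(NA_integer_, length(tt))
    if (nrow(seg)) {
      for (k in seq_len(nrow(seg))) {
        seg_idx[tt >= seg$start_ms[k] & tt < seg$end_ms[k]] <- k
      }
    }
    half <- schedule$jitter_deg / 4 * px_per_deg
    for (k in seq_len(nrow(seg))) {
      idx <- which(seg_idx == k)
      if (!length(idx)) next
      frame0 <- seg$start_ms[k] * skeleton$fps / 1000
      pose <- interpolate_pose2d(skeleton, frame0)
      bands <- bone_bands(skeleton, pose)
      b <- bands[bands$joint == seg$joint[k], ]
      if (!nrow(b)) {
        abort(sprintf("schedule targets joint `%s` which owns no bone.",
                      seg$joint[k]),
              class = "skelgaze_validation_error")
      }
      cx <- (b$ax[1] + b$bx[1]) / 2
      cy <- (b$ay[1] + b$by[1]) / 2
      x[idx] <- cx + stats::runif(length(idx), -half, half)
      y[idx] <- cy + stats::runif(length(idx), -half, half)
    }
    # saccades: deterministic wide sweep across a band far above the body
    sidx <- which(is.na(seg_idx))
    if (length(sidx)) {
      k <- seq_along(sidx)
      x[sidx] <- (k * 517) %% 1900 + stats::runif(length(sidx), -3, 3)
      y[sidx] <- 20 + (k * 89) %% 40 + stats::runif(length(sidx), -3, 3)
    }
    truth <- if (nrow(seg)) {
      tibble(joint = seg$joint, t_ms = seg$end_ms - seg$start_ms) |>
        dplyr::group_by(joint) |>
        dplyr::summarise(t_ms = sum(t_ms), .groups = "drop") |>
        dplyr::arrange(joint)
    } else {
      tibble(joint = character(), t_ms = numeric())
    }
    list(samples = tibble(t = tt, x = x, y = y), truth = truth,
         duration_ms = duration_ms)
  })
}

#' Draw a random valid schedule over a skeleton animation
#'
#' Convenience generator for property sweeps: alternating
#' fixation/saccade segments with fixation durations in
#' `[150, 600]` ms on random joints.
#'
#' @param skeleton A `skel_skeleton2d`.
#' @param n_fixations Number of planted fixations.
#' @param seed Integer seed.
#' @inheritParams planted_schedule
#' @return A `skel_schedule`.
#' @export
random_schedule <- function(skeleton, n_fixations = 5, jitter_deg = 0.4,
                            rate_hz = 1000, seed = 1) {
  n_frames <- max(skeleton$kf_frames) + 1
  duration_ms <- n_frames * 1000 / skeleton$fps
  owners <- unique(skeleton$bones$joint_b)
  with_local_seed(seed, {
    durs <- round(stats::runif(n_fixations, 150, 600))
    gaps <- round(stats::runif(n_fixations + 1, 60, 200))
    need <- sum(durs) + sum(gaps)
    if (need > duration_ms) {
      scale <- duration_ms / need
      durs <- pmax(150, floor(durs * scale))
      gaps <- pmax(30, floor(gaps * scale))
    }
    starts <- cumsum(c(gaps[1], head(durs, -1) + gaps[2:n_fixations]))
    ends <- starts + durs
    keep <- ends < duration_ms
    seg <- tibble(joint = sample(owners, n_fixations, replace = TRUE),
                  start_ms = starts, end_ms = ends)[keep, ]
    planted_schedule(seg, jitter_deg, rate_hz, seed)
  })
}
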