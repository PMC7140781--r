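#' Interpolate a 2D skeleton pose at a fractional frame
#'
#' Joint positions are annotated only on keyframes (typically every fourth
#' video frame); the remaining animation is computed by linear
#' interpolation of each joint's position between the bracketing keyframes.
#' Queries outside the keyframed range clamp to the first / last keyframe.
#'
#' @param skeleton A `skel_skeleton2d`.
#' @param frame Fractional frame index.
#' @return Tibble `joint`, `x`, `y`.
#' @export
interpolate_pose2d <- function(skeleton, frame) {
  stopifnot(inherits(skeleton, "skel_skeleton2d"))
  kf <- skeleton$kf_frames
  frame <- max(min(frame, max(kf)), min(kf))
  lo <- max(kf[kf <= frame])
  hi <- min(kf[kf >= frame])
  a <- dplyr::filter(skeleton$keyframes, frame == lo)
  if (hi == lo) {
    return(tibble(joint = a$joint, x = a$x, y = a$y))
  }
  b <- dplyr::filter(skeleton$keyframes, frame == hi)
  b <- b[match(a$joint, b$joint), ]
  s <- (frame - lo) / (hi - lo)
  tibble(joint = a$joint, x = (1 - s) * a$x + s * b$x,
         y = (1 - s) * a$y + s * b$y)
}

#' Bone bands of a posed 2D skeleton
#'
#' Realizes each bone as a segment with a half-width (the drawn thickness)
#' and a depth level at the given pose. The band's owning joint is the
#' bone's child (distal) joint; that convention is applied everywhere,
#' including skinning weights.
#'
#' @param skeleton A `skel_skeleton2d`.
#' @param pose Pose tibble from [interpolate_pose2d()].
#' @return Tibble with columns `joint` (owner), `ax`, `ay`, `bx`, `by`,
#'   `half_width`, `depth_level`.
#' @export
bone_bands <- function(skeleton, pose) {
  b <- skeleton$bones
  ia <- match(b$joint_a, pose$joint)
  ib <- match(b$joint_b, pose$joint)
  if (anyNA(ia) || anyNA(ib)) {
    abort("pose does not cover all bone endpoints.",
          class = "skelgaze_validation_error")
  }
  tibble(joint = b$joint_b,
         ax = pose$x[ia], ay = pose$y[ia],
         bx = pose$x[ib], by = pose$y[ib],
         half_width = b$width_px / 2,
         depth_level = b$depth_level)
}

# Distance from points (px, py) to segment (ax,ay)-(bx,by); all vectorized
# over the segments for a single point.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  s <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  s <- pmin(pmax(s, 0), 1)
  qx <- ax + s * dx; qy <- ay + s * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Map one gaze sample to a skeleton joint (2D)
#'
#' Implements the sample-joint mapping function: candidate bones are those
#' whose point-to-segment distance does not exceed the drawn half-width
#' plus the exclusion radius (the eye-tracker accuracy margin, in degrees).
#' Among candidates the bone nearest the camera (smallest depth level)
#' wins; among equal depths, the smallest distance. Samples too far from
#' every bone map to the empty string (off-character) — an ordinary value,
#' not an error.
#'
#' @param x,y Sample screen coordinates (pixels).
#' @param bands Bone bands from [bone_bands()].
#' @param exclusion_deg Exclusion radius in degrees (typical 0.25-0.5,
#'   default 0.5).
#' @param px_per_deg Pixels per degree.
#' @return The owning joint name, or `""`.
#' @export
map_sample_to_joint_2d <- function(x, y, bands, exclusion_deg = 0.5,
                                   px_per_deg) {
  d <- point_segment_distance(x, y, bands$ax, bands$ay, bands$bx, bands$by)
  cand <- which(d <= bands$half_width + exclusion_deg * px_per_deg)
  if (!length(cand)) return("")
  depth <- bands$depth_level[cand]
  cand <- cand[depth == min(depth)]
  bands$joint[cand[which.min(d[cand])]]
}

#' Label a whole sample table against an animated 2D skeleton
#'
#' Vectorized driver for [map_sample_to_joint_2d()]: each sample is mapped
#' at the skeleton pose of its video frame (`floor(t * fps / 1000)`),
#' interpolated from the keyframes.
#'
#' @param samples Sample tibble (`t`, `x`, `y`).
#' @param skeleton A `skel_skeleton2d`.
#' @inheritParams map_sample_to_joint_2d
#' @return The sample tibble with the `joint` column (re)filled.
#' @export
map_samples_2d <- function(samples, skeleton, exclusion_deg = 0.5,
                           px_per_deg) {
  df <- as_tibble(samples)
  frames <- floor(df$t * skeleton$fps / 1000)
  df$joint <- ""
  for (f in unique(frames)) {
    pose <- interpolate_pose2d(skeleton, f)
    bands <- bone_bands(skeleton, pose)
    idx <- which(frames == f)
    df$joint[idx] <- vapply(idx, function(k)
      map_sample_to_joint_2d(df$x[k], df$y[k], bands, exclusion_deg,
                             px_per_deg), "")
  }
  df
}

quat_rotate_vec <- function(q, v) {
  # rotate vector(s) v (n x 3) by unit quaternion q = c(w,x,y,z)
  w <- q[1]; u <- q[2:4]
  v <- matrix(v, ncol = 3)
  uv <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
              u[3] * v[, 1] - u[1] * v[, 3],
              u[1] * v[, 2] - u[2] * v[, 1])
  uuv <- cbind(u[2] * uv[, 3] - u[3] * uv[, 2],
               u[3] * uv[, 1] - u[1] * uv[, 3],
               u[1] * uv[, 2] - u[2] * uv[, 1])
  v + 2 * (w * uv + uuv)
}

#' Cast a gaze ray through a pinhole camera
#'
#' Projects the screen gaze coordinate through the camera into the scene:
#' the returned ray starts at the camera position and points along the
#' back-projected pixel direction (unit norm). The image-center sample maps
#' exactly onto the optical axis.
#'
#' @param x,y Screen coordinates in pixels (origin top-left, y down); must
#'   lie inside the image rectangle.
#' @param camera A `skel_camera`.
#' @return List with `origin` (length-3) and `direction` (unit length-3).
#' @export
project_gaze_ray <- function(x, y, camera) {
  stopifnot(inherits(camera, "skel_camera"))
  if (x < 0 || x > camera$width_px || y < 0 || y > camera$height_px) {
    abort("gaze sample outside the image rectangle.",
          class = "skelgaze_offscreen_error")
  }
  dir_cam <- c((x - camera$width_px / 2) / camera$focal_px,
               -(y - camera$height_px / 2) / camera$focal_px,
               1)
  dir <- quat_rotate_vec(camera$orientation, dir_cam)[1, ]
  list(origin = camera$position, direction = dir / sqrt(sum(dir^2)))
}

#' Project a scene point to screen pixels
#'
#' Inverse of [project_gaze_ray()] for points in front of the camera; used
#' to validate the projection round trip.
#'
#' @param p Length-3 scene point.
#' @param camera A `skel_camera`.
#' @return Length-2 pixel coordinates `c(x, y)`.
#' @export
project_point <- function(p, camera) {
  q <- camera$orientation
  q_inv <- c(q[1], -q[2:4])
  pc <- quat_rotate_vec(q_inv, matrix(p - camera$position, 1))[1, ]
  if (pc[3] <= 0) {
    abort("point behind the camera.", class = "skelgaze_validation_error")
  }
  c(camera$width_px / 2 + camera$focal_px * pc[1] / pc[3],
    camera$height_px / 2 - camera$focal_px * pc[2] / pc[3])
}

#' Bone capsules from posed 3D joint positions
#'
#' Stand-in for a game engine's body colliders: each bone becomes a capsule
#' around the parent-to-child segment. The capsule radius defaults to a
#' fraction of the bone length.
#'
#' @param positions Tibble `joint`, `x`, `y`, `z` of world joint positions
#'   at one frame.
#' @param bones Tibble `joint_a` (parent), `joint_b` (child / owner).
#' @param radius_fraction Capsule radius as a fraction of bone length.
#' @param min_radius Lower bound on the radius (scene units).
#' @return Tibble `joint`, `ax..az`, `bx..bz`, `radius`.
#' @export
bone_capsules <- function(positions, bones, radius_fraction = 0.15,
                          min_radius = 1e-3) {
  ia <- match(bones$joint_a, positions$joint)
  ib <- match(bones$joint_b, positions$joint)
  if (anyNA(ia) || anyNA(ib)) {
    abort("positions do not cover all bone endpoints.",
          class = "skelgaze_validation_error")
  }
  len <- sqrt((positions$x[ib] - positions$x[ia])^2 +
              (positions$y[ib] - positions$y[ia])^2 +
              (positions$z[ib] - positions$z[ia])^2)
  tibble(joint = bones$joint_b,
         ax = positions$x[ia], ay = positions$y[ia], az = positions$z[ia],
         bx = positions$x[ib], by = positions$y[ib], bz = positions$z[ib],
         radius = pmax(radius_fraction * len, min_radius))
}

# Smallest positive ray parameter hitting a single capsule, or Inf.
ray_capsule_t <- function(origin, dir, a, b, r) {
  hits <- numeric(0)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 > 0) {
    ah <- ab / sqrt(len2)
    m <- origin - a
    p <- dir - sum(dir * ah) * ah
    q <- m - sum(m * ah) * ah
    A <- sum(p * p)
    B <- 2 * sum(p * q)
    C <- sum(q * q) - r^2
    if (A > 1e-15) {
      disc <- B^2 - 4 * A * C
      if (disc >= 0) {
        for (tt in (-B + c(-1, 1) * sqrt(disc)) / (2 * A)) {
          if (tt > 0) {
            h <- origin + tt * dir
            s <- sum((h - a) * ah)
            if (s >= 0 && s * s <= len2) hits <- c(hits, tt)
          }
        }
      }
    }
  }
  for (cc in list(a, b)) {
    m <- origin - cc
    B <- 2 * sum(dir * m)
    C <- sum(m * m) - r^2
    disc <- B^2 - 4 * C
    if (disc >= 0) {
      for (tt in (-B + c(-1, 1) * sqrt(disc)) / 2) {
        if (tt > 0) hits <- c(hits, tt)
      }
    }
  }
  if (length(hits)) min(hits) else Inf
}

#' First body part hit by a gaze ray
#'
#' Checks the ray against every bone capsule of the posed character and
#' returns the owning joint of the first (nearest) intersection, or the
#' empty string when the ray misses the body entirely.
#'
#' @param ray List with `origin` and `direction` ([project_gaze_ray()]).
#' @param capsules Capsule tibble from [bone_capsules()].
#' @return Joint name or `""`.
#' @export
intersect_ray_capsules <- function(ray, capsules) {
  if (!nrow(capsules)) return("")
  ts <- vapply(seq_len(nrow(capsules)), function(k)
    ray_capsule_t(ray$origin, ray$direction,
                  c(capsules$ax[k], capsules$ay[k], capsules$az[k]),
                  c(capsules$bx[k], capsules$by[k], capsules$bz[k]),
                  capsules$radius[k]), 1.0)
  if (all(is.infinite(ts))) return("")
  capsules$joint[which.min(ts)]
}

#' Forward kinematics of a 3D motion frame
#'
#' Composes the per-joint local rotations down the parent chain to world
#' joint positions, given fixed bone offsets (child position in the parent
#' frame at rest).
#'
#' @param motion A `skel_motion3d`.
#' @param frame Frame index (1-based).
#' @param hierarchy Tibble `joint`, `parent` (`NA` for the root), `ox`,
#'   `oy`, `oz` rest offsets.
#' @return Tibble `joint`, `x`, `y`, `z`.
#' @export
fk_positions <- function(motion, frame, hierarchy) {
  stopifnot(inherits(motion, "skel_motion3d"),
            frame >= 1, frame <= motion$n_frames)
  h <- as_tibble(hierarchy)
  pos <- matrix(NA_real_, nrow(h), 3)
  rot <- vector("list", nrow(h))
  rownames(pos) <- h$joint
  for (k in seq_len(nrow(h))) {
    jname <- h$joint[k]
    ji <- match(jname, motion$joint_names)
    if (is.na(ji)) {
      abort(sprintf("hierarchy joint `%s` not in motion data.", jname),
            class = "skelgaze_validation_error")
    }
    q_local <- motion$rotations[frame, ji, ]
    if (is.na(h$parent[k])) {
      pos[k, ] <- motion$root[frame, ]
      rot[[k]] <- q_local
    } else {
      pk <- match(h$parent[k], h$joint)
      if (is.na(pk) || pk >= k) {
        abort("hierarchy must list parents before children.",
              class = "skelgaze_validation_error")
      }
      offset <- c(h$ox[k], h$oy[k], h$oz[k])
      pos[k, ] <- pos[pk, ] + quat_rotate_vec(rot[[pk]], offset)[1, ]
      rot[[k]] <- quat_mul(rot[[pk]], q_local)
    }
  }
  tibble(joint = h$joint, x = pos[, 1], y = pos[, 2], z = pos[, 3])
}
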