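#' Describe a media source
#'
#' A media source is one animated stimulus (a video or a rendered 3D motion
#' sequence) that viewers watched. Sources carry an optional partition into
#' analysis intervals (movement phases) and an optional reference mapping:
#' the name of another source this one is temporally warped onto so that
#' semantically equivalent gestures with different dynamics can be compared
#' on one time base.
#'
#' @param name Source name. Substrings of the name are used downstream to
#'   group and filter sources, so choose names with meaningful parts.
#' @param duration_ms Total duration in milliseconds (> 0).
#' @param intervals Optional data frame with columns `start_ms`, `end_ms`:
#'   non-overlapping, sorted, contained in `[0, duration_ms]`. When `NULL`
#'   or empty the whole `[0, duration_ms]` is one implicit interval.
#' @param reference Optional name of the reference source this source is
#'   warped onto.
#' @param format Skeleton payload format attached to this source:
#'   `"none"`, `"skeleton2d"` or `"motion3d"`.
#'
#' @return A one-row tibble with columns `name`, `duration_ms`, `format`,
#'   `reference` and a list-column `intervals`. Bind rows of several calls
#'   to build the experiment's source table.
#' @export
#' @examples
#' media_source("gym_c5_occ1", 30000)
media_source <- function(name, duration_ms, intervals = NULL,
                         reference = NA_character_,
                         format = c("none", "skeleton2d", "motion3d")) {
  format <- match.arg(format)
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "skelgaze_schema_error")
  }
  duration_ms <- as.numeric(duration_ms)
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    abort("`duration_ms` must be > 0.", class = "skelgaze_validation_error")
  }
  intervals <- validate_intervals(intervals, duration_ms)
  tibble(
    name = name, duration_ms = duration_ms, format = format,
    reference = as.character(reference), intervals = list(intervals)
  )
}

validate_intervals <- function(intervals, duration_ms) {
  if (is.null(intervals) || nrow(as.data.frame(intervals)) == 0L) {
    return(tibble(start_ms = 0, end_ms = duration_ms))
  }
  iv <- as_tibble(intervals)
  if (!all(c("start_ms", "end_ms") %in% names(iv))) {
    abort("intervals need columns `start_ms` and `end_ms`.",
          class = "skelgaze_schema_error")
  }
  iv <- iv[, c("start_ms", "end_ms")]
  iv$start_ms <- as.numeric(iv$start_ms)
  iv$end_ms <- as.numeric(iv$end_ms)
  if (any(iv$end_ms <= iv$start_ms)) {
    abort("each interval must satisfy end_ms > start_ms.",
          class = "skelgaze_validation_error")
  }
  if (any(iv$start_ms < 0) || any(iv$end_ms > duration_ms)) {
    abort("intervals must lie within [0, duration].",
          class = "skelgaze_validation_error")
  }
  if (is.unsorted(iv$start_ms, strictly = TRUE)) {
    abort("intervals must be sorted by start time.",
          class = "skelgaze_validation_error")
  }
  if (any(iv$start_ms[-1] < iv$end_ms[-nrow(iv)])) {
    abort("intervals must not overlap.", class = "skelgaze_validation_error")
  }
  iv
}

#' Validate a media-source table
#'
#' Checks every per-source invariant plus cross-source consistency of
#' `reference` links (a reference must name another source in the table).
#'
#' @param sources Tibble as built by [media_source()] rows.
#' @return The validated table, invisibly usable in pipes.
#' @export
validate_sources <- function(sources) {
  stopifnot(is.data.frame(sources))
  if (anyDuplicated(sources$name)) {
    abort("duplicate media source names.", class = "skelgaze_validation_error")
  }
  refs <- sources$reference[!is.na(sources$reference)]
  missing <- setdiff(refs, sources$name)
  if (length(missing)) {
    abort(paste0("reference mapping points to unknown source(s): ",
                 paste(missing, collapse = ", ")),
          class = "skelgaze_validation_error")
  }
  for (k in seq_len(nrow(sources))) {
    validate_intervals(sources$intervals[[k]], sources$duration_ms[k])
  }
  invisible(sources)
}

#' Build and validate a gaze-sample table
#'
#' Samples are screen gaze coordinates in pixels (origin top-left, y down)
#' with timestamps in milliseconds from media start, optionally pre-labelled
#' with the body-part AOI under the gaze (`joint`, empty string = gaze off
#' the character).
#'
#' @param t,x,y Numeric vectors of equal length.
#' @param joint Optional character vector of AOI labels ("" = off-character).
#' @return A tibble with columns `t`, `x`, `y`, `joint`, time-sorted.
#' @export
gaze_samples <- function(t, x, y, joint = NULL) {
  n <- length(t)
  joint <- joint %||% rep("", n)
  df <- tibble(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
               joint = as.character(joint))
  validate_samples(df)
}

#' @rdname gaze_samples
#' @param samples A data frame with at least `t`, `x`, `y` (and optionally
#'   `joint`) to validate.
#' @export
validate_samples <- function(samples) {
  df <- as_tibble(samples)
  need <- c("t", "x", "y")
  if (!all(need %in% names(df))) {
    abort("samples need columns t, x, y.", class = "skelgaze_schema_error")
  }
  if (!"joint" %in% names(df)) df$joint <- ""
  df$joint[is.na(df$joint)] <- ""
  if (any(df$t < 0)) {
    abort("sample times must be >= 0.", class = "skelgaze_validation_error")
  }
  if (nrow(df) > 1 && any(diff(df$t) <= 0)) {
    abort("sample times must be strictly increasing.",
          class = "skelgaze_validation_error")
  }
  df
}

#' Construct a keyframed 2D skeleton
#'
#' The 2D skeleton is the manual annotation layer drawn over a video: named
#' joints with parent links, bones carrying a drawn width (pixels) and a
#' depth level (smaller = nearer the camera, used to resolve overlap
#' masking), and joint positions keyframed on a subset of video frames.
#' Positions between keyframes are obtained by linear interpolation
#' ([interpolate_pose2d()]).
#'
#' @param joints Data frame with columns `name`, `parent` (`NA` for the
#'   root).
#' @param bones Data frame with columns `joint_a` (parent end), `joint_b`
#'   (child end, the bone's owning joint), `width_px` (> 0), `depth_level`
#'   (integer).
#' @param keyframes Data frame with columns `frame`, `joint`, `x`, `y`;
#'   frame indices must be strictly increasing per joint.
#' @param fps Video frame rate (frames per second).
#' @return An object of class `skel_skeleton2d`.
#' @export
skeleton2d <- function(joints, bones, keyframes, fps) {
  joints <- as_tibble(joints)
  bones <- as_tibble(bones)
  keyframes <- as_tibble(keyframes)
  stopifnot(all(c("name", "parent") %in% names(joints)),
            all(c("joint_a", "joint_b", "width_px", "depth_level") %in% names(bones)),
            all(c("frame", "joint", "x", "y") %in% names(keyframes)))
  bad <- setdiff(c(bones$joint_a, bones$joint_b), joints$name)
  if (length(bad)) {
    abort(paste0("bone endpoints reference unknown joints: ",
                 paste(unique(bad), collapse = ", ")),
          class = "skelgaze_validation_error")
  }
  if (any(bones$width_px <= 0)) {
    abort("bone widths must be > 0.", class = "skelgaze_validation_error")
  }
  bones$depth_level <- as.integer(bones$depth_level)
  if (anyNA(bones$depth_level)) {
    abort("depth levels must be integers.", class = "skelgaze_validation_error")
  }
  if (nrow(keyframes) == 0L) {
    abort("skeleton needs at least one keyframe.",
          class = "skelgaze_validation_error")
  }
  kf_frames <- sort(unique(keyframes$frame))
  per <- dplyr::count(keyframes, frame)
  if (length(unique(per$n)) != 1L) {
    abort("every keyframe must position every joint.",
          class = "skelgaze_validation_error")
  }
  structure(
    list(joints = joints, bones = bones,
         keyframes = dplyr::arrange(keyframes, frame, joint),
         kf_frames = kf_frames, fps = as.numeric(fps)),
    class = "skel_skeleton2d"
  )
}

#' @export
print.skel_skeleton2d <- function(x, ...) {
  cat(sprintf("<skel_skeleton2d> %d joints, %d bones, %d keyframes @ %g fps\n",
              nrow(x$joints), nrow(x$bones), length(x$kf_frames), x$fps))
  invisible(x)
}

#' Construct a 3D motion sequence
#'
#' Per-frame articulated posture: one unit quaternion per joint (local
#' rotation, `w,x,y,z` order) plus a root translation. Quaternions are
#' normalized on construction; a zero-norm quaternion is an error.
#'
#' @param joint_names Ordered character vector of the n joints.
#' @param rotations Numeric array `frames x n x 4` of quaternions.
#' @param root Numeric matrix `frames x 3` of root translations (defaults
#'   to zeros).
#' @param fps Frame rate.
#' @return An object of class `skel_motion3d`.
#' @export
motion3d <- function(joint_names, rotations, root = NULL, fps = 30) {
  stopifnot(is.array(rotations), length(dim(rotations)) == 3L,
            dim(rotations)[3] == 4L)
  n_frames <- dim(rotations)[1]
  n_joints <- dim(rotations)[2]
  if (n_joints != length(joint_names)) {
    abort("joint_names length must match the rotation array.",
          class = "skelgaze_validation_error")
  }
  nrm <- sqrt(apply(rotations^2, c(1, 2), sum))
  if (any(nrm < 1e-12)) {
    abort("zero-norm quaternion in motion data.",
          class = "skelgaze_validation_error")
  }
  rotations <- rotations / array(rep(nrm, 4), dim = dim(rotations))
  root <- root %||% matrix(0, n_frames, 3)
  root <- as.matrix(root)
  stopifnot(nrow(root) == n_frames, ncol(root) == 3L)
  structure(
    list(joint_names = joint_names, rotations = rotations, root = root,
         fps = as.numeric(fps), n_frames = n_frames, n_joints = n_joints),
    class = "skel_motion3d"
  )
}

#' @export
print.skel_motion3d <- function(x, ...) {
  cat(sprintf("<skel_motion3d> %d joints x %d frames @ %g fps\n",
              x$n_joints, x$n_frames, x$fps))
  invisible(x)
}

#' Construct a skinned mesh
#'
#' Vertices with triangle faces and per-vertex skinning weights binding the
#' mesh to skeleton joints. Weights must be non-negative and sum to one per
#' vertex (partition of unity, tolerance 1e-6) — the same weights used to
#' deform the mesh are reused to shade it into a heat mesh.
#'
#' @param vertices Numeric matrix `n x 3`.
#' @param faces Integer matrix `m x 3` of 1-based vertex indices.
#' @param weights Data frame with columns `vertex` (1-based index), `joint`
#'   (name), `w` (weight).
#' @param joint_names Optional character vector of valid joints; when given,
#'   every weighted joint must appear in it.
#' @return An object of class `skel_mesh`.
#' @export
skinned_mesh <- function(vertices, faces, weights, joint_names = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    abort("face indices out of range.", class = "skelgaze_validation_error")
  }
  weights <- as_tibble(weights)
  stopifnot(all(c("vertex", "joint", "w") %in% names(weights)))
  if (any(weights$w < 0)) {
    abort("skinning weights must be >= 0.", class = "skelgaze_validation_error")
  }
  sums <- tapply(weights$w, factor(weights$vertex, levels = seq_len(nrow(vertices))), sum)
  sums[is.na(sums)] <- 0
  if (any(abs(sums - 1) > 1e-6)) {
    abort("skinning weights must sum to 1 per vertex (tolerance 1e-6).",
          class = "skelgaze_validation_error")
  }
  if (!is.null(joint_names)) {
    bad <- setdiff(unique(weights$joint), joint_names)
    if (length(bad)) {
      abort(paste0("weights reference unknown joints: ",
                   paste(bad, collapse = ", ")),
            class = "skelgaze_validation_error")
    }
  }
  structure(list(vertices = vertices, faces = faces, weights = weights),
            class = "skel_mesh")
}

#' @export
print.skel_mesh <- function(x, ...) {
  cat(sprintf("<skel_mesh> %d vertices, %d faces, %d joints weighted\n",
              nrow(x$vertices), nrow(x$faces), length(unique(x$weights$joint))))
  invisible(x)
}

#' Construct a pinhole camera
#'
#' Minimal projective camera used to cast gaze rays into the 3D scene.
#' Convention: the camera looks along its local +z axis, x right, y up;
#' screen pixels have the origin at the top-left with y pointing down and
#' the principal point at the image center.
#'
#' @param width_px,height_px Image size in pixels.
#' @param focal_px Focal length in pixels (> 0). Alternatively give
#'   `fov_y_deg` (vertical field of view) and the focal length is derived.
#' @param fov_y_deg Vertical field of view in degrees (ignored when
#'   `focal_px` is given).
#' @param position Length-3 camera position in scene coordinates.
#' @param orientation Unit quaternion `c(w, x, y, z)` rotating camera-local
#'   directions into scene coordinates.
#' @return An object of class `skel_camera`.
#' @export
pinhole_camera <- function(width_px, height_px, focal_px = NULL,
                           fov_y_deg = 60, position = c(0, 0, 0),
                           orientation = c(1, 0, 0, 0)) {
  if (is.null(focal_px)) {
    focal_px <- (height_px / 2) / tan(fov_y_deg * pi / 360)
  }
  if (!is.finite(focal_px) || focal_px <= 0) {
    abort("focal length must be > 0.", class = "skelgaze_validation_error")
  }
  orientation <- as.numeric(orientation)
  nrm <- sqrt(sum(orientation^2))
  if (nrm < 1e-12) {
    abort("camera orientation quaternion has zero norm.",
          class = "skelgaze_validation_error")
  }
  structure(
    list(width_px = width_px, height_px = height_px, focal_px = focal_px,
         position = as.numeric(position), orientation = orientation / nrm),
    class = "skel_camera"
  )
}
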