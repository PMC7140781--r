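#' Quaternion helpers
#'
#' Hamilton product of two quaternions in `c(w, x, y, z)` order.
#'
#' @param a,b Length-4 numeric quaternions.
#' @return Length-4 quaternion.
#' @export
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Geodesic distance between two rotations
#'
#' `d = ||Log(qa^-1 qb)||` on the unit quaternion group, with the
#' antipodal double cover collapsed (`q` and `-q` are the same rotation),
#' so the distance lies in `[0, pi/2]` in half-angle units: a relative
#' rotation by angle `theta` gives `d = theta / 2`. Symmetric, and zero
#' exactly when both quaternions encode the same rotation. Inputs are
#' normalized on entry; a zero-norm quaternion is an error.
#'
#' @param qa,qb Length-4 quaternions `c(w, x, y, z)`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' quat_geodesic(c(1, 0, 0, 0), c(cos(pi / 4), 0, 0, sin(pi / 4))) # pi/4
quat_geodesic <- function(qa, qb) {
  na <- sqrt(sum(qa^2)); nb <- sqrt(sum(qb^2))
  if (na < 1e-12 || nb < 1e-12) {
    abort("zero-norm quaternion.", class = "skelgaze_validation_error")
  }
  d <- abs(sum(qa * qb) / (na * nb))
  acos(min(d, 1))
}

#' Posture distance between two skeleton frames
#'
#' Unweighted sum over the skeleton's n joints of the quaternion geodesic
#' distance between corresponding joint rotations. Root translation is
#' excluded: the distance compares joint angles only. An optional
#' per-joint weight vector is accepted for sensitivity analyses.
#'
#' @param qa,qb Numeric `n x 4` matrices of per-joint quaternions.
#' @param weights Optional length-n non-negative weights (default all 1).
#' @return Non-negative scalar, zero iff the postures encode identical
#'   rotations.
#' @export
posture_distance <- function(qa, qb, weights = NULL) {
  qa <- matrix(qa, ncol = 4); qb <- matrix(qb, ncol = 4)
  if (nrow(qa) != nrow(qb)) {
    abort("postures have different joint counts.",
          class = "skelgaze_validation_error")
  }
  w <- weights %||% rep(1, nrow(qa))
  d <- vapply(seq_len(nrow(qa)), function(j)
    quat_geodesic(qa[j, ], qb[j, ]), 1.0)
  sum(w * d)
}

posture_cost_matrix <- function(seqA, seqB, weights = NULL) {
  nA <- seqA$n_frames; nB <- seqB$n_frames; n <- seqA$n_joints
  w <- weights %||% rep(1, n)
  D <- matrix(0, nA, nB)
  for (j in seq_len(n)) {
    QA <- matrix(seqA$rotations[, j, ], ncol = 4)
    QB <- matrix(seqB$rotations[, j, ], ncol = 4)
    dot <- abs(QA %*% t(QB))
    D <- D + w[j] * acos(pmin(dot, 1))
  }
  D
}

#' Align two motion sequences with dynamic time warping
#'
#' Computes the full matrix of pairwise posture distances
#' ([posture_distance()]) between the frames of a reference sequence A and
#' a second sequence B, then the globally optimal monotone warping path
#' with steps (1,0), (0,1), (1,1) (plain DTW: no step weights, no band).
#' Ties during backtracking prefer the diagonal step. The resulting
#' correspondence lets gaze timelines recorded on B be replayed on A's
#' time base ([remap_time()]).
#'
#' @param seqA,seqB `skel_motion3d` sequences with identical joint lists.
#' @param weights Optional per-joint weights for the posture distance.
#' @return Object of class `skel_dtw`: `cost_matrix`, `path` (tibble `i`,
#'   `j`, 1-based), `cost` (total path cost), `fps_a`, `fps_b`.
#' @export
dtw_align <- function(seqA, seqB, weights = NULL) {
  stopifnot(inherits(seqA, "skel_motion3d"), inherits(seqB, "skel_motion3d"))
  if (seqA$n_frames < 1 || seqB$n_frames < 1) {
    abort("empty motion sequence.", class = "skelgaze_validation_error")
  }
  if (!identical(seqA$joint_names, seqB$joint_names)) {
    abort("sequences have different joint lists.",
          class = "skelgaze_validation_error")
  }
  D <- posture_cost_matrix(seqA, seqB, weights)
  nA <- nrow(D); nB <- ncol(D)
  acc <- matrix(Inf, nA, nB)
  acc[1, 1] <- D[1, 1]
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1 && j > 1) best <- min(best, acc[i - 1, j - 1])
      if (i > 1) best <- min(best, acc[i - 1, j])
      if (j > 1) best <- min(best, acc[i, j - 1])
      acc[i, j] <- D[i, j] + best
    }
  }
  # backtrack, diagonal preferred on ties
  path <- list(c(nA, nB))
  i <- nA; j <- nB
  while (i > 1 || j > 1) {
    if (i == 1) {
      j <- j - 1
    } else if (j == 1) {
      i <- i - 1
    } else {
      cand <- c(acc[i - 1, j - 1], acc[i - 1, j], acc[i, j - 1])
      k <- which.min(cand) # which.min takes the first minimum: diagonal wins ties
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) i <- i - 1
      else j <- j - 1
    }
    path[[length(path) + 1L]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  structure(
    list(cost_matrix = D,
         path = tibble(i = path[, 1], j = path[, 2]),
         cost = acc[nA, nB],
         fps_a = seqA$fps, fps_b = seqB$fps),
    class = "skel_dtw"
  )
}

#' @export
print.skel_dtw <- function(x, ...) {
  cat(sprintf("<skel_dtw> %d x %d frames, path length %d, cost %.6g\n",
              nrow(x$cost_matrix), ncol(x$cost_matrix), nrow(x$path), x$cost))
  invisible(x)
}

#' @export
tidy.skel_dtw <- function(x, ...) {
  p <- x$path
  p$cost <- x$cost_matrix[cbind(p$i, p$j)]
  p
}

#' @export
glance.skel_dtw <- function(x, ...) {
  tibble(cost = x$cost, n_a = nrow(x$cost_matrix), n_b = ncol(x$cost_matrix),
         path_length = nrow(x$path))
}

#' @export
autoplot.skel_dtw <- function(object, ...) {
  D <- object$cost_matrix
  df <- tidyr::expand_grid(i = seq_len(nrow(D)), j = seq_len(ncol(D)))
  df$d <- D[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = j, y = i, fill = d)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#08306b", high = "#f7fbff",
                                 name = "posture\ndistance") +
    ggplot2::geom_path(data = object$path,
                       ggplot2::aes(x = j, y = i), inherit.aes = FALSE,
                       color = "black", linewidth = 0.8) +
    ggplot2::labs(x = "sequence B frame", y = "reference frame",
                  title = "Time-warping matrix and optimal path") +
    ggplot2::theme_minimal()
}

#' Remap a time point through a warping path
#'
#' Maps a time in sequence B onto the reference sequence A's time base
#' using the DTW correspondence: each B frame maps to the mean of its
#' matched A frame times, and times between frame centers interpolate
#' linearly, giving a monotone non-decreasing remap. The first and last B
#' frames are pinned to the reference's first and last frame times so the
#' remap covers the reference's full range. Out-of-range times clamp to
#' the sequence bounds.
#'
#' @param alignment A `skel_dtw` from [dtw_align()].
#' @param t_in_b Numeric vector of times (ms) in sequence B.
#' @return Numeric vector of times (ms) in sequence A.
#' @export
remap_time <- function(alignment, t_in_b) {
  stopifnot(inherits(alignment, "skel_dtw"))
  p <- alignment$path
  a_mean <- tapply(p$i, p$j, mean)
  jb <- as.numeric(names(a_mean))
  tb <- (jb - 1) * 1000 / alignment$fps_b
  ta <- (a_mean - 1) * 1000 / alignment$fps_a
  # pin the endpoints so the remap covers the reference's full frame range
  ta[1] <- 0
  ta[length(ta)] <- (nrow(alignment$cost_matrix) - 1) * 1000 / alignment$fps_a
  approx(tb, ta, xout = pmin(pmax(t_in_b, min(tb)), max(tb)),
         rule = 2, ties = "ordered")$y
}
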