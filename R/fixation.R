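#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' A fixation is a pause of the gaze over an informative region: a window of
#' consecutive samples whose spatial dispersion stays within a threshold
#' (default 1 degree of visual angle) and that lasts strictly longer than a
#' minimum duration (default 100 ms). Dispersion is measured as
#' `(max x - min x) + (max y - min y)` over the window, converted to
#' degrees through `px_per_deg`. Windows are grown greedily: a candidate
#' window spanning the minimum duration is extended sample-by-sample while
#' the dispersion stays within threshold, then emitted.
#'
#' @param samples Data frame with columns `t` (ms, strictly increasing),
#'   `x`, `y` (pixels).
#' @param dispersion_deg Dispersion threshold in degrees.
#' @param min_duration_ms Minimum fixation duration in ms (strict: a
#'   fixation must last more than this).
#' @param px_per_deg Pixels per degree of visual angle (> 0), supplied by
#'   the user from the viewing geometry.
#' @return Tibble of fixations: `start_ms`, `end_ms`, `duration_ms`,
#'   `cx`, `cy` (centroid = mean of member samples), `first_idx`,
#'   `last_idx` (row range into `samples`). Fewer than two samples give an
#'   empty table.
#' @export
#' @examples
#' s <- gaze_samples(t = 0:299, x = rep(100, 300), y = rep(100, 300))
#' detect_fixations(s, px_per_deg = 40)
detect_fixations <- function(samples, dispersion_deg = 1,
                             min_duration_ms = 100, px_per_deg) {
  if (missing(px_per_deg) || !is.numeric(px_per_deg) || px_per_deg <= 0) {
    abort("`px_per_deg` must be a positive scalar.",
          class = "skelgaze_validation_error")
  }
  df <- as_tibble(samples)
  empty <- tibble(start_ms = numeric(), end_ms = numeric(),
                  duration_ms = numeric(), cx = numeric(), cy = numeric(),
                  first_idx = integer(), last_idx = integer())
  n <- nrow(df)
  if (n < 2L) return(empty)
  if (any(diff(df$t) <= 0)) {
    abort("samples must be strictly time-sorted.",
          class = "skelgaze_validation_error")
  }
  thr_px <- dispersion_deg * px_per_deg
  t <- df$t; x <- df$x; y <- df$y
  out <- vector("list", 0L)
  i <- 1L
  while (i <= n) {
    # smallest window from i spanning at least the minimum duration
    j <- i
    while (j <= n && t[j] - t[i] < min_duration_ms) j <- j + 1L
    if (j > n) break
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    if ((xmax - xmin) + (ymax - ymin) <= thr_px) {
      while (j < n) {
        nx <- x[j + 1L]; ny <- y[j + 1L]
        d <- (max(xmax, nx) - min(xmin, nx)) + (max(ymax, ny) - min(ymin, ny))
        if (d > thr_px) break
        j <- j + 1L
        xmin <- min(xmin, nx); xmax <- max(xmax, nx)
        ymin <- min(ymin, ny); ymax <- max(ymax, ny)
      }
      if (t[j] - t[i] > min_duration_ms) {
        out[[length(out) + 1L]] <- tibble(
          start_ms = t[i], end_ms = t[j], duration_ms = t[j] - t[i],
          cx = mean(x[i:j]), cy = mean(y[i:j]),
          first_idx = i, last_idx = j
        )
        i <- j + 1L
      } else {
        # the window met the dispersion bound but only spans exactly the
        # minimum duration: slide, a longer window may start one sample on
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Assign a fixation to a body-part AOI
#'
#' The fixation inherits the majority joint label among its member samples'
#' non-empty labels; a fixation whose samples are all off-character gets no
#' joint (`NA`). Ties are broken in favor of the label whose first
#' occurrence within the fixation is earliest.
#'
#' @param labels Character vector of the fixation's member-sample joint
#'   labels ("" = off-character).
#' @return A joint name, or `NA_character_` when all labels are empty.
#' @export
assign_fixation_joint <- function(labels) {
  labels <- as.character(labels)
  labels <- labels[!is.na(labels) & nzchar(labels)]
  if (!length(labels)) return(NA_character_)
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  firsts <- vapply(top, function(l) which(labels == l)[1], 1L)
  top[which.min(firsts)]
}

#' Attach joint assignments to a fixation table
#'
#' Applies [assign_fixation_joint()] to every fixation using the labelled
#' samples the fixations were detected from.
#'
#' @param fixations Fixation tibble from [detect_fixations()].
#' @param samples The same sample table, with a `joint` column.
#' @return The fixation tibble with a `joint` column added.
#' @export
assign_fixation_joints <- function(fixations, samples) {
  samples <- as_tibble(samples)
  if (!"joint" %in% names(samples)) samples$joint <- ""
  fixations$joint <- vapply(seq_len(nrow(fixations)), function(k) {
    idx <- fixations$first_idx[k]:fixations$last_idx[k]
    assign_fixation_joint(samples$joint[idx])
  }, NA_character_)
  fixations
}

#' Accumulate per-joint fixation time T(j)
#'
#' Sums the durations of fixations assigned to each joint over one analysis
#' interval. A fixation straddling an interval boundary contributes only
#' its inside part (proportional clipping by time; the joint assignment is
#' not re-evaluated per part). Fixations without a joint contribute
#' nothing, so the total over joints never exceeds the interval length.
#'
#' @param fixations Fixation tibble with a `joint` column (one capture).
#' @param interval Length-2 numeric `c(start_ms, end_ms)`.
#' @return Tibble `joint`, `t_ms`, one row per joint with positive time,
#'   sorted by joint.
#' @export
joint_time_map <- function(fixations, interval) {
  interval <- as.numeric(interval)
  if (length(interval) != 2L || !all(is.finite(interval)) ||
      interval[2] <= interval[1]) {
    abort("`interval` must be c(start, end) with end > start.",
          class = "skelgaze_validation_error")
  }
  fx <- as_tibble(fixations)
  if (!nrow(fx)) return(tibble(joint = character(), t_ms = numeric()))
  inside <- pmax(0, pmin(fx$end_ms, interval[2]) - pmax(fx$start_ms, interval[1]))
  keep <- !is.na(fx$joint) & inside > 0
  if (!any(keep)) return(tibble(joint = character(), t_ms = numeric()))
  tibble(joint = fx$joint[keep], t_ms = inside[keep]) |>
    dplyr::group_by(joint) |>
    dplyr::summarise(t_ms = sum(t_ms), .groups = "drop") |>
    dplyr::arrange(joint)
}
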