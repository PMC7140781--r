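#' Normalization constant for the heat mesh
#'
#' Three alternative definitions of the normalization `T_MAX` dividing the
#' per-joint fixation times in the vertex-color formula:
#' metric 1 — the total duration of the interval (fixations on and off the
#' character plus saccades all count toward the denominator);
#' metric 2 — the on-character total `sum_j T(j)`;
#' metric 3 — the per-joint maximum `max_j T(j)`.
#' By construction metric 3 <= metric 2 <= metric 1.
#'
#' @param metric 1, 2 or 3.
#' @param T_map Tibble `joint`, `t_ms` ([joint_time_map()]).
#' @param interval Length-2 numeric `c(start_ms, end_ms)` (used by
#'   metric 1).
#' @return Positive scalar. Metrics 2 and 3 with an all-zero map are an
#'   error (the normalization is undefined).
#' @export
t_max <- function(metric, T_map, interval) {
  interval <- as.numeric(interval)
  if (length(interval) != 2L || interval[2] <= interval[1]) {
    abort("`interval` must be c(start, end) with end > start.",
          class = "skelgaze_validation_error")
  }
  if (!metric %in% 1:3) {
    abort("`metric` must be 1, 2 or 3.", class = "skelgaze_validation_error")
  }
  if (metric == 1) return(interval[2] - interval[1])
  tot <- sum(T_map$t_ms)
  if (tot <= 0) {
    abort("T_MAX metrics 2 and 3 are undefined for an all-zero T map.",
          class = "skelgaze_validation_error")
  }
  if (metric == 2) tot else max(T_map$t_ms)
}

#' Color a skinned mesh by per-joint fixation time
#'
#' The heat mesh: every vertex gets the scalar color
#' `v_c = sum_j w(v, j) * T(j) / t_max`, clipped to `[0, 1]` — the same
#' linear-blend skinning weights that deform the mesh shade it, so colors
#' blend smoothly across body-part boundaries.
#'
#' @param mesh A `skel_mesh`.
#' @param T_map Tibble `joint`, `t_ms`.
#' @param t_max Positive normalization constant (see [t_max()]).
#' @return Object of class `skel_heat_mesh`: tibble `vertex`, `v_c` with
#'   the mesh attached as an attribute.
#' @export
vertex_colors <- function(mesh, T_map, t_max) {
  stopifnot(inherits(mesh, "skel_mesh"))
  if (!is.numeric(t_max) || t_max <= 0) {
    abort("`t_max` must be > 0.", class = "skelgaze_validation_error")
  }
  w <- mesh$weights
  tj <- setNames(T_map$t_ms, T_map$joint)
  contrib <- w$w * unname(tj[w$joint])
  contrib[is.na(contrib)] <- 0
  v_c <- tapply(contrib, factor(w$vertex, levels = seq_len(nrow(mesh$vertices))), sum)
  v_c[is.na(v_c)] <- 0
  out <- tibble(vertex = seq_len(nrow(mesh$vertices)),
                v_c = pmin(pmax(as.numeric(v_c) / t_max, 0), 1))
  structure(out, class = c("skel_heat_mesh", class(out)), mesh = mesh)
}

#' @export
autoplot.skel_heat_mesh <- function(object, ...) {
  mesh <- attr(object, "mesh")
  df <- tibble(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
               v_c = object$v_c)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, color = v_c)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_gradient(low = "#2166ac", high = "#b2182b",
                                  limits = c(0, 1), name = "normalized\nfixation time") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Heat mesh (vertex colors)") +
    ggplot2::theme_minimal()
}

#' Average per-joint fixation times over viewers
#'
#' Multi-viewer heat meshes are colored from the arithmetic mean of the
#' viewers' T(j) maps; a joint absent from a viewer's map counts as 0 for
#' that viewer.
#'
#' @param T_maps Non-empty list of `joint`/`t_ms` tibbles sharing one
#'   (media, interval) scope.
#' @return A single `joint`/`t_ms` tibble.
#' @export
average_viewers <- function(T_maps) {
  if (!length(T_maps)) {
    abort("need at least one T map.", class = "skelgaze_validation_error")
  }
  k <- length(T_maps)
  dplyr::bind_rows(T_maps) |>
    dplyr::group_by(joint) |>
    dplyr::summarise(t_ms = sum(t_ms) / k, .groups = "drop") |>
    dplyr::arrange(joint)
}

new_timeline <- function(joint, steps, step_ms, pct_timeline, pct_block,
                         mode, viewer = NA_character_) {
  structure(
    list(joint = joint, steps = steps, step_ms = step_ms,
         percentage_timeline = pct_timeline, percentage_block = pct_block,
         mode = mode, viewer = viewer),
    class = "skel_timeline"
  )
}

#' @export
print.skel_timeline <- function(x, ...) {
  cat(sprintf("<skel_timeline %s> joint %s, %d steps of %g ms, timeline %.1f%%, block %.1f%%\n",
              x$mode, x$joint, nrow(x$steps), x$step_ms,
              x$percentage_timeline, x$percentage_block))
  invisible(x)
}

#' @export
tidy.skel_timeline <- function(x, ...) {
  out <- x$steps
  out$joint <- x$joint
  out$viewer <- x$viewer
  out$mode <- x$mode
  out
}

#' Single-viewer timeline for one body part
#'
#' Discretizes one capture's fixations on a joint into a binary watch
#' trace: a step is 1 when a fixation assigned to the joint covers any
#' part of it. Two percentages summarize the block: the timeline
#' percentage is the joint's fixation time over the interval length; the
#' block percentage is its share of the on-character fixation time only.
#'
#' @param fixations Fixation tibble with `joint` (one capture).
#' @param joint Body-part name.
#' @param interval Length-2 `c(start_ms, end_ms)`.
#' @param step_ms Step size (> 0); defaults to the media frame period when
#'   you pass `1000 / fps`.
#' @param viewer Optional viewer id carried along for display.
#' @return A `skel_timeline` (mode `"single"`, values in {0, 1}).
#' @export
single_timeline <- function(fixations, joint, interval, step_ms,
                            viewer = NA_character_) {
  if (!is.numeric(step_ms) || step_ms <= 0) {
    abort("`step_ms` must be > 0.", class = "skelgaze_validation_error")
  }
  interval <- as.numeric(interval)
  n_steps <- ceiling((interval[2] - interval[1]) / step_ms - 1e-9)
  starts <- interval[1] + (seq_len(n_steps) - 1) * step_ms
  fx <- dplyr::filter(as_tibble(fixations), !is.na(.data$joint),
                      .data$joint == !!joint)
  value <- vapply(starts, function(s0) {
    s1 <- min(s0 + step_ms, interval[2])
    as.numeric(any(fx$start_ms < s1 & fx$end_ms > s0))
  }, 1.0)
  Tall <- joint_time_map(fixations, interval)
  tj <- sum(Tall$t_ms[Tall$joint == joint])
  tot <- sum(Tall$t_ms)
  new_timeline(
    joint, tibble(step_start = starts, value = value), step_ms,
    pct_timeline = 100 * tj / (interval[2] - interval[1]),
    pct_block = if (tot > 0) 100 * tj / tot else 0,
    mode = "single", viewer = viewer
  )
}

#' Aggregate several timelines for one body part
#'
#' Aggregated mode: the per-step mean of the binary traces (several
#' occurrences or viewers of the same motion; timelines over different
#' but semantically equivalent sources must first be brought onto the
#' reference time base through [remap_time()]), normalized by the maximum
#' mean observed among all displayed body parts for the interval.
#'
#' @param timelines Non-empty list of `skel_timeline`s sharing joint and
#'   step grid.
#' @param norm_max Normalization constant: the maximum per-step mean over
#'   all displayed joints. Default `NULL` normalizes by this block's own
#'   maximum.
#' @return A `skel_timeline` (mode `"aggregated"`, values in `[0, 1]`).
#' @export
aggregate_timelines <- function(timelines, norm_max = NULL) {
  if (!length(timelines)) {
    abort("need at least one timeline.", class = "skelgaze_validation_error")
  }
  grids <- lapply(timelines, function(tl) tl$steps$step_start)
  if (length(unique(vapply(grids, length, 1L))) != 1L ||
      !all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])), TRUE))) {
    abort("timelines must share one step grid (remap first).",
          class = "skelgaze_validation_error")
  }
  vals <- rowMeans(do.call(cbind, lapply(timelines, function(tl) tl$steps$value)))
  norm_max <- norm_max %||% max(vals)
  norm <- if (norm_max > 0) pmin(vals / norm_max, 1) else vals
  new_timeline(
    timelines[[1]]$joint,
    tibble(step_start = grids[[1]], value = norm),
    timelines[[1]]$step_ms,
    pct_timeline = mean(vapply(timelines, function(tl) tl$percentage_timeline, 1.0)),
    pct_block = mean(vapply(timelines, function(tl) tl$percentage_block, 1.0)),
    mode = "aggregated"
  )
}

#' Timeline block across body parts
#'
#' Builds the aggregated timeline of every requested joint from a set of
#' captures, applying the cross-joint max normalization the aggregated
#' display uses.
#'
#' @param fixation_sets Named (by viewer/capture) list of fixation tibbles
#'   with `joint`.
#' @param joints Character vector of body parts to display.
#' @param interval,step_ms As in [single_timeline()].
#' @return Named list of aggregated `skel_timeline`s.
#' @export
timeline_block <- function(fixation_sets, joints, interval, step_ms) {
  singles <- lapply(joints, function(j)
    lapply(fixation_sets, single_timeline, joint = j, interval = interval,
           step_ms = step_ms))
  names(singles) <- joints
  means <- lapply(singles, function(tls)
    rowMeans(do.call(cbind, lapply(tls, function(tl) tl$steps$value))))
  norm_max <- max(vapply(means, max, 1.0))
  out <- lapply(joints, function(j)
    aggregate_timelines(singles[[j]], norm_max = norm_max))
  names(out) <- joints
  out
}

#' @export
autoplot.skel_timeline <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = step_start, y = 1, fill = value)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 limits = c(0, 1),
                                 name = if (object$mode == "single") "watched" else "share") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = sprintf("%s — timeline %.1f%%, block %.1f%%",
                                  object$joint, object$percentage_timeline,
                                  object$percentage_block)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Per-interval heat meshes
#'
#' A movement is often a concatenation of phases; this computes one heat
#' mesh per declared interval, each from the fixation time accumulated
#' inside that interval only. An interval without fixations yields an
#' all-zero mesh under metric 1 (metrics 2 and 3 are undefined there and
#' fall back to metric 1 with a warning).
#'
#' @param mesh A `skel_mesh`.
#' @param fixations Fixation tibble with `joint`.
#' @param intervals Tibble `start_ms`, `end_ms`.
#' @param metric `T_MAX` metric (1, 2 or 3).
#' @return Tibble with `start_ms`, `end_ms` and a list-column `heat` of
#'   `skel_heat_mesh` objects.
#' @export
partition_by_intervals <- function(mesh, fixations, intervals, metric = 1) {
  iv <- as_tibble(intervals)
  heats <- lapply(seq_len(nrow(iv)), function(k) {
    interval <- c(iv$start_ms[k], iv$end_ms[k])
    Tk <- joint_time_map(fixations, interval)
    tm <- if (metric != 1 && sum(Tk$t_ms) <= 0) {
      warn("empty interval: falling back to metric 1 normalization.",
           class = "skelgaze_empty_interval")
      t_max(1, Tk, interval)
    } else {
      t_max(metric, Tk, interval)
    }
    vertex_colors(mesh, Tk, tm)
  })
  iv$heat <- heats
  iv
}
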