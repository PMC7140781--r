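#' Fixation statistics for a body-part AOI
#'
#' For one joint within an interval: the number and mean duration of the
#' fixations assigned to it, plus the merged-run view, where consecutive
#' fixations on the joint with no differently-assigned fixation between
#' them are summed into one run (adjacent-fixation merging). By
#' construction the merged runs conserve total duration and never
#' outnumber the fixations.
#'
#' @param fixations Time-ordered fixation tibble with `joint`.
#' @param joint Body-part name, or `NULL` for one row per joint present.
#' @param interval Optional `c(start_ms, end_ms)`; fixations straddling
#'   the boundary are clipped proportionally.
#' @return Tibble with columns `joint`, `n_fixations`, `mean_duration_ms`,
#'   `n_merged_runs` and list-column `merged_run_durations_ms`.
#' @export
aoi_fixation_stats <- function(fixations, joint = NULL, interval = NULL) {
  fx <- as_tibble(fixations)
  if (nrow(fx) && is.unsorted(fx$start_ms)) {
    abort("fixations must be time-ordered.", class = "skelgaze_validation_error")
  }
  dur <- fx$duration_ms
  if (!is.null(interval)) {
    interval <- as.numeric(interval)
    dur <- pmax(0, pmin(fx$end_ms, interval[2]) - pmax(fx$start_ms, interval[1]))
    keep <- dur > 0
    fx <- fx[keep, ]; dur <- dur[keep]
  }
  joints <- joint %||% sort(unique(fx$joint[!is.na(fx$joint)]))
  rows <- lapply(joints, function(jn) {
    on <- !is.na(fx$joint) & fx$joint == jn
    if (!any(on)) {
      return(tibble(joint = jn, n_fixations = 0L, mean_duration_ms = NA_real_,
                    n_merged_runs = 0L, merged_run_durations_ms = list(numeric())))
    }
    r <- rle(on)
    run_id <- rep(seq_along(r$lengths), r$lengths)
    runs <- tapply(dur[on], run_id[on], sum)
    tibble(joint = jn, n_fixations = sum(on),
           mean_duration_ms = mean(dur[on]),
           n_merged_runs = length(runs),
           merged_run_durations_ms = list(as.numeric(runs)))
  })
  dplyr::bind_rows(rows)
}

#' Select rarely scanned body parts
#'
#' Joints holding less than a threshold fraction (default 1%) of the total
#' pooled scanning time across viewers. Fixations on such parts tend to
#' mark events (e.g. execution errors) rather than sustained attention,
#' which makes them natural candidates for synchronization analysis.
#'
#' @param T_maps List of per-viewer `joint`/`t_ms` tibbles sharing one
#'   scope.
#' @param threshold_fraction Rarity threshold on the pooled share.
#' @return Character vector of joint names (possibly empty).
#' @export
rare_aois <- function(T_maps, threshold_fraction = 0.01) {
  pooled <- dplyr::bind_rows(T_maps) |>
    dplyr::group_by(joint) |>
    dplyr::summarise(t_ms = sum(t_ms), .groups = "drop")
  total <- sum(pooled$t_ms)
  if (total <= 0) return(character(0))
  sort(pooled$joint[pooled$t_ms / total < threshold_fraction])
}

#' Overlap duration: how long viewers watch a part simultaneously
#'
#' The synchronization statistic: total time during which at least a given
#' fraction of the viewers (default one third, count rounded up so "at
#' least a third of 9" means 3) are simultaneously watching the body part.
#' Input timelines must share one step grid; the result is the sum of the
#' step sizes of the steps meeting the threshold.
#'
#' @param timelines Non-empty list of single-mode `skel_timeline`s for one
#'   joint, one per viewer, on a common grid.
#' @param min_fraction Required fraction of viewers.
#' @return Overlap duration in milliseconds.
#' @export
overlap_duration <- function(timelines, min_fraction = 1 / 3) {
  if (!length(timelines)) {
    abort("need at least one viewer timeline.",
          class = "skelgaze_validation_error")
  }
  vals <- do.call(cbind, lapply(timelines, function(tl) tl$steps$value))
  need <- ceiling(min_fraction * length(timelines))
  step_ms <- timelines[[1]]$step_ms
  sum(rowSums(vals >= 1) >= need) * step_ms
}

#' Group summary (mean, sd, n)
#'
#' @param mean,sd,n Summary statistics of one group (`sd >= 0`, `n >= 2`).
#' @return A validated list of class `skel_group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) abort("sd must be >= 0.", class = "skelgaze_validation_error")
  if (n < 2) abort("n must be >= 2.", class = "skelgaze_validation_error")
  structure(list(mean = mean, sd = sd, n = n), class = "skel_group_summary")
}

#' Welch two-sample t-test from group summaries
#'
#' Computes the unequal-variance t statistic
#' `t = (m_a - m_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with the
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value —
#' directly from printed group summaries, so published comparisons can be
#' recomputed without the raw per-subject data.
#'
#' @param a,b `skel_group_summary` objects ([group_summary()]).
#' @return Object of class `skel_welch` with `statistic`, `df`, `p.value`
#'   and the inputs; `tidy()` and `glance()` return a one-row tibble.
#' @export
#' @examples
#' welch_t(group_summary(38, 9.3, 5), group_summary(38.5, 8.9, 5))
welch_t <- function(a, b) {
  stopifnot(inherits(a, "skel_group_summary"), inherits(b, "skel_group_summary"))
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    if (a$mean == b$mean) {
      return(structure(list(statistic = 0, df = a$n + b$n - 2, p.value = 1,
                            a = a, b = b), class = "skel_welch"))
    }
    abort("degenerate input: zero variance in both groups with unequal means.",
          class = "skelgaze_validation_error")
  }
  t_stat <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * pt(-abs(t_stat), df)
  structure(list(statistic = t_stat, df = df, p.value = p, a = a, b = b),
            class = "skel_welch")
}

#' @export
print.skel_welch <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test from summaries: t(%.4g) = %.4g, p = %.4g\n",
              x$df, x$statistic, x$p.value))
  invisible(x)
}

#' @export
tidy.skel_welch <- function(x, ...) {
  tibble(estimate = x$a$mean - x$b$mean, statistic = x$statistic,
         df = x$df, p.value = x$p.value)
}

#' @export
glance.skel_welch <- function(x, ...) tidy(x)

#' Wilcoxon rank-sum on raw vectors
#'
#' Thin wrapper over [stats::wilcox.test()] returning a tidy one-row
#' tibble, for comparisons where raw per-trial values are available.
#'
#' @param x,y Numeric vectors.
#' @param ... Passed to [stats::wilcox.test()].
#' @return Tibble with `statistic` (W) and `p.value`.
#' @export
rank_sum <- function(x, y, ...) {
  ht <- stats::wilcox.test(x, y, ...)
  tibble(statistic = unname(ht$statistic), p.value = ht$p.value)
}
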