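# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written in the most literal way possible and share
# no code with the package internals.

# I-DT by sample-by-sample window growth, recomputing the dispersion of the
# whole window from scratch at every step.
oracle_idt <- function(samples, dispersion_deg = 1, min_duration_ms = 100,
                       px_per_deg = 40) {
  t <- samples$t; x <- samples$x; y <- samples$y
  n <- length(t)
  thr <- dispersion_deg * px_per_deg
  disp <- function(i, j) {
    (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
  }
  res <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && disp(i, j + 1L) <= thr) j <- j + 1L
    if (t[j] - t[i] > min_duration_ms) {
      res[[length(res) + 1L]] <- data.frame(
        start_ms = t[i], end_ms = t[j],
        cx = mean(x[i:j]), cy = mean(y[i:j]),
        first_idx = i, last_idx = j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(res)) {
    return(data.frame(start_ms = numeric(), end_ms = numeric(),
                      cx = numeric(), cy = numeric(),
                      first_idx = integer(), last_idx = integer()))
  }
  do.call(rbind, res)
}

# All-bones scan for the 2D sample-joint mapping: explicit loop over every
# bone, keeping every candidate, then sorting by (depth, distance).
oracle_map2d <- function(px, py, bands, exclusion_deg = 0.5, px_per_deg = 40) {
  best <- ""
  best_depth <- Inf
  best_dist <- Inf
  for (k in seq_len(nrow(bands))) {
    ax <- bands$ax[k]; ay <- bands$ay[k]
    bx <- bands$bx[k]; by <- bands$by[k]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    u <- if (L2 == 0) 0 else ((px - ax) * vx + (py - ay) * vy) / L2
    u <- max(0, min(1, u))
    d <- sqrt((px - (ax + u * vx))^2 + (py - (ay + u * vy))^2)
    if (d <= bands$half_width[k] + exclusion_deg * px_per_deg) {
      if (bands$depth_level[k] < best_depth ||
          (bands$depth_level[k] == best_depth && d < best_dist)) {
        best <- bands$joint[k]
        best_depth <- bands$depth_level[k]
        best_dist <- d
      }
    }
  }
  best
}

# Exhaustive enumeration of every monotone warping path through D,
# returning the minimum total cost.
oracle_dtw_cost <- function(D) {
  n <- nrow(D); m <- ncol(D)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + D[i, j]
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    invisible()
  }
  # the acc >= best cut is exact branch-and-bound: it never discards a
  # path that could improve the minimum
  recurse(1, 1, 0)
  best
}

# Overlap duration by counting per-millisecond: paint each viewer's watch
# trace onto a 1 ms grid and count the milliseconds where enough viewers
# overlap.
oracle_overlap_ms <- function(timelines, min_fraction = 1 / 3) {
  interval0 <- timelines[[1]]$steps$step_start[1]
  step <- timelines[[1]]$step_ms
  n_steps <- nrow(timelines[[1]]$steps)
  total_ms <- round(n_steps * step)
  counts <- integer(total_ms)
  for (tl in timelines) {
    for (s in seq_len(n_steps)) {
      if (tl$steps$value[s] >= 1) {
        ms0 <- round((s - 1) * step)
        idx <- (ms0 + 1):min(ms0 + round(step), total_ms)
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  need <- ceiling(min_fraction * length(timelines))
  sum(counts >= need)
}

# Dense ray-marching first hit over a capsule list.
oracle_ray_march <- function(origin, dir, capsules, t_max = 50, dt = 0.005) {
  seg_dist <- function(p, a, b) {
    ab <- b - a
    L2 <- sum(ab^2)
    u <- if (L2 == 0) 0 else sum((p - a) * ab) / L2
    u <- max(0, min(1, u))
    sqrt(sum((p - (a + u * ab))^2))
  }
  for (tt in seq(dt, t_max, by = dt)) {
    p <- origin + tt * dir
    for (k in seq_len(nrow(capsules))) {
      a <- c(capsules$ax[k], capsules$ay[k], capsules$az[k])
      b <- c(capsules$bx[k], capsules$by[k], capsules$bz[k])
      if (seg_dist(p, a, b) <= capsules$radius[k]) return(capsules$joint[k])
    }
  }
  ""
}

# A jittery random-walk gaze trace with occasional large jumps: generic
# input for oracle-equivalence sweeps.
random_walk_trace <- function(n = 1500, seed = 1, px_per_deg = 40) {
  set.seed(seed)
  jump <- stats::runif(n) < 0.02
  dx <- ifelse(jump, stats::rnorm(n, 0, 8 * px_per_deg), stats::rnorm(n, 0, 1))
  dy <- ifelse(jump, stats::rnorm(n, 0, 8 * px_per_deg), stats::rnorm(n, 0, 1))
  tibble::tibble(t = seq_len(n) - 1,
                 x = 500 + cumsum(dx), y = 400 + cumsum(dy))
}

# Exact-moment raw vector with a given mean and sd (n >= 2): lets
# stats::t.test serve as a reference for the summary-based Welch test.
raw_with_moments <- function(mean, sd, n, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
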