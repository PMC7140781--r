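fx_seq <- function(joints, dur = 200) {
  n <- length(joints)
  tibble::tibble(start_ms = (seq_len(n) - 1) * 400,
                 end_ms = (seq_len(n) - 1) * 400 + dur,
                 duration_ms = dur, joint = joints)
}

test_that("adjacent fixations on one AOI merge into runs", {
  fx <- fx_seq(c("hip", "hip", "knee", "hip"))
  st <- aoi_fixation_stats(fx, "hip")
  expect_equal(st$n_fixations, 3L)
  expect_equal(st$n_merged_runs, 2L)
  expect_equal(st$merged_run_durations_ms[[1]], c(400, 200))
  expect_equal(st$mean_duration_ms, 200)
  one <- aoi_fixation_stats(fx_seq("hip"), "hip")
  expect_equal(one$n_merged_runs, 1L)
  expect_equal(one$merged_run_durations_ms[[1]], 200)
})

test_that("merged runs conserve total duration and never outnumber fixations", {
  set.seed(15)
  for (k in 1:100) {
    joints <- sample(c("hip", "knee", "head", NA), 12, replace = TRUE)
    durs <- round(stats::runif(12, 110, 400))
    fx <- fx_seq(joints)
    fx$duration_ms <- durs
    fx$end_ms <- fx$start_ms + durs
    st <- aoi_fixation_stats(fx)
    for (r in seq_len(nrow(st))) {
      on <- !is.na(fx$joint) & fx$joint == st$joint[r]
      expect_equal(sum(st$merged_run_durations_ms[[r]]), sum(fx$duration_ms[on]))
      expect_lte(st$n_merged_runs[r], st$n_fixations[r])
    }
  }
})

test_that("rare AOIs are those below the pooled share threshold", {
  T1 <- tibble::tibble(joint = c("hip", "toe"), t_ms = c(5000, 0))
  T2 <- tibble::tibble(joint = c("hip", "toe", "head"), t_ms = c(4000, 30, 1000))
  rare <- rare_aois(list(T1, T2))
  expect_true("toe" %in% rare)   # 30 / 10030 < 1%
  expect_false("hip" %in% rare)  # half of the pooled time
  # a joint with zero time everywhere is rare (0 < threshold)
  expect_true("toe" %in% rare_aois(list(T1)))
  # monotone: raising the threshold never removes a joint
  set.seed(16)
  for (k in 1:20) {
    maps <- list(tibble::tibble(joint = paste0("j", 1:8),
                                t_ms = stats::rexp(8, 0.01)))
    lo <- rare_aois(maps, 0.01)
    hi <- rare_aois(maps, 0.05)
    expect_true(all(lo %in% hi))
  }
  expect_equal(rare_aois(list(tibble::tibble(joint = "a", t_ms = 0))),
               character(0))
})

watch_timeline <- function(watch, step_ms = 100) {
  fx <- tibble::tibble(start_ms = (which(watch == 1) - 1) * step_ms,
                       end_ms = which(watch == 1) * step_ms,
                       duration_ms = step_ms, joint = "hip")
  single_timeline(fx, "hip", c(0, length(watch) * step_ms), step_ms)
}

test_that("overlap duration applies the at-least-a-third rule with ceil", {
  # 9 viewers, only one watching at every step: needs ceil(9/3) = 3
  tls <- c(list(watch_timeline(rep(1, 5))),
           lapply(1:8, function(k) watch_timeline(rep(0, 5))))
  expect_equal(overlap_duration(tls), 0)
  # exactly 3 of 9 watching one single 100 ms window
  tls3 <- c(lapply(1:3, function(k) watch_timeline(c(0, 1, 0, 0, 0))),
            lapply(1:6, function(k) watch_timeline(rep(0, 5))))
  expect_equal(overlap_duration(tls3), 100)
  expect_error(overlap_duration(list()), class = "skelgaze_validation_error")
})

test_that("overlap duration matches per-millisecond counting on random viewer sets", {
  set.seed(17)
  for (k in 1:20) {
    n_viewers <- sample(3:9, 1)
    tls <- lapply(seq_len(n_viewers), function(v)
      watch_timeline(stats::rbinom(12, 1, 0.4)))
    expect_equal(overlap_duration(tls), oracle_overlap_ms(tls),
                 info = paste("case", k))
  }
})

test_that("overlap duration is monotone in the required fraction", {
  set.seed(18)
  tls <- lapply(1:7, function(v) watch_timeline(stats::rbinom(15, 1, 0.5)))
  fracs <- c(0.1, 1 / 3, 0.5, 0.8, 1)
  ov <- vapply(fracs, function(f) overlap_duration(tls, f), 1.0)
  expect_true(all(diff(ov) <= 0))
  # single viewer at any fraction <= 1: the viewer's own watch time
  single <- watch_timeline(c(1, 0, 1, 1, 0))
  expect_equal(overlap_duration(list(single), 1), 300)
})

test_that("Welch t from summaries matches stats::t.test on reconstructed data", {
  set.seed(19)
  for (k in 1:100) {
    ma <- stats::runif(1, -10, 10); mb <- stats::runif(1, -10, 10)
    sa <- stats::runif(1, 0.5, 5); sb <- stats::runif(1, 0.5, 5)
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    got <- welch_t(group_summary(ma, sa, na), group_summary(mb, sb, nb))
    xa <- raw_with_moments(ma, sa, na, seed = k)
    xb <- raw_with_moments(mb, sb, nb, seed = k + 1000)
    ref <- stats::t.test(xa, xb)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Welch t handles identical and degenerate summaries", {
  same <- welch_t(group_summary(5, 2, 8), group_summary(5, 2, 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  zero <- welch_t(group_summary(5, 0, 8), group_summary(5, 0, 8))
  expect_equal(zero$statistic, 0)
  expect_error(welch_t(group_summary(5, 0, 8), group_summary(6, 0, 8)),
               class = "skelgaze_validation_error")
  expect_error(group_summary(1, -1, 5), class = "skelgaze_validation_error")
  expect_error(group_summary(1, 1, 1), class = "skelgaze_validation_error")
})

test_that("Welch t is antisymmetric in group order", {
  a <- group_summary(38, 9.3, 5); b <- group_summary(38.5, 8.9, 5)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p.value, ba$p.value)
  expect_equal(ab$df, ba$df)
})

test_that("rank_sum wraps the rank-sum test tidily", {
  set.seed(20)
  x <- stats::rnorm(10); y <- stats::rnorm(10, 1)
  got <- rank_sum(x, y)
  ref <- stats::wilcox.test(x, y)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value)
})
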