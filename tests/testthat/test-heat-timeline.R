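toy_mesh <- function() {
  v <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  f <- matrix(c(1, 2, 3), 1, 3)
  w <- data.frame(vertex = c(1, 2, 3, 3), joint = c("hip", "knee", "hip", "knee"),
                  w = c(1, 1, 0.5, 0.5))
  skinned_mesh(v, f, w)
}

test_that("the three T_MAX metrics follow their definitions and ordering", {
  Tm <- tibble::tibble(joint = c("hip", "knee"), t_ms = c(300, 100))
  expect_equal(t_max(1, Tm, c(0, 1000)), 1000)
  expect_equal(t_max(2, Tm, c(0, 1000)), 400)
  expect_equal(t_max(3, Tm, c(0, 1000)), 300)
  single <- tibble::tibble(joint = "hip", t_ms = 500)
  expect_equal(t_max(2, single, c(0, 1000)), t_max(3, single, c(0, 1000)))
  zero <- tibble::tibble(joint = "hip", t_ms = 0)
  expect_error(t_max(2, zero, c(0, 1000)), class = "skelgaze_validation_error")
  expect_error(t_max(3, zero, c(0, 1000)), class = "skelgaze_validation_error")
  set.seed(12)
  for (k in 1:100) {
    Tm <- tibble::tibble(joint = paste0("j", 1:6),
                         t_ms = stats::runif(6, 0, 200))
    iv <- c(0, sum(Tm$t_ms) + stats::runif(1, 0, 500))
    m1 <- t_max(1, Tm, iv); m2 <- t_max(2, Tm, iv); m3 <- t_max(3, Tm, iv)
    expect_true(m3 <= m2 && m2 <= m1)
  }
})

test_that("vertex colors follow the skinning-weighted normalization", {
  mesh <- toy_mesh()
  Tm <- tibble::tibble(joint = c("hip", "knee"), t_ms = c(2000, 4000))
  hm <- vertex_colors(mesh, Tm, t_max = 4000)
  expect_equal(hm$v_c, c(0.5, 1, 0.75))
  # all-zero T gives an all-zero mesh
  hm0 <- vertex_colors(mesh, tibble::tibble(joint = "hip", t_ms = 0), 1000)
  expect_equal(hm0$v_c, c(0, 0, 0))
  # fully-weighted vertex at T = t_max saturates at exactly 1
  hm1 <- vertex_colors(mesh, tibble::tibble(joint = "hip", t_ms = 4000), 4000)
  expect_equal(hm1$v_c[1], 1)
  expect_error(vertex_colors(mesh, Tm, 0), class = "skelgaze_validation_error")
  expect_true(all(hm$v_c >= 0 & hm$v_c <= 1))
})

test_that("metric-2 normalization conserves total share and colors are scale-invariant", {
  set.seed(13)
  for (k in 1:20) {
    Tm <- tibble::tibble(joint = paste0("j", 1:5),
                         t_ms = stats::runif(5, 1, 300))
    m2 <- t_max(2, Tm, c(0, 5000))
    expect_equal(sum(Tm$t_ms / m2), 1, tolerance = 1e-12)
  }
  mesh <- toy_mesh()
  Tm <- tibble::tibble(joint = c("hip", "knee"), t_ms = c(120, 80))
  a <- vertex_colors(mesh, Tm, 200)
  Tm2 <- Tm; Tm2$t_ms <- Tm$t_ms * 7.5
  b <- vertex_colors(mesh, Tm2, 200 * 7.5)
  expect_equal(a$v_c, b$v_c, tolerance = 1e-12)
})

test_that("viewer averaging is the per-joint mean with missing joints as zero", {
  Ta <- tibble::tibble(joint = "hip", t_ms = 200)
  Tb <- tibble::tibble(joint = c("hip", "knee"), t_ms = c(400, 100))
  avg <- average_viewers(list(Ta, Tb))
  expect_equal(avg$t_ms[avg$joint == "hip"], 300)
  expect_equal(avg$t_ms[avg$joint == "knee"], 50)
  expect_equal(average_viewers(list(Tb)), dplyr::arrange(Tb, joint))
  expect_equal(average_viewers(list(Tb, Tb, Tb)), dplyr::arrange(Tb, joint))
  expect_error(average_viewers(list()), class = "skelgaze_validation_error")
})

test_that("single timelines mark watched steps and report both percentages", {
  fx <- tibble::tibble(start_ms = 200, end_ms = 500, duration_ms = 300,
                       joint = "hip")
  tl <- single_timeline(fx, "hip", c(0, 1000), 100)
  expect_equal(sum(tl$steps$value), 3)
  expect_equal(tl$steps$value, c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(tl$percentage_timeline, 30)
  expect_equal(tl$percentage_block, 100)
  none <- single_timeline(fx, "knee", c(0, 1000), 100)
  expect_equal(sum(none$steps$value), 0)
  expect_equal(none$percentage_timeline, 0)
  expect_equal(none$percentage_block, 0)
})

test_that("block percentages sum to 100 over joints when any on-body fixation exists", {
  set.seed(14)
  fx <- tibble::tibble(
    start_ms = seq(0, 3600, by = 400), end_ms = seq(150, 3750, by = 400),
    duration_ms = 150,
    joint = sample(c("hip", "knee", "head", NA), 10, replace = TRUE))
  joints <- unique(fx$joint[!is.na(fx$joint)])
  pct <- vapply(joints, function(j)
    single_timeline(fx, j, c(0, 4000), 100)$percentage_block, 1.0)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
})

test_that("aggregation averages occurrences, normalizes by the block maximum", {
  fx1 <- tibble::tibble(start_ms = 0, end_ms = 250, duration_ms = 250,
                        joint = "hip")
  fx2 <- tibble::tibble(start_ms = 150, end_ms = 450, duration_ms = 300,
                        joint = "hip")
  t1 <- single_timeline(fx1, "hip", c(0, 500), 100)
  t2 <- single_timeline(fx2, "hip", c(0, 500), 100)
  agg <- aggregate_timelines(list(t1, t2))
  # means: steps 0-100:0.5+? t1 covers 0..250 -> steps 1:3; t2 covers 150..450 -> steps 2:5
  expect_equal(agg$steps$value, c(0.5, 1, 1, 0.5, 0.5) / 1)
  expect_true(all(agg$steps$value >= 0 & agg$steps$value <= 1))
  # identical timelines aggregate to themselves after normalization
  same <- aggregate_timelines(list(t1, t1))
  expect_equal(same$steps$value, t1$steps$value)
  # the block-maximum joint contains a step of exactly 1 when self-normalized
  expect_true(any(agg$steps$value == 1))
  # permutation invariance in viewer order
  expect_equal(aggregate_timelines(list(t2, t1))$steps$value,
               agg$steps$value)
  expect_error(aggregate_timelines(list()), class = "skelgaze_validation_error")
})

test_that("timeline blocks share one cross-joint normalization", {
  fx_a <- tibble::tibble(start_ms = c(0, 300), end_ms = c(200, 500),
                         duration_ms = 200, joint = c("hip", "knee"))
  fx_b <- tibble::tibble(start_ms = 0, end_ms = 200, duration_ms = 200,
                         joint = "hip")
  block <- timeline_block(list(a = fx_a, b = fx_b), c("hip", "knee"),
                          c(0, 500), 100)
  # hip is watched by both viewers early: mean 1 -> the global maximum
  expect_equal(max(block$hip$steps$value), 1)
  # knee's peak mean is 0.5, normalized by hip's 1.0
  expect_equal(max(block$knee$steps$value), 0.5)
})

test_that("interval partitioning computes per-phase meshes additively", {
  mesh <- toy_mesh()
  fx <- tibble::tibble(start_ms = c(100, 1200), end_ms = c(400, 1500),
                       duration_ms = 300, joint = c("hip", "knee"))
  full <- partition_by_intervals(mesh, fx,
                                 data.frame(start_ms = 0, end_ms = 2000))
  direct <- vertex_colors(mesh, joint_time_map(fx, c(0, 2000)),
                          t_max(1, NULL, c(0, 2000)))
  expect_equal(full$heat[[1]]$v_c, direct$v_c)
  parts <- partition_by_intervals(
    mesh, fx, data.frame(start_ms = c(0, 1000), end_ms = c(1000, 2000)))
  T1 <- joint_time_map(fx, c(0, 1000))
  T2 <- joint_time_map(fx, c(1000, 2000))
  Tfull <- joint_time_map(fx, c(0, 2000))
  merged <- dplyr::bind_rows(T1, T2) |>
    dplyr::group_by(joint) |>
    dplyr::summarise(t_ms = sum(t_ms), .groups = "drop")
  expect_equal(merged, Tfull)
  # an empty interval yields an all-zero mesh under metric 1
  empty <- partition_by_intervals(mesh, fx,
                                  data.frame(start_ms = 600, end_ms = 900))
  expect_equal(empty$heat[[1]]$v_c, c(0, 0, 0))
})

test_that("timeline and heat-mesh autoplot methods return ggplot objects", {
  fx <- tibble::tibble(start_ms = 0, end_ms = 250, duration_ms = 250,
                       joint = "hip")
  tl <- single_timeline(fx, "hip", c(0, 500), 100)
  expect_s3_class(autoplot(tl), "ggplot")
  hm <- vertex_colors(toy_mesh(), tibble::tibble(joint = "hip", t_ms = 100), 200)
  expect_s3_class(autoplot(hm), "ggplot")
  td <- tidy(tl)
  expect_true(all(c("step_start", "value", "joint") %in% names(td)))
})
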