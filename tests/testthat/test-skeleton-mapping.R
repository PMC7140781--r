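simple_skeleton <- function() {
  joints <- data.frame(name = c("a", "b", "c"), parent = c(NA, "a", "b"))
  bones <- data.frame(joint_a = c("a", "b"), joint_b = c("b", "c"),
                      width_px = c(10, 10), depth_level = c(1L, 2L))
  kf <- rbind(
    data.frame(frame = 0, joint = c("a", "b", "c"),
               x = c(0, 0, 100), y = c(0, 100, 100)),
    data.frame(frame = 4, joint = c("a", "b", "c"),
               x = c(0, 10, 110), y = c(0, 120, 140)))
  skeleton2d(joints, bones, kf, fps = 30)
}

test_that("pose interpolation is exact at keyframes, linear between, clamped outside", {
  sk <- simple_skeleton()
  p0 <- interpolate_pose2d(sk, 0)
  expect_equal(p0$x[p0$joint == "b"], 0)
  pm <- interpolate_pose2d(sk, 2)
  expect_equal(pm$x[pm$joint == "b"], 5)
  expect_equal(pm$y[pm$joint == "b"], 110)
  p_end <- interpolate_pose2d(sk, 99)
  p4 <- interpolate_pose2d(sk, 4)
  expect_equal(p_end, p4)
  p_neg <- interpolate_pose2d(sk, -3)
  expect_equal(p_neg, p0)
})

test_that("sample on a bone maps to the bone's child joint; far samples map to empty", {
  sk <- simple_skeleton()
  pose <- interpolate_pose2d(sk, 0)
  bands <- bone_bands(sk, pose)
  # exactly on the a-b segment, far from b-c
  expect_equal(map_sample_to_joint_2d(0, 50, bands, 0.5, 40), "b")
  # exactly on the b-c segment, far from a-b
  expect_equal(map_sample_to_joint_2d(60, 100, bands, 0.5, 40), "c")
  # far away from every bone: half_width 5 + exclusion 20 px
  expect_equal(map_sample_to_joint_2d(500, 500, bands, 0.5, 40), "")
})

test_that("crossing bones resolve by depth level, then distance", {
  joints <- data.frame(name = c("r", "p", "q"), parent = c(NA, "r", "r"))
  bones <- data.frame(joint_a = c("r", "r"), joint_b = c("p", "q"),
                      width_px = c(20, 20), depth_level = c(2L, 1L))
  kf <- data.frame(frame = 0, joint = c("r", "p", "q"),
                   x = c(0, 100, 100), y = c(0, 100, -100))
  sk <- skeleton2d(joints, bones, kf, 30)
  bands <- bone_bands(sk, interpolate_pose2d(sk, 0))
  # near the crossing point both bands contain the sample; depth 1 wins
  expect_equal(map_sample_to_joint_2d(1, 0, bands, 0.5, 40), "q")
  # equal depths: nearest bone wins
  bands$depth_level <- c(1L, 1L)
  expect_equal(map_sample_to_joint_2d(10, 3, bands, 0.5, 40), "p")
  expect_equal(map_sample_to_joint_2d(10, -3, bands, 0.5, 40), "q")
})

test_that("2D mapping agrees with an all-bones scan on 1000 random samples", {
  sk <- make_skeleton_walk_2d(8, 60, seed = 21)
  pose <- interpolate_pose2d(sk, 17.3)
  bands <- bone_bands(sk, pose)
  set.seed(22)
  px <- stats::runif(1000, 0, 1000)
  py <- stats::runif(1000, 200, 400)
  got <- vapply(seq_along(px), function(k)
    map_sample_to_joint_2d(px[k], py[k], bands, 0.5, 40), "")
  want <- vapply(seq_along(px), function(k)
    oracle_map2d(px[k], py[k], bands, 0.5, 40), "")
  expect_identical(got, want)
  expect_gt(sum(nzchar(got)), 0) # the sweep actually hits the skeleton
})

test_that("2D mapping is invariant under global translation and monotone in the exclusion radius", {
  sk <- make_skeleton_walk_2d(6, 40, seed = 31)
  bands <- bone_bands(sk, interpolate_pose2d(sk, 10))
  set.seed(32)
  px <- stats::runif(300, 0, 900); py <- stats::runif(300, 250, 350)
  lab <- vapply(seq_along(px), function(k)
    map_sample_to_joint_2d(px[k], py[k], bands, 0.5, 40), "")
  shifted <- bands
  shifted$ax <- bands$ax + 123.5; shifted$bx <- bands$bx + 123.5
  shifted$ay <- bands$ay - 77.25; shifted$by <- bands$by - 77.25
  lab_shift <- vapply(seq_along(px), function(k)
    map_sample_to_joint_2d(px[k] + 123.5, py[k] - 77.25, shifted, 0.5, 40), "")
  expect_identical(lab, lab_shift)
  lab_small <- vapply(seq_along(px), function(k)
    map_sample_to_joint_2d(px[k], py[k], bands, 0.25, 40), "")
  expect_true(all(!(nzchar(lab_small) & !nzchar(lab))))
})

test_that("gaze rays pass through the optical axis and invert the projection", {
  cam <- pinhole_camera(800, 600, fov_y_deg = 60,
                        position = c(1, 2, 3),
                        orientation = c(cos(0.3), 0, sin(0.3), 0))
  ray <- project_gaze_ray(400, 300, cam)
  axis <- skelgaze:::quat_rotate_vec(cam$orientation, c(0, 0, 1))[1, ]
  expect_equal(ray$direction, axis / sqrt(sum(axis^2)), tolerance = 1e-12)
  expect_equal(sum(ray$direction^2), 1, tolerance = 1e-12)
  # corners are symmetric about the axis for a centered principal point
  r1 <- project_gaze_ray(0, 0, cam)$direction
  r2 <- project_gaze_ray(800, 600, cam)$direction
  expect_equal(sum(r1 * axis), sum(r2 * axis), tolerance = 1e-12)
  # re-projecting a point on the ray recovers the pixel
  set.seed(5)
  for (k in 1:20) {
    px <- stats::runif(1, 0, 800); py <- stats::runif(1, 0, 600)
    ray <- project_gaze_ray(px, py, cam)
    p <- ray$origin + stats::runif(1, 0.5, 20) * ray$direction
    expect_equal(project_point(p, cam), c(px, py), tolerance = 1e-6)
  }
  expect_error(project_gaze_ray(-5, 10, cam),
               class = "skelgaze_offscreen_error")
})

test_that("ray-capsule intersection picks the first hit and agrees with ray marching", {
  caps <- tibble::tibble(
    joint = c("near", "far"),
    ax = c(0, 0), ay = c(-1, -1), az = c(2, 5),
    bx = c(0, 0), by = c(1, 1), bz = c(2, 5),
    radius = c(0.3, 0.3))
  ray <- list(origin = c(0, 0, 0), direction = c(0, 0, 1))
  expect_equal(intersect_ray_capsules(ray, caps), "near")
  miss <- list(origin = c(10, 10, 0), direction = c(0, 0, 1))
  expect_equal(intersect_ray_capsules(miss, caps), "")
  # randomized scenes vs dense ray marching
  set.seed(77)
  for (k in 1:15) {
    caps <- tibble::tibble(
      joint = paste0("j", 1:4),
      ax = stats::runif(4, -3, 3), ay = stats::runif(4, -3, 3),
      az = stats::runif(4, 4, 12),
      bx = stats::runif(4, -3, 3), by = stats::runif(4, -3, 3),
      bz = stats::runif(4, 4, 12),
      radius = stats::runif(4, 0.4, 0.8))
    dir <- c(stats::rnorm(2, 0, 0.1), 1)
    dir <- dir / sqrt(sum(dir^2))
    ray <- list(origin = c(0, 0, 0), direction = dir)
    got <- intersect_ray_capsules(ray, caps)
    want <- oracle_ray_march(ray$origin, ray$direction, caps,
                             t_max = 20, dt = 0.002)
    expect_equal(got, want, info = paste("scene", k))
  }
})

test_that("forward kinematics places a simple chain correctly", {
  # two-joint chain: root rotates 90 degrees about z, child offset (1,0,0)
  rot <- array(0, dim = c(1, 2, 4))
  rot[1, 1, ] <- c(cos(pi / 4), 0, 0, sin(pi / 4)) # 90 deg about z
  rot[1, 2, ] <- c(1, 0, 0, 0)
  mo <- motion3d(c("root", "child"), rot, root = matrix(c(1, 1, 0), 1))
  h <- tibble::tibble(joint = c("root", "child"), parent = c(NA, "root"),
                      ox = c(0, 1), oy = c(0, 0), oz = c(0, 0))
  pos <- fk_positions(mo, 1, h)
  expect_equal(unname(unlist(pos[pos$joint == "child", c("x", "y", "z")])),
               c(1, 2, 0), tolerance = 1e-12)
})

test_that("end-to-end 3D gaze mapping labels the gazed body part", {
  # a capsule chain in front of the camera; aim a ray at the child bone mid
  positions <- tibble::tibble(joint = c("hips", "spine", "head"),
                              x = c(0, 0, 0), y = c(-1, 0, 1), z = c(6, 6, 6))
  bones <- tibble::tibble(joint_a = c("hips", "spine"),
                          joint_b = c("spine", "head"))
  caps <- bone_capsules(positions, bones, radius_fraction = 0.2)
  cam <- pinhole_camera(800, 600, fov_y_deg = 60)
  target <- c(0, 0.5, 6) # midpoint of spine-head bone
  px <- project_point(target, cam)
  ray <- project_gaze_ray(px[1], px[2], cam)
  expect_equal(intersect_ray_capsules(ray, caps), "head")
})
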