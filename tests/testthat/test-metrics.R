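test_that("resampling is the identity on an already-uniform 100 Hz grid", {
  t <- seq(0, 3, by = 0.01)
  pos <- cbind(sin(t), cos(t), t)
  tr <- object_trajectory(t, pos, target_center = c(0, 0, 0))
  rs <- resample_trajectory(tr, 100)
  expect_equal(rs$t, t, tolerance = 1e-12)
  expect_equal(rs$pos, pos, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("resampling interpolates a 2-sample segment in closed form", {
  tr <- object_trajectory(c(0, 1), rbind(c(0, 0, 0), c(1, 0, 0)),
                          target_center = c(1, 0, 0))
  rs <- resample_trajectory(tr, 100)
  expect_length(rs$t, 101)
  expect_equal(rs$pos[, 1], rs$t, tolerance = 1e-12)
  expect_error(resample_trajectory(
    object_trajectory(0, matrix(0, 1, 3), c(0, 0, 0))), "2 samples")
})

test_that("trajectory construction rejects invalid inputs", {
  expect_error(object_trajectory(c(0, 0.1, 0.1), matrix(0, 3, 3), c(0, 0, 0)),
               "strictly increasing")
  expect_error(object_trajectory(c(0, 0.1), rbind(c(0, 0, 0), c(NA, 0, 0)),
                                 c(0, 0, 0)), "finite")
})

test_that("speed follows closed forms", {
  t <- seq(0, 2, by = 0.01)
  still <- object_trajectory(t, matrix(1, length(t), 3), c(0, 0, 0))
  expect_true(all(compute_speed(still) == 0))

  lin <- object_trajectory(t, cbind(0.2 * t, 0, 0), c(0, 0, 0))
  sp <- compute_speed(lin)
  expect_equal(sp, rep(0.2, length(t)), tolerance = 1e-10)

  th <- t                                     # angular rate 1 rad/s
  circ <- object_trajectory(t, cbind(0.1 * cos(th), 0.1 * sin(th), 0),
                            c(0, 0, 0))
  spc <- compute_speed(circ)
  expect_lt(max(abs(spc[2:(length(t) - 1)] - 0.1)) / 0.1, 0.01)
})

test_that("the moving mask thresholds speed", {
  expect_identical(moving_mask(c(0, 0.005, 0.02), 0.01), c(FALSE, FALSE, TRUE))
  expect_identical(moving_mask(c(0, 0, 0), 0), rep(FALSE, 3))
  expect_error(moving_mask(1, -1), ">= 0")
})

test_that("completion time counts moving samples", {
  t <- seq(0, 2.99, by = 0.01)
  still <- object_trajectory(t, matrix(0, 300, 3), c(0, 0, 0))
  expect_equal(completion_time(still), 0)

  # 149 displacement steps give exactly 150 samples with nonzero
  # central-difference velocity
  x <- numeric(300)
  x[76:224] <- (1:149) * 0.001
  x[225:300] <- x[224]
  tr <- object_trajectory(t, cbind(x, 0, 0), c(0, 0, 0))
  expect_equal(sum(moving_mask(compute_speed(tr), 0)), 150)
  expect_equal(completion_time(tr), 1.5, tolerance = 1e-12)
})

test_that("pathlength accumulates displacements while moving", {
  t <- seq(0, 2.99, by = 0.01)
  still <- object_trajectory(t, matrix(0, 300, 3), c(0, 0, 0))
  expect_equal(pathlength(still), 0)

  line <- make_line_trajectory(length_m = 0.25)
  expect_equal(pathlength(line), 0.25, tolerance = 1e-9)

  half <- make_halfcircle_trajectory(r = 0.1)
  expect_lt(abs(pathlength(half) - pi * 0.1) / (pi * 0.1), 0.01)
})

test_that("pathlength is monotone in the speed gate", {
  tr <- make_minjerk_trajectory()
  gates <- c(0, 0.001, 0.01, 0.05, 0.2)
  p <- vapply(gates, function(g) pathlength(resample_trajectory(tr), g), 1)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("placement error is the in-plane distance to the target", {
  t <- seq(0, 1, by = 0.01)
  mk <- function(final) {
    x <- numeric(101); x[31:60] <- seq(0.001, 0.03, length.out = 30)
    x[61:101] <- x[60]
    pos <- cbind(x, 0, 0)
    pos[61:101, ] <- matrix(final, 41, 3, byrow = TRUE)
    pos[31:60, ] <- cbind(seq(0.001, final[1], length.out = 30),
                          seq(0.001, final[2], length.out = 30),
                          seq(0.001, final[3], length.out = 30))
    object_trajectory(t, pos, target_center = c(0, 0, 0))
  }
  # directly above the target: projection removes height
  expect_equal(placement_error(mk(c(0, 0, 0.05))), 0, tolerance = 1e-12)
  # 5 mm along an in-plane axis
  expect_equal(placement_error(mk(c(0.005, 0, 0.02))), 0.005,
               tolerance = 1e-12)
  # hand arithmetic
  expect_equal(placement_error(mk(c(0.01, 0.02, 0.04))),
               sqrt(0.01^2 + 0.02^2), tolerance = 1e-12)
  # a trajectory still moving at its end has no resting pose
  moving <- object_trajectory(t, cbind(t, 0, 0), c(0, 0, 0))
  expect_error(placement_error(moving), "rest")
})

test_that("a stationary trial scores (0, 0, start-to-target distance)", {
  t <- seq(0, 1, by = 0.01)
  tr <- object_trajectory(t, matrix(rep(c(0.03, 0.04, 0.1), each = 101), 101),
                          target_center = c(0, 0, 0))
  m <- score_trial(tr)
  expect_equal(m$time_s, 0)
  expect_equal(m$path_m, 0)
  expect_equal(m$error_m, 0.05, tolerance = 1e-12)
})

test_that("metrics are scale-equivariant and rigid-motion invariant", {
  p0 <- learning_params(noise_sd = c(time_s = 0, path_m = 0, error_m = 0))
  tr <- generate_task_trajectory("pre", 1, "NF", p0, seed = 13)
  m <- score_trial(tr)

  # doubling all spatial quantities doubles P and E, leaves T unchanged
  tr2 <- tr
  tr2$pos <- tr$pos * 2
  tr2$target_center <- tr$target_center * 2
  m2 <- score_trial(tr2)
  expect_equal(m2$path_m, 2 * m$path_m, tolerance = 1e-9)
  expect_equal(m2$error_m, 2 * m$error_m, tolerance = 1e-9)
  expect_equal(m2$time_s, m$time_s)

  # rotation + translation applied to trajectory, target and plane
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(0.1, -0.2, 0.05)
  tr3 <- tr
  tr3$pos <- tr$pos %*% t(R) + matrix(shift, nrow(tr$pos), 3, byrow = TRUE)
  tr3$target_center <- drop(R %*% tr$target_center) + shift
  tr3$table_plane <- list(point = drop(R %*% tr$table_plane$point) + shift,
                          normal = drop(R %*% tr$table_plane$normal))
  m3 <- score_trial(tr3)
  expect_equal(m3$path_m, m$path_m, tolerance = 1e-9)
  expect_equal(m3$error_m, m$error_m, tolerance = 1e-9)
  expect_equal(m3$time_s, m$time_s)
})

test_that("analytic fixtures reproduce closed forms at 100 Hz", {
  line <- make_line_trajectory(length_m = 0.25, move_s = 1.0)
  expect_lt(abs(pathlength(line) - 0.25) / 0.25, 0.01)
  expect_lte(abs(completion_time(line) - 1.0), 0.01 + 1e-9)

  half <- make_halfcircle_trajectory(r = 0.1, move_s = 1.0)
  expect_lt(abs(pathlength(half) - pi * 0.1) / (pi * 0.1), 0.01)
  expect_lte(abs(completion_time(half) - 1.0), 0.01 + 1e-9)

  mj <- make_minjerk_trajectory(length_m = 0.25, move_s = 1.48)
  expect_lt(abs(pathlength(mj) - 0.25) / 0.25, 0.01)
  expect_lte(abs(completion_time(mj) - 1.48), 0.01 + 1e-9)
})
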