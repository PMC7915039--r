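test_that("rest trials with zero noise are identically zero and combos validate", {
  tr <- generate_grasp_trial("none", "rest", noise_sd = 0, seed = 1)
  expect_true(all(tr$force == 0))
  expect_true(all(tr$flex == 0))
  expect_null(tr$hold_window)
  expect_error(generate_grasp_trial("pinch", "rest"), "grip")
  expect_error(generate_grasp_trial("none", "hold"), "rest")
  expect_error(generate_grasp_trial("pinch", "hold", noise_sd = -1), ">= 0")
})

test_that("hold trials have a valid annotated hold window and 40 Hz timing", {
  tr <- generate_grasp_trial("pinch", "hold", seed = 2)
  expect_length(tr$t, 401)
  expect_equal(diff(tr$t), rep(1 / 40, 400), tolerance = 1e-12)
  w <- tr$hold_window
  expect_true(w[1] >= 1 && w[2] <= 401 && w[1] < w[2])
  expect_gte(tr$t[w[2]] - tr$t[w[1]], 3)     # steady hold spans >= 3 s
  # plateau mean far above the noise floor
  expect_gt(mean(tr$force[w[1]:w[2], 2]), 10 * sensor_params()$noise_sd)
})

test_that("pinch hold frames keep index and thumb force near-equal in the window", {
  tr <- generate_grasp_trial("pinch", "hold", noise_sd = 0.01, seed = 7)
  w <- tr$hold_window
  fi <- tr$force[w[1]:w[2], 2]
  ft <- tr$force[w[1]:w[2], 1]
  expect_true(all(abs(fi - ft) <= 0.05 * pmax(fi, ft)))
})

test_that("tri-pod and whole-hand thumb force plateau is weak", {
  digits <- list(tripod = 2:3, whole_hand = 2:5)
  for (g in names(digits)) {
    tr <- generate_grasp_trial(g, "hold", seed = 3)
    w <- tr$hold_window
    thumb <- mean(tr$force[w[1]:w[2], 1])
    others <- mean(tr$force[w[1]:w[2], digits[[g]]])
    expect_lt(thumb, 0.2 * others)
  }
})

test_that("tap trials are short contact bursts below the secure plateau", {
  tr <- generate_grasp_trial("pinch", "tap", seed = 11)
  expect_null(tr$hold_window)
  hold <- generate_grasp_trial("pinch", "hold", seed = 11)
  w <- hold$hold_window
  plateau <- mean(hold$force[w[1]:w[2], 2])
  # contact episodes (index force above half the noise-free floor) last < 0.5 s
  on <- tr$force[, 2] > 0.25 * plateau
  runs <- rle(on)
  expect_true(all(runs$lengths[runs$values] < 0.5 * tr$rate_hz))
  expect_lt(max(tr$force[, 2]), 0.95 * plateau)
})

test_that("training corpus has the session composition and is reproducible", {
  c1 <- generate_training_corpus("s1", 0.01, 42)
  c2 <- generate_training_corpus("s1", 0.01, 42)
  expect_identical(c1, c2)
  expect_length(c1$trials, 125)
  prot <- vapply(c1$trials, function(tr) tr$protocol, character(1))
  expect_equal(unname(table(prot)[c("hold", "tap", "rest")]),
               c(60L, 60L, 5L), ignore_attr = TRUE)
  c3 <- generate_training_corpus("s1", 0.01, 43)
  v1 <- unlist(lapply(c1$trials, function(tr) tr$force))
  v3 <- unlist(lapply(c3$trials, function(tr) tr$force))
  expect_false(identical(v1, v3))
})

test_that("zero-noise trajectories realize the configured metrics", {
  p0 <- learning_params(noise_sd = c(time_s = 0, path_m = 0, error_m = 0))
  tr <- generate_task_trajectory("pre", 1, "NF", p0, seed = 5)
  expect_equal(unname(tr$metrics_drawn),
               unname(p0$baseline), tolerance = 1e-12)
  m <- score_trial(tr)
  expect_equal(m$path_m, 0.25, tolerance = 1e-3)
  expect_equal(m$error_m, 0.0056, tolerance = 1e-9)
  # completion time is quantized by the metric grid and boundary smoothing
  expect_lt(abs(m$time_s - 1.48), 0.035)
  # start and end at rest
  rs <- resample_trajectory(tr)
  sp <- compute_speed(rs)
  expect_true(all(sp[1:20] < 1e-9))
  expect_true(all(sp[(length(sp) - 19):length(sp)] < 1e-9))
  # determinism
  tr2 <- generate_task_trajectory("pre", 1, "NF", p0, seed = 5)
  expect_identical(tr, tr2)
})

test_that("training-block trajectories follow the configured slope", {
  p1 <- learning_params(
    baseline = c(time_s = 1.5, path_m = 0.25, error_m = 0.0056),
    slope = rbind(NF = c(0, 0, 0), IF = c(0, 0, 0), IBF = c(-0.005, 0, 0)),
    noise_sd = c(time_s = 0, path_m = 0, error_m = 0))
  tr <- generate_task_trajectory("training", 30, "IBF", p1, seed = 9)
  expect_equal(tr$metrics_drawn[["time_s"]], 1.5 - 29 * 0.005,
               tolerance = 1e-9)
  expect_lt(abs(score_trial(tr)$time_s - 1.355), 0.035)
  expect_error(generate_task_trajectory("training", 31, "IBF", p1, seed = 9),
               "outside")
  expect_error(learning_params(baseline = c(time_s = -1, path_m = 0.25,
                                            error_m = 0.0056)), "> 0")
})

test_that("zero-noise metric round trip holds across modes and blocks", {
  p0 <- learning_params(noise_sd = c(time_s = 0, path_m = 0, error_m = 0))
  for (mode in c("NF", "IF", "IBF")) {
    for (case in list(c("pre", 3), c("training", 17), c("post", 8))) {
      tr <- generate_task_trajectory(case[1], as.integer(case[2]), mode,
                                     p0, seed = 31)
      m <- score_trial(tr)
      expect_lt(abs(m$path_m - tr$metrics_drawn[["path_m"]]) /
                  tr$metrics_drawn[["path_m"]], 1e-3)
      expect_lt(abs(m$error_m - tr$metrics_drawn[["error_m"]]), 1e-9)
      expect_lt(abs(m$time_s - tr$metrics_drawn[["time_s"]]), 0.035)
    }
  }
})

test_that("study structure matches the session design", {
  st <- generate_study(17, seed = 2021)
  expect_equal(nrow(st$trials), 17 * 3 * 60)
  counts <- table(st$trials$block)
  expect_equal(unname(counts[c("pre", "training", "post")]),
               c(15L, 30L, 15L) * 51L, ignore_attr = TRUE)
  expect_setequal(unique(st$trials$feedback_mode), c("NF", "IF", "IBF"))
  # trajectories materialize one per trial
  st1 <- generate_study(1, seed = 4, trajectories = TRUE)
  expect_length(st1$trajectories, 180)
})

test_that("subject baseline variability matches the configured CV", {
  st <- generate_study(17, seed = 2021)
  cv_cfg <- learning_params()$subject_cv
  cv_real <- apply(st$subject_scales, 2, function(s) sd(s) / mean(s))
  expect_equal(unname(cv_real), unname(cv_cfg), tolerance = 0.2)
  # single subject with no inter-subject variance sits at the group baseline
  p0 <- learning_params(subject_cv = c(time_s = 0, path_m = 0, error_m = 0))
  st1 <- generate_study(1, p0, seed = 99)
  expect_equal(unname(st1$subject_scales[1, ]), c(1, 1, 1))
})

test_that("realized metrics carry the drawn noise (scored equals drawn)", {
  st <- generate_study(2, seed = 3, trajectories = TRUE)
  sc <- score_study(st)
  expect_lt(max(abs(sc$path_m - st$trials$path_m) / st$trials$path_m), 1e-3)
  expect_lt(max(abs(sc$error_m - st$trials$error_m)), 1e-9)
  expect_lt(max(abs(sc$time_s - st$trials$time_s)), 0.035)
})
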