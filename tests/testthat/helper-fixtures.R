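# Shared fixtures, built in code at test time.

# hand-built sensor trial with explicit channel values
make_manual_trial <- function(force, flex, protocol = "hold", grip = "pinch",
                              hold_window = c(1L, nrow(force)),
                              rate_hz = 40, v_max = 3.3) {
  n <- nrow(force)
  colnames(force) <- paste0("f", 1:5)
  colnames(flex) <- paste0("x", 1:5)
  structure(list(grip = grip, protocol = protocol,
                 t = (seq_len(n) - 1) / rate_hz,
                 force = force, flex = flex,
                 hold_window = if (protocol == "hold") hold_window else NULL,
                 seed = NA, rate_hz = rate_hz, v_max = v_max),
            class = "grasp_trial")
}

# duplicated-XOR benchmark dataset (4 points x 50, padded to 10 features)
make_xor_dataset <- function(split_seed = 1, reps = 50) {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(0, 1, 1, 0)
  X <- X[rep(1:4, reps), ]
  y <- rep(y, reps)
  n <- length(y)
  X <- cbind(X, matrix(0, n, 8))
  colnames(X) <- c(paste0("f", 1:5), paste0("x", 1:5))
  set.seed(split_seed)
  n_tr <- round(0.7 * n); n_va <- round(0.15 * n)
  spl <- sample(rep(c("train", "val", "test"), c(n_tr, n_va, n - n_tr - n_va)))
  structure(list(features = X, labels = y,
                 split = factor(spl, levels = c("train", "val", "test")),
                 trial_id = rep("xor", n), frame_idx = seq_len(n),
                 grip = rep("pinch", n), protocol = rep("hold", n),
                 meta = list(v_max = 3.3)),
            class = "labeled_dataset")
}

# default corpus / dataset / trained model, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

default_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    .fixture_cache$corpus <- generate_training_corpus("s1", seed = 42)
  }
  .fixture_cache$corpus
}

default_dataset <- function() {
  if (is.null(.fixture_cache$dataset)) {
    .fixture_cache$dataset <- assemble_dataset(default_corpus(), seed = 42)
  }
  .fixture_cache$dataset
}

default_model <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- train_ann(default_dataset(), seed = 42)
  }
  .fixture_cache$model
}

# trajectory fixtures built directly on the 100 Hz grid -----------------------

# rest | constant-velocity straight segment | rest
make_line_trajectory <- function(length_m = 0.25, move_s = 1.0,
                                 rest_s = 0.2, rate = 100) {
  dt <- 1 / rate
  t <- seq(0, move_s + 2 * rest_s, by = dt)
  s <- pmin(pmax((t - rest_s) / move_s, 0), 1)
  pos <- cbind(length_m * s, 0, 0)
  object_trajectory(t, pos, target_center = c(length_m, 0, 0))
}

# rest | half circle of radius r at constant angular rate | rest
make_halfcircle_trajectory <- function(r = 0.1, move_s = 1.0,
                                       rest_s = 0.2, rate = 100) {
  dt <- 1 / rate
  t <- seq(0, move_s + 2 * rest_s, by = dt)
  s <- pmin(pmax((t - rest_s) / move_s, 0), 1)
  th <- pi * s
  pos <- cbind(r * cos(th), r * sin(th), 0)
  object_trajectory(t, pos, target_center = c(-r, 0, 0))
}

# rest | straight minimum-jerk segment of length L | rest
make_minjerk_trajectory <- function(length_m = 0.25, move_s = 1.48,
                                    rest_s = 0.3, rate = 100) {
  dt <- 1 / rate
  t <- seq(0, move_s + 2 * rest_s, by = dt)
  tau <- pmin(pmax((t - rest_s) / move_s, 0), 1)
  s <- tau^3 * (10 - 15 * tau + 6 * tau^2)
  pos <- cbind(length_m * s, 0, 0)
  object_trajectory(t, pos, target_center = c(length_m, 0, 0))
}
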