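#' Resample an object trajectory onto a uniform grid
#'
#' Linear interpolation of each coordinate onto a uniform grid (default
#' 100 Hz) spanning the original time range. The performance metrics are
#' always computed on the 100 Hz grid regardless of the camera rate.
#'
#' @param traj An `object_trajectory` (>= 2 samples, strictly increasing
#'   timestamps).
#' @param rate Target sampling rate (Hz).
#' @return A resampled `object_trajectory`.
#' @export
resample_trajectory <- function(traj, rate = 100) {
  stopifnot(inherits(traj, "object_trajectory"))
  abort_if(nrow(traj$pos) < 2, "need at least 2 samples to resample")
  t0 <- traj$t[1]
  span <- traj$t[length(traj$t)] - t0
  dt <- 1 / rate
  grid <- t0 + (0:floor(span / dt + 1e-9)) * dt
  pos <- vapply(1:3, function(j)
    approx(traj$t, traj$pos[, j], grid, rule = 2)$y,
    numeric(length(grid)))
  out <- traj
  out$t <- grid
  out$pos <- pos
  out
}

#' Per-sample object speed
#'
#' Central-difference velocity (one-sided at the ends), Euclidean norm.
#' Assumes a uniformly resampled trajectory.
#'
#' @param traj An `object_trajectory`.
#' @return Numeric vector of speeds (m/s), one per sample.
#' @export
compute_speed <- function(traj) {
  stopifnot(inherits(traj, "object_trajectory"))
  t <- traj$t
  p <- traj$pos
  n <- length(t)
  abort_if(n < 2, "need at least 2 samples")
  v <- matrix(NA_real_, n, 3)
  v[1, ] <- (p[2, ] - p[1, ]) / (t[2] - t[1])
  v[n, ] <- (p[n, ] - p[n - 1, ]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    v[i, ] <- (p[i + 1, , drop = FALSE] - p[i - 1, , drop = FALSE]) /
      (t[i + 1] - t[i - 1])
  }
  sqrt(rowSums(v^2))
}

#' Moving-sample mask
#'
#' `TRUE` where speed exceeds the gate. With `v_gate = 0` this is the
#' literal non-zero-velocity rule, appropriate for noise-free trajectories;
#' a small positive gate (e.g. 0.01 m/s) is recommended for measured data,
#' where a strict zero test would mark every sample as moving.
#'
#' @param speed Per-sample speed (m/s).
#' @param v_gate Speed gate (m/s, >= 0).
#' @return Logical vector.
#' @export
moving_mask <- function(speed, v_gate = 0) {
  abort_if(v_gate < 0, "v_gate must be >= 0")
  speed > v_gate
}

#' Task completion time
#'
#' Elapsed time during which the object is moving: the number of moving
#' samples times the sample period.
#'
#' @param traj A uniformly resampled `object_trajectory`.
#' @param v_gate Speed gate (m/s).
#' @return Seconds.
#' @export
completion_time <- function(traj, v_gate = 0) {
  mask <- moving_mask(compute_speed(traj), v_gate)
  dt <- (traj$t[length(traj$t)] - traj$t[1]) / (length(traj$t) - 1)
  sum(mask) * dt
}

#' Motion pathlength
#'
#' Accumulated 3-D displacement between consecutive samples while the
#' object is moving (a segment counts when either endpoint is moving, so
#' the full displacement of each movement episode is captured).
#'
#' @inheritParams completion_time
#' @return Meters.
#' @export
pathlength <- function(traj, v_gate = 0) {
  mask <- moving_mask(compute_speed(traj), v_gate)
  p <- traj$pos
  n <- nrow(p)
  if (n < 2) return(0)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  sum(seg[mask[-n] | mask[-1]])
}

# orthogonal projection of points onto a plane
project_onto_plane <- function(p, plane) {
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  d <- drop((p - matrix(plane$point, nrow(p), 3, byrow = TRUE)) %*% nrm)
  p - d %o% nrm
}

#' Placement error
#'
#' In-plane distance between the object's final resting position projected
#' onto the table surface and the (projected) target centre. The final
#' pose is the mean position over the trailing non-moving segment, which is
#' robust to residual jitter.
#'
#' @param traj A uniformly resampled `object_trajectory`.
#' @param target_center 3-D target centre (m); defaults to the
#'   trajectory's own.
#' @param table_plane List with `point` and `normal`; defaults to the
#'   trajectory's own.
#' @param v_gate Speed gate (m/s).
#' @return Meters.
#' @export
placement_error <- function(traj, target_center = traj$target_center,
                            table_plane = traj$table_plane, v_gate = 0) {
  mask <- moving_mask(compute_speed(traj), v_gate)
  n <- length(mask)
  last_moving <- if (any(mask)) max(which(mask)) else 0L
  abort_if(last_moving >= n,
           "no trailing rest segment: trajectory does not come to rest")
  final <- colMeans(traj$pos[(last_moving + 1L):n, , drop = FALSE])
  fp <- project_onto_plane(final, table_plane)
  tp <- project_onto_plane(target_center, table_plane)
  sqrt(sum((fp - tp)^2))
}

#' Score one functional-task trial
#'
#' Resamples to the metric rate, computes speed and the moving mask, and
#' returns the three performance metrics with gate diagnostics.
#'
#' @param traj An `object_trajectory`.
#' @param v_gate Speed gate (m/s). The default 0 is the literal
#'   non-zero-velocity rule, exact for the smooth synthetic trajectories;
#'   use ~0.01 m/s for noisy measured data.
#' @param rate Metric sampling rate (Hz).
#' @return Object of class `trial_metrics`: `time_s`, `path_m`, `error_m`,
#'   `n_moving`, `v_gate`, `rate`.
#' @export
score_trial <- function(traj, v_gate = 0, rate = 100) {
  rs <- resample_trajectory(traj, rate)
  speed <- compute_speed(rs)
  mask <- moving_mask(speed, v_gate)
  structure(list(time_s = completion_time(rs, v_gate),
                 path_m = pathlength(rs, v_gate),
                 error_m = placement_error(rs, v_gate = v_gate),
                 n_moving = sum(mask), v_gate = v_gate, rate = rate),
            class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("<trial_metrics> T = %.3f s, P = %.4f m, E = %.4f m (%d moving samples, gate %g m/s)\n",
              x$time_s, x$path_m, x$error_m, x$n_moving, x$v_gate))
  invisible(x)
}

#' Score every trajectory of a study
#'
#' @param study A `glove_study` generated with `trajectories = TRUE`.
#' @param v_gate,rate Passed to [score_trial()].
#' @return data.frame with subject, feedback_mode, block, trial and the
#'   three measured metrics.
#' @export
score_study <- function(study, v_gate = 0, rate = 100) {
  stopifnot(inherits(study, "glove_study"))
  abort_if(is.null(study$trajectories),
           "study has no trajectories; regenerate with trajectories = TRUE")
  scored <- t(vapply(study$trajectories, function(tr) {
    m <- score_trial(tr, v_gate, rate)
    c(m$time_s, m$path_m, m$error_m)
  }, numeric(3)))
  out <- study$trials[, c("subject", "feedback_mode", "block", "trial")]
  out$time_s <- scored[, 1]
  out$path_m <- scored[, 2]
  out$error_m <- scored[, 3]
  out
}
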