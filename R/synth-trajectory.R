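#' Learning-effect parameters of the synthetic functional-task study
#'
#' Encodes the study conditions that the trajectory generator realizes:
#' group baseline means for the three performance metrics (completion time,
#' pathlength, placement error), per-feedback-mode intra-training slopes
#' (metric units per trial; negative = improvement, the no-feedback mode
#' drifts mildly worse), post-training offsets (post mean minus pre mean),
#' per-trial metric noise SDs, and inter-subject baseline coefficients of
#' variation. Defaults reproduce the group pre-training means (1.48 s,
#' 0.25 m, 5.6 mm) and the per-mode effect structure of the glove study's
#' outcome tables.
#'
#' @param baseline Named numeric: `time_s`, `path_m`, `error_m` group
#'   baseline means (must be > 0).
#' @param slope 3 x 3 matrix of intra-training slopes, rows NF/IF/IBF,
#'   columns time_s/path_m/error_m (metric units per trial).
#' @param post_offset 3 x 3 matrix of post-training offsets (post mean
#'   minus pre mean), same layout as `slope`.
#' @param noise_sd Named numeric of per-trial metric noise SDs (>= 0).
#' @param subject_cv Named numeric of inter-subject baseline coefficients
#'   of variation.
#' @param start,target_center 3-D start position and target centre (m);
#'   the target sits ~20 cm to the left of the start.
#' @param lift_height Lift bump height of the transport path (m).
#' @param rest_pad_s Stationary padding before and after the movement (s).
#' @param mocap_rate_hz Trajectory sampling rate (Hz).
#' @return A list of class `learning_params`.
#' @export
learning_params <- function(
    baseline = c(time_s = 1.48, path_m = 0.25, error_m = 0.0056),
    slope = rbind(NF  = c(0.0067,  2.64e-4,  2.40e-5),
                  IF  = c(-0.0023, -1.15e-4, -1.32e-5),
                  IBF = c(-0.0048, -2.58e-4, -8.63e-6)),
    post_offset = rbind(NF  = c(0.0156,  0.0022,  8.65e-4),
                        IF  = c(-0.0831, -0.0017, 1.81e-4),
                        IBF = c(-0.090,  -0.0065, 7.06e-5)),
    noise_sd = c(time_s = 0.13, path_m = 0.02, error_m = 5e-4),
    subject_cv = c(time_s = 0.24, path_m = 0.07, error_m = 0.12),
    start = c(0, 0, 0), target_center = c(-0.20, 0, 0),
    lift_height = 0.02, rest_pad_s = 0.3, mocap_rate_hz = 120) {
  metrics <- c("time_s", "path_m", "error_m")
  abort_if(any(baseline <= 0), "baseline means must be > 0")
  abort_if(any(noise_sd < 0), "noise SDs must be >= 0")
  colnames(slope) <- metrics
  colnames(post_offset) <- metrics
  structure(list(baseline = baseline[metrics],
                 slope = slope[c("NF", "IF", "IBF"), , drop = FALSE],
                 post_offset = post_offset[c("NF", "IF", "IBF"), , drop = FALSE],
                 noise_sd = noise_sd[metrics],
                 subject_cv = subject_cv[metrics],
                 start = start, target_center = target_center,
                 lift_height = lift_height, rest_pad_s = rest_pad_s,
                 mocap_rate_hz = mocap_rate_hz),
            class = "learning_params")
}

block_sizes <- function() c(pre = 15L, training = 30L, post = 15L)

#' Expected trial metrics implied by the learning parameters
#'
#' Deterministic (noise-free) metric values for one trial: the subject's
#' baseline during the pre block, baseline plus `slope * (trial_index - 1)`
#' during training, and baseline plus the post-training offset in the post
#' block. Effects scale with the subject's baseline factor so that the
#' normalized effect structure is identical across subjects.
#'
#' @param block `"pre"`, `"training"` or `"post"`.
#' @param trial_index Trial number within the block (1-based).
#' @param feedback_mode `"NF"`, `"IF"` or `"IBF"`.
#' @param params A [learning_params()] object.
#' @param subject_scale Length-3 multiplicative baseline factor
#'   (time, path, error); 1 for the group-average subject.
#' @return Named numeric: `time_s`, `path_m`, `error_m`.
#' @export
expected_trial_metrics <- function(block, trial_index, feedback_mode,
                                   params = learning_params(),
                                   subject_scale = c(1, 1, 1)) {
  abort_if(!block %in% names(block_sizes()), "unknown block '%s'", block)
  abort_if(trial_index < 1 || trial_index > block_sizes()[[block]],
           "trial_index %d outside %s block", trial_index, block)
  eff <- switch(block,
                pre = c(0, 0, 0),
                training = params$slope[feedback_mode, ] * (trial_index - 1),
                post = params$post_offset[feedback_mode, ])
  m <- subject_scale * (params$baseline + eff)
  names(m) <- names(params$baseline)
  m
}

# draw one trial's realized metrics (expected + seeded noise) plus the
# in-plane placement-offset angle; clamped away from degenerate values
draw_trial_metrics <- function(block, trial_index, feedback_mode, params,
                               subject_scale, seed) {
  mu <- expected_trial_metrics(block, trial_index, feedback_mode,
                               params, subject_scale)
  with_seed(seed, {
    z <- rnorm(3)
    angle <- runif(1, 0, 2 * pi)
  })
  v <- mu + z * params$noise_sd
  v["time_s"] <- max(v["time_s"], 0.4)
  v["error_m"] <- max(v["error_m"], 0)
  # shortest realizable path for the drawn end point (chord + lift bump)
  endpt <- params$target_center +
    v[["error_m"]] * c(cos(angle), sin(angle), 0)
  d <- sqrt(sum((endpt - params$start)^2))
  min_len <- shape_arc_length(d, params$lift_height)
  v["path_m"] <- max(v["path_m"], min_len * (1 + 1e-12))
  list(metrics = v, angle = angle)
}

# arc length of the transport shape: straight chord of length `d` plus a
# perpendicular sinusoidal bump of combined amplitude `c` (lift + lateral);
# both perpendicular components are orthogonal to the chord, so
# |r'(s)|^2 = d^2 + pi^2 c^2 cos^2(pi s). Evaluated by trapezoid quadrature.
shape_arc_length <- function(d, c_amp, n_quad = 400) {
  s <- seq(0, 1, length.out = n_quad + 1)
  f <- sqrt(d^2 + pi^2 * c_amp^2 * cos(pi * s)^2)
  sum((f[-1] + f[-length(f)]) / 2) / n_quad
}

# build positions of a minimum-jerk transport whose arc length equals
# `path_m`, ending `error_m` from the target centre (direction `angle`),
# padded with stationary rest at both ends; sampled at the mocap rate
build_transport_positions <- function(time_s, path_m, error_m, angle, params) {
  start <- params$start
  endpt <- params$target_center +
    error_m * c(cos(angle), sin(angle), 0)
  d_vec <- endpt - start
  d <- sqrt(sum(d_vec^2))
  abort_if(d <= 0, "degenerate geometry: start equals end point")
  d_hat <- d_vec / d
  up <- c(0, 0, 1)
  lat <- c(-d_hat[2], d_hat[1], 0)           # horizontal, perpendicular to chord
  lnorm <- sqrt(sum(lat^2))
  lat <- if (lnorm > 0) lat / lnorm else c(1, 0, 0)

  h <- params$lift_height
  base_len <- shape_arc_length(d, h)
  target_len <- max(path_m, base_len)
  a <- 0
  if (target_len > base_len + 1e-12) {
    a <- uniroot(function(a) shape_arc_length(d, sqrt(h^2 + a^2)) - target_len,
                 interval = c(0, target_len), tol = 1e-12)$root
  }

  dt <- 1 / params$mocap_rate_hz
  pad <- params$rest_pad_s
  total <- time_s + 2 * pad
  t <- seq(0, total, by = dt)
  tau <- pmin(pmax((t - pad) / time_s, 0), 1)
  s <- tau^3 * (10 - 15 * tau + 6 * tau^2)   # minimum-jerk time profile
  bump <- sin(pi * s)
  pos <- cbind(start[1] + d_vec[1] * s + (h * up[1] + a * lat[1]) * bump,
               start[2] + d_vec[2] * s + (h * up[2] + a * lat[2]) * bump,
               start[3] + d_vec[3] * s + (h * up[3] + a * lat[3]) * bump)
  list(t = t, pos = pos)
}

#' Construct an object-trajectory record
#'
#' Container for one functional-task trial: timestamped 3-D object-centre
#' positions together with the task geometry needed to score it.
#'
#' @param t Strictly increasing timestamps (s).
#' @param pos n x 3 matrix of object-centre positions (m).
#' @param target_center 3-D target centre (m).
#' @param table_plane List with `point` (3-D) and `normal` (unit 3-D).
#' @param trial_index,block,feedback_mode Protocol tags (optional).
#' @param seed Generator seed (optional).
#' @param metrics_drawn Realized metric values the trajectory encodes
#'   (optional, generator bookkeeping).
#' @return Object of class `object_trajectory`.
#' @export
object_trajectory <- function(t, pos, target_center,
                              table_plane = list(point = c(0, 0, 0),
                                                 normal = c(0, 0, 1)),
                              trial_index = NA_integer_, block = NA_character_,
                              feedback_mode = NA_character_, seed = NA,
                              metrics_drawn = NULL) {
  pos <- as.matrix(pos)
  abort_if(length(t) != nrow(pos), "t and pos lengths differ")
  abort_if(any(diff(t) <= 0), "timestamps must be strictly increasing")
  abort_if(any(!is.finite(pos)), "positions must be finite")
  nrm <- table_plane$normal / sqrt(sum(table_plane$normal^2))
  structure(list(t = t, pos = pos, target_center = target_center,
                 table_plane = list(point = table_plane$point, normal = nrm),
                 trial_index = trial_index, block = block,
                 feedback_mode = feedback_mode, seed = seed,
                 metrics_drawn = metrics_drawn),
            class = "object_trajectory")
}

#' @export
print.object_trajectory <- function(x, ...) {
  cat(sprintf("<object_trajectory> %d samples, %.2f s (%s/%s trial %s)\n",
              nrow(x$pos), diff(range(x$t)), x$feedback_mode, x$block,
              x$trial_index))
  invisible(x)
}

#' Generate one functional-task object trajectory
#'
#' Draws the trial's realized metrics (expected value from
#' [expected_trial_metrics()] plus zero-mean noise) and synthesizes a
#' smooth minimum-jerk grasp-move-place trajectory realizing them exactly:
#' movement duration equals the drawn completion time, path arc length
#' equals the drawn pathlength (straight chord plus a 2 cm lift bump and a
#' lateral sinusoidal detour solved to match), and the final resting
#' position sits the drawn placement error from the target centre, in a
#' seeded random in-plane direction. Stationary rest pads the movement at
#' both ends.
#'
#' @inheritParams expected_trial_metrics
#' @param seed Integer seed for the trial's noise draws.
#' @return An [object_trajectory()].
#' @export
generate_task_trajectory <- function(block, trial_index,
                                     feedback_mode = c("NF", "IF", "IBF"),
                                     params = learning_params(), seed = 1,
                                     subject_scale = c(1, 1, 1)) {
  feedback_mode <- match.arg(feedback_mode)
  dr <- draw_trial_metrics(block, trial_index, feedback_mode, params,
                           subject_scale, seed)
  bp <- build_transport_positions(dr$metrics[["time_s"]],
                                  dr$metrics[["path_m"]],
                                  dr$metrics[["error_m"]], dr$angle, params)
  object_trajectory(bp$t, bp$pos, params$target_center,
                    trial_index = trial_index, block = block,
                    feedback_mode = feedback_mode, seed = seed,
                    metrics_drawn = dr$metrics)
}

#' Generate one subject session (pre / training / post blocks)
#'
#' One session = one feedback mode: 15 pre-training trials, 30 training
#' trials under the mode, 15 post-training retention trials. Per-trial
#' metric values are drawn from the learning model; full trajectories are
#' materialized on request.
#'
#' @param subject_id Subject label.
#' @param feedback_mode `"NF"`, `"IF"` or `"IBF"`.
#' @param params A [learning_params()] object.
#' @param seed Session master seed (per-trial sub-seeds derived from it).
#' @param subject_scale Length-3 baseline factor for this subject.
#' @param blocks Which blocks to generate (default all three).
#' @param trajectories If `TRUE`, also return the synthesized
#'   `object_trajectory` list.
#' @return List with `trials` (data.frame: subject, feedback_mode, block,
#'   trial, time_s, path_m, error_m, seed) and `trajectories` (list or NULL).
#' @export
generate_session <- function(subject_id, feedback_mode,
                             params = learning_params(), seed = 1,
                             subject_scale = c(1, 1, 1),
                             blocks = c("pre", "training", "post"),
                             trajectories = FALSE) {
  sizes <- block_sizes()[blocks]
  ntot <- sum(sizes)
  out <- matrix(NA_real_, ntot, 3)
  blk <- character(ntot)
  idx <- integer(ntot)
  seeds <- numeric(ntot)
  trajs <- if (trajectories) vector("list", ntot) else NULL
  row <- 0L
  counter <- 0L
  for (b in blocks) {
    for (k in seq_len(sizes[[b]])) {
      row <- row + 1L
      counter <- counter + 1L
      s_k <- derive_seed(seed, counter)
      dr <- draw_trial_metrics(b, k, feedback_mode, params, subject_scale, s_k)
      out[row, ] <- dr$metrics
      blk[row] <- b
      idx[row] <- k
      seeds[row] <- s_k
      if (trajectories) {
        bp <- build_transport_positions(dr$metrics[["time_s"]],
                                        dr$metrics[["path_m"]],
                                        dr$metrics[["error_m"]], dr$angle,
                                        params)
        trajs[[row]] <- object_trajectory(bp$t, bp$pos, params$target_center,
                                          trial_index = k, block = b,
                                          feedback_mode = feedback_mode,
                                          seed = s_k,
                                          metrics_drawn = dr$metrics)
      }
    }
  }
  trials <- data.frame(subject = subject_id, feedback_mode = feedback_mode,
                       block = blk, trial = idx,
                       time_s = out[, 1], path_m = out[, 2],
                       error_m = out[, 3], seed = seeds,
                       stringsAsFactors = FALSE)
  list(trials = trials, trajectories = trajs)
}

#' Generate a full synthetic study
#'
#' Every subject completes three sessions, one per feedback mode
#' (within-subject design), each with 15/30/15 pre/training/post trials.
#' Subject baseline factors are drawn per metric with the configured
#' coefficient of variation and standardized so the realized group mean is
#' exactly 1 and the realized CV exactly matches the configuration
#' (motivating intra-subject normalization without sampling drift).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param params A [learning_params()] object.
#' @param seed Master seed.
#' @param trajectories If `TRUE`, materialize all object trajectories
#'   (n_subjects x 3 x 60 of them).
#' @return Object of class `glove_study`: list with `trials` (data.frame),
#'   `trajectories` (list or NULL), `subject_scales` (n x 3 matrix),
#'   `params`, `seed`.
#' @export
#' @examples
#' st <- generate_study(3, seed = 11)
#' head(st$trials)
generate_study <- function(n_subjects, params = learning_params(), seed = 1,
                           trajectories = FALSE) {
  abort_if(n_subjects < 1, "n_subjects must be >= 1")
  scales <- with_seed(derive_seed(seed, 0), {
    m <- matrix(1, n_subjects, 3,
                dimnames = list(NULL, names(params$baseline)))
    if (n_subjects > 1) {
      for (j in 1:3) {
        cv <- params$subject_cv[[j]]
        if (cv > 0) {
          z <- rnorm(n_subjects)
          z <- (z - mean(z)) / sd(z)
          m[, j] <- pmax(1 + cv * z, 0.05)
        }
      }
    }
    m
  })
  modes <- c("NF", "IF", "IBF")
  all_trials <- vector("list", n_subjects * 3L)
  all_trajs <- if (trajectories) list() else NULL
  k <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    for (m in modes) {
      k <- k + 1L
      ses <- generate_session(sid, m, params,
                              seed = derive_seed(seed, k),
                              subject_scale = scales[i, ],
                              trajectories = trajectories)
      all_trials[[k]] <- ses$trials
      if (trajectories) all_trajs <- c(all_trajs, ses$trajectories)
    }
  }
  structure(list(trials = do.call(rbind, all_trials),
                 trajectories = all_trajs,
                 subject_scales = scales, params = params, seed = seed),
            class = "glove_study")
}

#' @export
print.glove_study <- function(x, ...) {
  ns <- length(unique(x$trials$subject))
  cat(sprintf("<glove_study> %d subjects x 3 sessions, %d trials%s\n",
              ns, nrow(x$trials),
              if (!is.null(x$trajectories))
                sprintf(" (%d trajectories)", length(x$trajectories)) else ""))
  invisible(x)
}
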