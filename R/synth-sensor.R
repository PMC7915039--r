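#' Sensor-model parameters for the synthetic glove generator
#'
#' Fixed description of the emulated glove: ten voltage channels (five
#' force, five flex, one pair per digit in thumb..little order) sampled at
#' 40 Hz over 10-second trials, voltages clipped to `[0, v_max]`.
#'
#' The signal model is a logistic rise/fall envelope per active channel:
#' contact begins near `t_on`, a steady hold plateau spans the annotated
#' hold window, and release occurs near `t_off`. Physiological texture is
#' added deliberately:
#' \itemize{
#'   \item per-trial plateau amplitude jitter (`amp_jitter`, relative SD);
#'   \item a small per-trial thumb/index force imbalance for precision
#'     pinch (`pinch_imbalance_max`, drawn uniformly from 0 to this value),
#'     keeping the two plateaus near-equal;
#'   \item an initial thumb-force overshoot during grip formation
#'     (`thumb_overshoot` relative amplitude, Gaussian bump centred at
#'     `overshoot_center` s) — the transient where force equilibrium
#'     between digits has not yet settled;
#'   \item grip-force fluctuation shared across active force channels
#'     (common-mode fraction of the voltage noise), with the remainder
#'     independent per channel.
#' }
#' For tri-pod and whole-hand grips the thumb pad opposes several digits at
#' once, so its force-sensor plateau is generated weak
#' (`thumb_weak_frac` of the other digits' plateau).
#'
#' The object is light, so active force channels plateau at a low voltage
#' (`force_plateau_v`, default 0.34 V) sitting just above 10% of the
#' sensor range — the regime in which an analytical force-equilibrium
#' detector with a 10%-of-maximum floor degrades, because grip-force
#' fluctuation intermittently drops the reading below the floor while the
#' frame remains inside the secure band. Flex channels, which measure
#' digit bend rather than contact force, plateau much higher.
#'
#' @param rate_hz Sampling rate (Hz).
#' @param duration_s Trial duration (s).
#' @param v_max Sensor saturation voltage (V).
#' @param force_plateau_v Hold-plateau amplitude of an active force channel (V).
#' @param flex_plateau_v Hold-plateau amplitude of an active flex channel (V).
#' @param thumb_weak_frac Thumb force plateau as a fraction of the other
#'   active digits' plateau, for tri-pod and whole-hand grips.
#' @param noise_sd Default voltage noise SD (V); 2% of the force plateau.
#' @param rest_noise_sd Noise floor used for rest trials inside a training
#'   corpus (V); 0.5% of `v_max`.
#' @param t_on,t_off Contact / release times of the hold envelope (s).
#' @param tau Logistic envelope time constant (s).
#' @param hold_window_s Annotated steady-hold window (s, start/end).
#' @param amp_jitter Relative SD of the per-trial plateau amplitude.
#' @param pinch_imbalance_max Maximum relative thumb/index plateau
#'   imbalance for precision pinch.
#' @param thumb_overshoot Relative amplitude of the thumb-force formation
#'   overshoot.
#' @param overshoot_center,overshoot_width Centre and Gaussian width of the
#'   overshoot bump (s).
#' @param noise_common_frac Fraction of force-channel noise SD that is
#'   common-mode across active force channels (`sqrt(1 - frac^2)` remains
#'   independent).
#' @param tap_centers Contact times of the tap protocol (s).
#' @param tap_halfwidth Half-duration of one tap contact (s).
#' @param tap_tau Logistic time constant of tap edges (s).
#' @param tap_peak_range Range of per-tap peak amplitude as a fraction of
#'   the hold plateau; taps stay below the secure band by construction.
#' @return A list of class `sensor_params`.
#' @export
sensor_params <- function(rate_hz = 40, duration_s = 10, v_max = 3.3,
                          force_plateau_v = 0.34, flex_plateau_v = 1.2,
                          thumb_weak_frac = 0.15,
                          noise_sd = 0.02 * force_plateau_v,
                          rest_noise_sd = 0.005 * v_max,
                          t_on = 2, t_off = 8, tau = 0.15,
                          hold_window_s = c(3, 7),
                          amp_jitter = 0.02, pinch_imbalance_max = 0.01,
                          thumb_overshoot = 0.16,
                          overshoot_center = 2.45, overshoot_width = 0.22,
                          noise_common_frac = 0.97,
                          tap_centers = seq(1.5, 8.5, by = 1),
                          tap_halfwidth = 0.15, tap_tau = 0.03,
                          tap_peak_range = c(0.5, 0.85)) {
  abort_if(v_max <= 0, "v_max must be positive")
  abort_if(noise_sd < 0 || rest_noise_sd < 0, "noise SDs must be >= 0")
  abort_if(hold_window_s[2] - hold_window_s[1] < 3,
           "hold window must span at least 3 s")
  p <- list(rate_hz = rate_hz, duration_s = duration_s, v_max = v_max,
            force_plateau_v = force_plateau_v,
            flex_plateau_v = flex_plateau_v,
            thumb_weak_frac = thumb_weak_frac,
            noise_sd = noise_sd, rest_noise_sd = rest_noise_sd,
            t_on = t_on, t_off = t_off, tau = tau,
            hold_window_s = hold_window_s,
            amp_jitter = amp_jitter,
            pinch_imbalance_max = pinch_imbalance_max,
            thumb_overshoot = thumb_overshoot,
            overshoot_center = overshoot_center,
            overshoot_width = overshoot_width,
            noise_common_frac = noise_common_frac,
            tap_centers = tap_centers, tap_halfwidth = tap_halfwidth,
            tap_tau = tap_tau, tap_peak_range = tap_peak_range)
  class(p) <- "sensor_params"
  p
}

# digits engaged by each grip (1 = thumb, 2 = index, ..., 5 = little)
grip_digits <- function(grip) {
  switch(grip,
         pinch = c(1L, 2L),
         tripod = c(1L, 2L, 3L),
         whole_hand = 1:5,
         none = integer(0),
         stop("unknown grip: ", grip, call. = FALSE))
}

#' Generate one synthetic glove sensor trial
#'
#' Emulates a single 10-s, 40 Hz recording of the five force and five flex
#' channels for one grip/protocol combination. `hold` trials rise to a
#' steady plateau and fall back to rest, with the steady-hold window
#' annotated; `tap` trials contain short (< 0.5 s) contact bursts whose
#' peaks stay below the secure band; `rest` trials are baseline noise only
#' (identically zero when `noise_sd = 0`).
#'
#' @param grip One of `"pinch"`, `"tripod"`, `"whole_hand"`, `"none"`.
#'   `"none"` is required for (and only for) the rest protocol.
#' @param protocol One of `"hold"`, `"tap"`, `"rest"`.
#' @param noise_sd Voltage noise SD (V).
#' @param seed Integer seed; identical arguments give identical trials.
#' @param params A [sensor_params()] object.
#' @return An object of class `grasp_trial`: list with `grip`, `protocol`,
#'   `t` (timestamps, s), `force` and `flex` (n x 5 voltage matrices),
#'   `hold_window` (frame index range, hold trials only), `seed`,
#'   `rate_hz`, `v_max`.
#' @export
#' @examples
#' tr <- generate_grasp_trial("pinch", "hold", noise_sd = 0.01, seed = 7)
#' tr$hold_window
generate_grasp_trial <- function(grip = c("pinch", "tripod", "whole_hand", "none"),
                                 protocol = c("hold", "tap", "rest"),
                                 noise_sd = NULL, seed = 1,
                                 params = sensor_params()) {
  grip <- match.arg(grip)
  protocol <- match.arg(protocol)
  if (is.null(noise_sd)) noise_sd <- params$noise_sd
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  abort_if(protocol == "rest" && grip != "none",
           "rest protocol requires grip = 'none' (got '%s')", grip)
  abort_if(protocol != "rest" && grip == "none",
           "grip = 'none' is only valid for the rest protocol")

  n <- round(params$duration_s * params$rate_hz) + 1L
  t <- (seq_len(n) - 1L) / params$rate_hz
  digits <- grip_digits(grip)

  force_amp <- numeric(5)
  flex_amp <- numeric(5)
  hold_window <- NULL

  with_seed(seed, {
    a_rel <- 1 + rnorm(1, 0, params$amp_jitter)
    delta <- runif(1, 0, params$pinch_imbalance_max)
    tap_peaks <- runif(length(params$tap_centers),
                       params$tap_peak_range[1], params$tap_peak_range[2])
    common <- rnorm(n, 0, 1)
    eps <- matrix(rnorm(n * 10L, 0, 1), n, 10L)

    if (length(digits)) {
      force_amp[digits] <- params$force_plateau_v
      flex_amp[digits] <- params$flex_plateau_v
      if (grip == "pinch") {
        force_amp[1L] <- params$force_plateau_v * (1 - delta)
      } else {
        force_amp[1L] <- params$force_plateau_v * params$thumb_weak_frac
      }
    }

    env <- switch(protocol,
      hold = plogis((t - params$t_on) / params$tau) *
             plogis((params$t_off - t) / params$tau),
      tap = {
        e <- numeric(n)
        for (j in seq_along(params$tap_centers)) {
          cj <- params$tap_centers[j]
          e <- e + tap_peaks[j] *
            plogis((t - (cj - params$tap_halfwidth)) / params$tap_tau) *
            plogis(((cj + params$tap_halfwidth) - t) / params$tap_tau)
        }
        pmin(e, 1)
      },
      rest = numeric(n))

    # thumb-force formation overshoot (hold trials only)
    ov <- if (protocol == "hold") {
      1 + params$thumb_overshoot *
        exp(-((t - params$overshoot_center) / params$overshoot_width)^2)
    } else {
      rep(1, n)
    }

    force <- outer(env, a_rel * force_amp)
    force[, 1L] <- force[, 1L] * ov
    flex <- outer(env, a_rel * flex_amp)

    # voltage noise: grip-force fluctuation is common-mode across active
    # force channels; everything else is independent sensor noise
    cf <- params$noise_common_frac
    indep <- sqrt(max(0, 1 - cf^2))
    noise <- eps * noise_sd
    if (length(digits)) {
      noise[, digits] <- (indep * eps[, digits] + cf * common) * noise_sd
    }
    force <- force + noise[, 1:5]
    flex <- flex + noise[, 6:10]
  })

  force <- pmin(pmax(force, 0), params$v_max)
  flex <- pmin(pmax(flex, 0), params$v_max)
  colnames(force) <- paste0("f", 1:5)
  colnames(flex) <- paste0("x", 1:5)

  if (protocol == "hold") {
    idx <- which(t >= params$hold_window_s[1] & t <= params$hold_window_s[2])
    hold_window <- c(min(idx), max(idx))
  }

  structure(list(grip = grip, protocol = protocol, t = t,
                 force = force, flex = flex,
                 hold_window = hold_window, seed = seed,
                 rate_hz = params$rate_hz, v_max = params$v_max),
            class = "grasp_trial")
}

#' @export
print.grasp_trial <- function(x, ...) {
  cat(sprintf("<grasp_trial> grip=%s protocol=%s  %d frames @ %g Hz (%.1f s)\n",
              x$grip, x$protocol, length(x$t), x$rate_hz,
              length(x$t) / x$rate_hz))
  if (!is.null(x$hold_window)) {
    cat(sprintf("  hold window: frames %d..%d (t = %.2f..%.2f s)\n",
                x$hold_window[1], x$hold_window[2],
                x$t[x$hold_window[1]], x$t[x$hold_window[2]]))
  }
  invisible(x)
}

#' Voltage feature matrix of a trial
#'
#' Returns the n x 10 matrix of sensor voltages (force channels f1..f5,
#' then flex channels x1..x5) used as classifier features.
#'
#' @param trial A `grasp_trial`.
#' @return Numeric matrix with 10 columns.
#' @export
trial_features <- function(trial) {
  stopifnot(inherits(trial, "grasp_trial"))
  cbind(trial$force, trial$flex)
}

#' Generate a per-subject training corpus
#'
#' Produces the fixed training-session composition: 20 hold trials per each
#' of the three grips, 20 tap trials per grip, and 5 rest trials (125
#' trials total). Per-trial sub-seeds are derived deterministically from
#' the master seed, so the corpus is reproducible bit-for-bit.
#'
#' Rest trials use the generator's rest noise floor
#' (`params$rest_noise_sd`) rather than `noise_sd`, so the insecure rest
#' class is never degenerate.
#'
#' @param subject_id Character or integer subject label.
#' @param noise_sd Voltage noise SD for hold and tap trials (V).
#' @param seed Master seed.
#' @param params A [sensor_params()] object.
#' @param n_hold,n_tap,n_rest Trials per grip (hold, tap) and rest-trial
#'   count; defaults follow the study session design.
#' @return Object of class `training_corpus`: list with `subject_id`,
#'   `trials` (named list of `grasp_trial`), `seed`.
#' @export
generate_training_corpus <- function(subject_id, noise_sd = NULL, seed = 1,
                                     params = sensor_params(),
                                     n_hold = 20, n_tap = 20, n_rest = 5) {
  if (is.null(noise_sd)) noise_sd <- params$noise_sd
  grips <- c("pinch", "tripod", "whole_hand")
  trials <- list()
  counter <- 0L
  for (protocol in c("hold", "tap")) {
    nrep <- if (protocol == "hold") n_hold else n_tap
    for (g in grips) {
      for (k in seq_len(nrep)) {
        counter <- counter + 1L
        id <- sprintf("%s_%s_%s_%02d", subject_id, substr(protocol, 1, 1), g, k)
        trials[[id]] <- generate_grasp_trial(g, protocol, noise_sd,
                                             seed = derive_seed(seed, counter),
                                             params = params)
      }
    }
  }
  for (k in seq_len(n_rest)) {
    counter <- counter + 1L
    id <- sprintf("%s_r_rest_%02d", subject_id, k)
    trials[[id]] <- generate_grasp_trial("none", "rest", params$rest_noise_sd,
                                         seed = derive_seed(seed, counter),
                                         params = params)
  }
  structure(list(subject_id = subject_id, trials = trials, seed = seed,
                 noise_sd = noise_sd, params = params),
            class = "training_corpus")
}

#' @export
print.training_corpus <- function(x, ...) {
  prot <- vapply(x$trials, function(tr) tr$protocol, character(1))
  cat(sprintf("<training_corpus> subject=%s  %d trials (%s)\n",
              x$subject_id, length(x$trials),
              paste(sprintf("%s=%d", names(table(prot)), table(prot)),
                    collapse = ", ")))
  invisible(x)
}
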