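#' Build a feedback schedule for a training block
#'
#' Three feedback modes: `NF` (no feedback: no events are ever emitted),
#' `IF` (immediate feedback: zero delay on every trial), and `IBF`
#' (intentional-binding feedback: the delay between secure-grasp detection
#' and the sensory cue ramps linearly from 1 s on trial 1 to 0 s on the
#' last trial, a fixed decrement of `1/(n_trials - 1)` s — about 34 ms per
#' trial over 30 trials).
#'
#' @param mode `"NF"`, `"IF"` or `"IBF"`.
#' @param n_trials Trials in the training block (default 30; IBF requires
#'   at least 2).
#' @return Object of class `feedback_schedule`: `mode`, `n_trials`,
#'   `delays` (seconds per trial; `NULL` for NF).
#' @export
#' @examples
#' sched <- build_schedule("IBF", 30)
#' sched$delays[c(1, 30)]
build_schedule <- function(mode = c("NF", "IF", "IBF"), n_trials = 30) {
  mode <- match.arg(mode)
  abort_if(n_trials < 1, "n_trials must be >= 1")
  delays <- switch(mode,
    NF = NULL,
    IF = rep(0, n_trials),
    IBF = {
      abort_if(n_trials < 2, "IBF ramp requires n_trials >= 2")
      (n_trials - seq_len(n_trials)) / (n_trials - 1)
    })
  structure(list(mode = mode, n_trials = n_trials, delays = delays),
            class = "feedback_schedule")
}

#' @export
print.feedback_schedule <- function(x, ...) {
  cat(sprintf("<feedback_schedule> mode=%s, %d trials", x$mode, x$n_trials))
  if (x$mode == "IBF") {
    cat(sprintf("; delay %0.3f -> %0.3f s (step %.1f ms)",
                x$delays[1], x$delays[x$n_trials],
                1000 / (x$n_trials - 1)))
  }
  cat("\n")
  invisible(x)
}

#' Secure-grasp onset time from a rounded detection sequence
#'
#' Returns the timestamp of the first frame that begins a run of at least
#' `debounce_frames` consecutive secure (1) decisions, or `NULL` if no such
#' run exists. Detection is causal: the onset depends only on frames at or
#' before it.
#'
#' @param rounded Integer 0/1 decision per frame.
#' @param t Frame timestamps (s).
#' @param debounce_frames Minimum run length (default 1).
#' @return Onset time in seconds, or `NULL`.
#' @export
secure_onset_time <- function(rounded, t, debounce_frames = 1) {
  abort_if(length(rounded) == 0, "empty detection stream")
  abort_if(length(rounded) != length(t), "rounded and t lengths differ")
  r <- rle(rounded == 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= debounce_frames)
  if (!length(hit)) return(NULL)
  t[starts[hit[1]]]
}

#' Detect secure-grasp onset from a streaming classifier
#'
#' Runs the trained network over a sensor-trial stream, rounds the
#' continuous output, and returns the onset of the first debounced run of
#' secure decisions.
#'
#' @param model A trained `ann_model`.
#' @param trial A `grasp_trial` sensor stream.
#' @param debounce_frames Minimum consecutive secure frames (default 1,
#'   triggering directly on the rounded network output).
#' @return Detection time in seconds (trial clock), or `NULL` if secure
#'   grasp is never detected.
#' @export
detect_secure_onset <- function(model, trial, debounce_frames = 1) {
  stopifnot(inherits(model, "ann_model"), inherits(trial, "grasp_trial"))
  abort_if(length(trial$t) == 0, "empty sensor stream")
  rounded <- round_output(predict(model, trial_features(trial)))
  secure_onset_time(rounded, trial$t, debounce_frames)
}

#' Emit the beep/LED feedback event for one trial
#'
#' Under NF no event is emitted. Otherwise the audio beep (fixed 100 ms
#' duration) starts at the detection time plus the trial's scheduled delay,
#' and the LED activates simultaneously with the beep and stays on until
#' object release. If the delayed onset falls after release, the event is
#' still emitted but its LED interval is empty and the event is flagged.
#'
#' @param schedule A [build_schedule()] result.
#' @param trial_index Trial number within the schedule.
#' @param t_d Secure-grasp detection time (s, trial clock).
#' @param t_release Object release time (s); optional.
#' @return `NULL` for NF, otherwise an object of class `feedback_event`:
#'   `trial_index`, `t_detect`, `beep_onset`, `beep_duration` (0.1 s),
#'   `led_interval` (length-2 or NULL), `flagged`.
#' @export
emit_events <- function(schedule, trial_index, t_d, t_release = NULL) {
  stopifnot(inherits(schedule, "feedback_schedule"))
  abort_if(trial_index < 1 || trial_index > schedule$n_trials,
           "trial_index %d outside schedule (1..%d)",
           trial_index, schedule$n_trials)
  if (schedule$mode == "NF") return(NULL)
  abort_if(!is.null(t_release) && t_release <= t_d,
           "t_release must be after detection time")
  onset <- t_d + schedule$delays[trial_index]
  flagged <- FALSE
  led <- NULL
  if (!is.null(t_release)) {
    if (onset > t_release) {
      flagged <- TRUE                        # cue would land after release
    } else {
      led <- c(onset, t_release)
    }
  } else {
    led <- c(onset, NA_real_)
  }
  structure(list(trial_index = trial_index, t_detect = t_d,
                 beep_onset = onset, beep_duration = 0.100,
                 led_interval = led, flagged = flagged),
            class = "feedback_event")
}

#' @export
print.feedback_event <- function(x, ...) {
  cat(sprintf("<feedback_event> trial %d: detect %.3f s, beep %.3f s%s\n",
              x$trial_index, x$t_detect, x$beep_onset,
              if (x$flagged) " [flagged: empty LED interval]" else ""))
  invisible(x)
}
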