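#' Hold-window channel statistics
#'
#' Per-channel arithmetic mean voltage over a hold trial's steady-hold
#' window, with an activity flag per channel. A channel is active when its
#' hold mean reaches `activity_floor * v_max`; the secure-grasp band is
#' applied only to active channels, since a relative band around a
#' near-zero mean would be noise-dominated and vacuous.
#'
#' @param trial A `grasp_trial` with `protocol == "hold"` and an annotated
#'   hold window.
#' @param activity_floor Fraction of `v_max` a channel's hold mean must
#'   reach to count as active (set 0 to force the band onto all channels).
#' @return Object of class `hold_stats`: `means` (named length-10),
#'   `active` (logical length-10), `v_max`, `activity_floor`.
#' @export
compute_hold_statistics <- function(trial, activity_floor = 0.05) {
  stopifnot(inherits(trial, "grasp_trial"))
  abort_if(trial$protocol != "hold",
           "hold statistics require a hold trial (got '%s')", trial$protocol)
  abort_if(is.null(trial$hold_window), "trial has no hold window")
  w <- trial$hold_window
  feats <- trial_features(trial)
  abort_if(w[1] < 1 || w[2] > nrow(feats) || w[1] > w[2],
           "hold window out of bounds")
  means <- colMeans(feats[w[1]:w[2], , drop = FALSE])
  hold_stats(means, trial$v_max, activity_floor)
}

#' @rdname compute_hold_statistics
#' @param means Named length-10 vector of channel means (V).
#' @param v_max Sensor saturation voltage (V).
#' @export
hold_stats <- function(means, v_max, activity_floor = 0.05) {
  abort_if(length(means) != 10, "expected 10 channel means")
  structure(list(means = means,
                 active = unname(means >= activity_floor * v_max),
                 v_max = v_max, activity_floor = activity_floor),
            class = "hold_stats")
}

#' @export
print.hold_stats <- function(x, ...) {
  cat("<hold_stats> active channels:",
      paste(names(x$means)[x$active], collapse = " "), "\n")
  print(round(x$means, 3))
  invisible(x)
}

#' Label frames as secure (1) or insecure (0) grasp
#'
#' A frame is secure iff, on every active channel, its voltage lies within
#' `tol` (relative) of that channel's steady-hold mean; all other frames
#' are insecure. Tap and rest trials are labeled by the same rule against
#' the hold statistics of their grip context, which makes their frames
#' predominantly insecure exemplars.
#'
#' @param trial A `grasp_trial` (any protocol).
#' @param stats A `hold_stats` object giving the grip context.
#' @param tol Relative half-width of the secure band (default 0.10,
#'   i.e. +/- 10%).
#' @return Integer vector of 0/1 labels, one per frame.
#' @export
label_frames <- function(trial, stats, tol = 0.10) {
  stopifnot(inherits(trial, "grasp_trial"), inherits(stats, "hold_stats"))
  abort_if(tol <= 0, "tol must be > 0")
  abort_if(!any(stats$active),
           "no active channels in hold statistics: uninformative grip context")
  feats <- trial_features(trial)
  label_feature_frames(feats, stats, tol)
}

# vectorized core: works on any n x 10 feature matrix
label_feature_frames <- function(feats, stats, tol = 0.10) {
  act <- which(stats$active)
  m <- stats$means[act]
  dev <- abs(sweep(feats[, act, drop = FALSE], 2, m)) <=
    matrix(tol * m, nrow(feats), length(act), byrow = TRUE)
  as.integer(rowSums(dev) == length(act))
}

# pooled hold statistics for one grip: means over all hold-window frames
# of that grip's hold trials
pool_hold_statistics <- function(corpus, grip, activity_floor = 0.05) {
  hold <- Filter(function(tr) tr$protocol == "hold" && tr$grip == grip,
                 corpus$trials)
  abort_if(!length(hold), "corpus has no hold trials for grip '%s'", grip)
  rows <- lapply(hold, function(tr) {
    w <- tr$hold_window
    trial_features(tr)[w[1]:w[2], , drop = FALSE]
  })
  hold_stats(colMeans(do.call(rbind, rows)), hold[[1]]$v_max, activity_floor)
}

#' Assemble the labeled train/validation/test dataset for one subject
#'
#' Pools every frame of every trial in the corpus into one feature matrix,
#' labels frames with the secure band rule (hold trials against their own
#' hold statistics; tap trials against the pooled hold statistics of the
#' same grip; rest trials against the pooled statistics of
#' `rest_context`), and assigns a seeded random 70/15/15
#' train/validation/test split.
#'
#' @param corpus A `training_corpus`.
#' @param fractions Train/validation/test fractions (must sum to 1).
#' @param tol Secure-band relative tolerance.
#' @param activity_floor Channel activity floor (fraction of `v_max`).
#' @param seed Split seed.
#' @param split_by `"frame"` (random by frame, the study default) or
#'   `"trial"` (whole trials per split, which avoids leaking temporally
#'   correlated frames across splits).
#' @param rest_context Grip whose pooled hold statistics label the rest
#'   trials (default `"pinch"`).
#' @return Object of class `labeled_dataset`: `features` (N x 10 matrix),
#'   `labels` (0/1), `split` (factor train/val/test), `trial_id`,
#'   `frame_idx`, `grip`, `protocol`, and `meta` (tol, floor, seed,
#'   fractions, class counts).
#' @export
assemble_dataset <- function(corpus, fractions = c(0.70, 0.15, 0.15),
                             tol = 0.10, activity_floor = 0.05, seed = 1,
                             split_by = c("frame", "trial"),
                             rest_context = "pinch") {
  stopifnot(inherits(corpus, "training_corpus"))
  split_by <- match.arg(split_by)
  abort_if(!length(corpus$trials), "empty corpus")
  abort_if(abs(sum(fractions) - 1) > 1e-9, "fractions must sum to 1")

  grips <- unique(vapply(Filter(function(tr) tr$protocol == "hold",
                                corpus$trials),
                         function(tr) tr$grip, character(1)))
  pooled <- lapply(setNames(grips, grips), function(g)
    pool_hold_statistics(corpus, g, activity_floor))
  abort_if(!rest_context %in% names(pooled),
           "rest_context grip '%s' has no hold trials", rest_context)

  ids <- names(corpus$trials)
  feat_list <- vector("list", length(ids))
  lab_list <- vector("list", length(ids))
  n_frames <- integer(length(ids))
  grip_v <- character(length(ids))
  prot_v <- character(length(ids))
  for (i in seq_along(ids)) {
    tr <- corpus$trials[[i]]
    stats <- if (tr$protocol == "hold") {
      compute_hold_statistics(tr, activity_floor)
    } else if (tr$protocol == "tap") {
      pooled[[tr$grip]]
    } else {
      pooled[[rest_context]]
    }
    feat_list[[i]] <- trial_features(tr)
    lab_list[[i]] <- label_frames(tr, stats, tol)
    n_frames[i] <- nrow(feat_list[[i]])
    grip_v[i] <- tr$grip
    prot_v[i] <- tr$protocol
  }
  features <- do.call(rbind, feat_list)
  labels <- unlist(lab_list, use.names = FALSE)
  trial_id <- rep(ids, n_frames)
  frame_idx <- unlist(lapply(n_frames, seq_len), use.names = FALSE)
  grip <- rep(grip_v, n_frames)
  protocol <- rep(prot_v, n_frames)
  n <- length(labels)

  split <- with_seed(seed, {
    if (split_by == "frame") {
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      n_te <- n - n_tr - n_va
      sample(rep(c("train", "val", "test"), c(n_tr, n_va, n_te)))
    } else {
      ord <- sample(ids)
      cum <- cumsum(n_frames[match(ord, ids)]) / n
      grp <- cut(cum, c(-Inf, fractions[1], fractions[1] + fractions[2], Inf),
                 labels = c("train", "val", "test"))
      rep(as.character(grp), n_frames[match(ord, ids)])[
        order(rep(match(ord, ids), n_frames[match(ord, ids)]))]
    }
  })
  split <- factor(split, levels = c("train", "val", "test"))

  structure(list(features = features, labels = labels, split = split,
                 trial_id = trial_id, frame_idx = frame_idx,
                 grip = grip, protocol = protocol,
                 meta = list(tol = tol, activity_floor = activity_floor,
                             seed = seed, fractions = fractions,
                             split_by = split_by,
                             v_max = corpus$trials[[1]]$v_max,
                             class_counts = table(labels))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d frames (%d secure / %d insecure)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  print(table(split = x$split))
  invisible(x)
}
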