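#' Write / read a sensor trial as CSV plus JSON sidecar
#'
#' The CSV holds one row per frame (columns `t`, `f1..f5`, `x1..x5`); the
#' sidecar (`<path>.json`) carries the metadata (grip, protocol, hold
#' window, seed, rate, v_max).
#'
#' @param trial A `grasp_trial`.
#' @param path CSV file path.
#' @return `path`, invisibly (`write_trial_csv`); a `grasp_trial`
#'   (`read_trial_csv`).
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "grasp_trial"))
  df <- data.frame(t = trial$t, trial$force, trial$flex)
  write.csv(df, path, row.names = FALSE)
  meta <- list(grip = trial$grip, protocol = trial$protocol,
               hold_window = trial$hold_window, seed = trial$seed,
               rate_hz = trial$rate_hz, v_max = trial$v_max)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  force <- as.matrix(df[paste0("f", 1:5)])
  flex <- as.matrix(df[paste0("x", 1:5)])
  structure(list(grip = meta$grip, protocol = meta$protocol, t = df$t,
                 force = force, flex = flex,
                 hold_window = if (length(meta$hold_window))
                   as.integer(meta$hold_window) else NULL,
                 seed = meta$seed, rate_hz = meta$rate_hz,
                 v_max = meta$v_max),
            class = "grasp_trial")
}

#' Write / read an object trajectory as CSV plus JSON sidecar
#'
#' CSV columns `t`, `X`, `Y`, `Z`; the sidecar carries the target centre,
#' table plane, and protocol tags.
#'
#' @param traj An `object_trajectory`.
#' @param path CSV file path.
#' @return `path`, invisibly (`write_trajectory_csv`); an
#'   `object_trajectory` (`read_trajectory_csv`).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "object_trajectory"))
  df <- data.frame(t = traj$t, X = traj$pos[, 1], Y = traj$pos[, 2],
                   Z = traj$pos[, 3])
  write.csv(df, path, row.names = FALSE)
  meta <- list(target_center = traj$target_center,
               table_plane = traj$table_plane,
               trial_index = traj$trial_index, block = traj$block,
               feedback_mode = traj$feedback_mode, seed = traj$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  object_trajectory(df$t, as.matrix(df[c("X", "Y", "Z")]),
                    target_center = unlist(meta$target_center),
                    table_plane = list(point = unlist(meta$table_plane$point),
                                       normal = unlist(meta$table_plane$normal)),
                    trial_index = meta$trial_index[[1]],
                    block = meta$block[[1]],
                    feedback_mode = meta$feedback_mode[[1]],
                    seed = meta$seed[[1]])
}

#' Write / read a labeled dataset as CSV plus JSON sidecar
#'
#' CSV columns: the 10 voltage features, `label`, `split`, `trial_id`,
#' `frame_idx`, `grip`, `protocol`; the sidecar carries the labeling
#' settings and class counts.
#'
#' @param dataset A `labeled_dataset`.
#' @param path CSV file path.
#' @return `path`, invisibly (`write_dataset_csv`); a `labeled_dataset`
#'   (`read_dataset_csv`).
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- data.frame(dataset$features, label = dataset$labels,
                   split = as.character(dataset$split),
                   trial_id = dataset$trial_id, frame_idx = dataset$frame_idx,
                   grip = dataset$grip, protocol = dataset$protocol)
  write.csv(df, path, row.names = FALSE)
  meta <- dataset$meta
  meta$class_counts <- as.list(setNames(as.integer(meta$class_counts),
                                        names(meta$class_counts)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feat_cols <- c(paste0("f", 1:5), paste0("x", 1:5))
  structure(list(features = as.matrix(df[feat_cols]),
                 labels = df$label,
                 split = factor(df$split, levels = c("train", "val", "test")),
                 trial_id = df$trial_id, frame_idx = df$frame_idx,
                 grip = df$grip, protocol = df$protocol,
                 meta = meta),
            class = "labeled_dataset")
}

#' Write / read a trained network model as JSON
#'
#' Serializes weights, input scaling, configuration and the training trace.
#'
#' @param model An `ann_model`.
#' @param path JSON file path.
#' @return `path`, invisibly (`write_ann_json`); an `ann_model`
#'   (`read_ann_json`).
#' @export
write_ann_json <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(n_in = nrow(model$W1), W1 = as.vector(model$W1),
              b1 = model$b1, W2 = model$W2, b2 = model$b2,
              xmin = model$xmin, xmax = model$xmax,
              config = unclass(model$config), trace = model$trace,
              stop_iter = model$stop_iter, stop_reason = model$stop_reason,
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ann_json
#' @export
read_ann_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W1 <- matrix(obj$W1, nrow = obj$n_in)
  cfg <- do.call(ann_config, obj$config[c("hidden", "sigma", "lambda0",
                                          "max_iter", "max_fail", "init",
                                          "init_range", "eps", "grad_tol")])
  ann_model(W1, obj$b1, obj$W2, obj$b2, obj$xmin, obj$xmax, cfg,
            trace = if (!is.null(obj$trace)) as.data.frame(obj$trace) else NULL,
            stop_iter = obj$stop_iter, stop_reason = obj$stop_reason,
            seed = obj$seed)
}
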