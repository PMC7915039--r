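#' Training configuration for the secure-grasp network
#'
#' The detector is a feedforward network with one hidden layer of 10 tanh
#' units and a logistic output, trained by scaled conjugate gradients
#' (conjugate directions with a Levenberg-Marquardt scaling parameter in
#' place of a line search; Hessian-vector products approximated by forward
#' differencing of the gradient). The objective is mean binary
#' cross-entropy in natural log. Early stopping monitors the validation
#' split and returns the best-validation weights.
#'
#' @param hidden Hidden-layer size (the study network uses 10).
#' @param sigma Finite-difference step scale for the Hessian-vector
#'   approximation.
#' @param lambda0 Initial Levenberg-Marquardt scale.
#' @param max_iter Maximum optimizer iterations.
#' @param max_fail Consecutive validation-CE non-improvements tolerated
#'   before stopping.
#' @param init `"uniform"` (seeded uniform in `[-init_range, init_range]`)
#'   or `"layer"` (the same, scaled by `1/sqrt(fan-in)` per layer).
#' @param init_range Half-width of the uniform weight initialization.
#' @param eps Probability clamp used inside the cross-entropy.
#' @param grad_tol Gradient-norm convergence threshold.
#' @return List of class `ann_config`.
#' @export
ann_config <- function(hidden = 10, sigma = 5e-5, lambda0 = 5e-7,
                       max_iter = 1000, max_fail = 6,
                       init = c("uniform", "layer"), init_range = 0.5,
                       eps = 1e-12, grad_tol = 1e-8) {
  structure(list(hidden = hidden, sigma = sigma, lambda0 = lambda0,
                 max_iter = max_iter, max_fail = max_fail,
                 init = match.arg(init), init_range = init_range,
                 eps = eps, grad_tol = grad_tol),
            class = "ann_config")
}

# ---- weight packing -------------------------------------------------------

pack_weights <- function(W1, b1, W2, b2) c(as.vector(W1), b1, W2, b2)

unpack_weights <- function(w, n_in, n_hid) {
  i <- n_in * n_hid
  list(W1 = matrix(w[1:i], n_in, n_hid),
       b1 = w[(i + 1):(i + n_hid)],
       W2 = w[(i + n_hid + 1):(i + 2 * n_hid)],
       b2 = w[i + 2 * n_hid + 1])
}

ann_forward <- function(wts, X) {
  Z <- tanh(sweep(X %*% wts$W1, 2, wts$b1, "+"))
  list(Z = Z, yhat = plogis(drop(Z %*% wts$W2) + wts$b2))
}

#' Mean binary cross-entropy (natural log)
#'
#' @param yhat Predicted probabilities in `[0, 1]`.
#' @param y Binary targets.
#' @param eps Probability clamp.
#' @return Mean cross-entropy in nats.
#' @export
cross_entropy <- function(yhat, y, eps = 1e-12) {
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

# loss and gradient of mean binary CE wrt packed weights
ann_loss_grad <- function(w, X, y, n_in, n_hid, eps = 1e-12,
                          want_grad = TRUE) {
  wts <- unpack_weights(w, n_in, n_hid)
  fw <- ann_forward(wts, X)
  loss <- cross_entropy(fw$yhat, y, eps)
  if (!want_grad) return(list(loss = loss))
  n <- length(y)
  d <- (fw$yhat - y) / n                     # dCE/dlogit for logistic + CE
  gW2 <- drop(crossprod(fw$Z, d))
  gb2 <- sum(d)
  dZ <- (d %o% wts$W2) * (1 - fw$Z^2)
  gW1 <- crossprod(X, dZ)
  gb1 <- colSums(dZ)
  list(loss = loss, grad = pack_weights(gW1, gb1, gW2, gb2))
}

scale_features <- function(X, xmin, xmax) {
  rng <- xmax - xmin
  Xs <- sweep(sweep(X, 2, xmin), 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  Xs[, rng <= 0] <- 0
  Xs
}

#' Construct a secure-grasp network model from explicit weights
#'
#' Mainly for tests and deserialization; [train_ann()] is the usual entry
#' point. With the default scaling (`xmin = -1`, `xmax = 1`) inputs pass
#' through unchanged.
#'
#' @param W1 Input-to-hidden weight matrix (n_in x n_hidden).
#' @param b1 Hidden biases.
#' @param W2 Hidden-to-output weights.
#' @param b2 Output bias (scalar).
#' @param xmin,xmax Per-channel affine input scaling onto `[-1, 1]`.
#' @param config An [ann_config()].
#' @param trace Optional training trace.
#' @param stop_iter,stop_reason,seed Training bookkeeping.
#' @return Object of class `ann_model`.
#' @export
ann_model <- function(W1, b1, W2, b2,
                      xmin = rep(-1, nrow(W1)), xmax = rep(1, nrow(W1)),
                      config = ann_config(hidden = length(b1)),
                      trace = NULL, stop_iter = NA_integer_,
                      stop_reason = NA_character_, seed = NA) {
  W1 <- as.matrix(W1)
  abort_if(length(b1) != ncol(W1) || length(W2) != length(b1) ||
             length(b2) != 1, "inconsistent weight shapes")
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 xmin = xmin, xmax = xmax, config = config,
                 trace = trace, stop_iter = stop_iter,
                 stop_reason = stop_reason, seed = seed),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d-%d-1 (tanh / logistic)", nrow(x$W1), ncol(x$W1)))
  if (!is.na(x$stop_iter)) {
    cat(sprintf("; stopped at iteration %d (%s)", x$stop_iter, x$stop_reason))
  }
  cat("\n")
  invisible(x)
}

#' Train the secure-grasp network by scaled conjugate gradients
#'
#' Minimizes mean binary cross-entropy on the training split with early
#' stopping on the validation split. Training cross-entropy is
#' non-increasing over successful iterations (rejected steps leave the
#' weights unchanged and only inflate the scaling parameter), and the
#' returned weights are those with the lowest validation cross-entropy
#' seen.
#'
#' @param dataset A `labeled_dataset` (both classes must be present in the
#'   training split).
#' @param config An [ann_config()].
#' @param seed Weight-initialization seed.
#' @return An [ann_model()] carrying the per-iteration train/val/test
#'   cross-entropy trace, the stop iteration and the stop reason.
#' @export
train_ann <- function(dataset, config = ann_config(), seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tr <- dataset$split == "train"
  va <- dataset$split == "val"
  te <- dataset$split == "test"
  y_tr <- dataset$labels[tr]
  abort_if(length(unique(y_tr)) < 2,
           "training split contains a single class; cannot train")

  n_in <- ncol(dataset$features)
  n_hid <- config$hidden
  xmin <- apply(dataset$features[tr, , drop = FALSE], 2, min)
  xmax <- apply(dataset$features[tr, , drop = FALSE], 2, max)
  X_tr <- scale_features(dataset$features[tr, , drop = FALSE], xmin, xmax)
  X_va <- scale_features(dataset$features[va, , drop = FALSE], xmin, xmax)
  X_te <- scale_features(dataset$features[te, , drop = FALSE], xmin, xmax)
  y_va <- dataset$labels[va]
  y_te <- dataset$labels[te]

  w <- with_seed(seed, {
    nw <- n_in * n_hid + n_hid + n_hid + 1
    w0 <- runif(nw, -config$init_range, config$init_range)
    if (config$init == "layer") {
      sc <- pack_weights(matrix(1 / sqrt(n_in), n_in, n_hid),
                         rep(1, n_hid), rep(1 / sqrt(n_hid), n_hid), 1)
      w0 <- w0 * sc
    }
    w0
  })

  loss_at <- function(w) ann_loss_grad(w, X_tr, y_tr, n_in, n_hid,
                                       config$eps, want_grad = FALSE)$loss
  grad_at <- function(w) ann_loss_grad(w, X_tr, y_tr, n_in, n_hid,
                                       config$eps)$grad
  side_ce <- function(w) {
    wts <- unpack_weights(w, n_in, n_hid)
    c(val = if (length(y_va)) cross_entropy(ann_forward(wts, X_va)$yhat,
                                            y_va, config$eps) else NA_real_,
      test = if (length(y_te)) cross_entropy(ann_forward(wts, X_te)$yhat,
                                             y_te, config$eps) else NA_real_)
  }

  # ---- Moller's scaled conjugate gradient ---------------------------------
  E_w <- loss_at(w)
  abort_if(!is.finite(E_w), "non-finite initial loss")
  g <- grad_at(w)
  r <- -g
  p <- r
  lambda <- config$lambda0
  lambda_bar <- 0
  success <- TRUE
  nw <- length(w)
  delta <- 0
  norm_p2 <- sum(p^2)

  sc0 <- side_ce(w)
  trace <- list(data.frame(iter = 0L, ce_train = E_w,
                           ce_val = sc0[["val"]], ce_test = sc0[["test"]]))
  best_val <- sc0[["val"]]
  best_w <- w
  n_fail <- 0L
  stop_reason <- "max_iter"
  stop_iter <- config$max_iter

  k <- 0L
  while (k < config$max_iter) {
    k <- k + 1L
    if (success) {
      norm_p2 <- sum(p^2)
      norm_p <- sqrt(norm_p2)
      if (norm_p < config$grad_tol) {
        stop_reason <- "gradient_converged"; stop_iter <- k; break
      }
      sigma_k <- config$sigma / norm_p
      s <- (grad_at(w + sigma_k * p) - g) / sigma_k
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * norm_p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / norm_p2)
      delta <- -delta + lambda * norm_p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    E_new <- loss_at(w + alpha * p)
    abort_if(!is.finite(E_new), "non-finite loss at iteration %d", k)
    Delta <- 2 * delta * (E_w - E_new) / mu^2

    if (Delta >= 0) {                        # successful step
      w <- w + alpha * p
      E_w <- E_new
      g <- grad_at(w)
      r_new <- -g
      lambda_bar <- 0
      success <- TRUE
      if (k %% nw == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4

      sc <- side_ce(w)
      trace[[length(trace) + 1L]] <-
        data.frame(iter = k, ce_train = E_w,
                   ce_val = sc[["val"]], ce_test = sc[["test"]])
      if (!is.na(sc[["val"]])) {
        if (sc[["val"]] < best_val) {
          best_val <- sc[["val"]]; best_w <- w; n_fail <- 0L
        } else {
          n_fail <- n_fail + 1L
          if (n_fail >= config$max_fail) {
            stop_reason <- "early_stop"; stop_iter <- k; break
          }
        }
      } else {
        best_w <- w                           # no validation split
      }
      if (sqrt(sum(r^2)) < config$grad_tol) {
        stop_reason <- "gradient_converged"; stop_iter <- k; break
      }
    } else {                                  # step rejected
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / norm_p2
    if (!is.finite(lambda) || lambda > 1e100) {
      stop_reason <- "lambda_overflow"; stop_iter <- k; break
    }
  }
  if (stop_reason == "max_iter") stop_iter <- k

  wts <- unpack_weights(best_w, n_in, n_hid)
  ann_model(wts$W1, wts$b1, wts$W2, wts$b2, xmin, xmax, config,
            trace = do.call(rbind, trace), stop_iter = stop_iter,
            stop_reason = stop_reason, seed = seed)
}

#' Predict secure-grasp probability for sensor frames
#'
#' Deterministic forward pass through the stored input scaling and weights.
#'
#' @param object An `ann_model`.
#' @param newdata Numeric vector of 10 channel voltages, or an n x 10
#'   matrix of frames.
#' @param ... Ignored.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  abort_if(ncol(newdata) != nrow(object$W1),
           "expected %d features, got %d", nrow(object$W1), ncol(newdata))
  abort_if(any(!is.finite(newdata)), "features must be finite")
  Xs <- scale_features(newdata, object$xmin, object$xmax)
  ann_forward(object[c("W1", "b1", "W2", "b2")], Xs)$yhat
}

#' Round continuous network output to a secure/insecure decision
#'
#' Outputs strictly greater than 0.5 round to secure (1); everything else,
#' including exactly 0.5, rounds to insecure (0) — the conservative choice
#' for feedback triggering.
#'
#' @param y Probabilities in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
round_output <- function(y) {
  abort_if(any(y < 0 | y > 1), "outputs must lie in [0, 1]")
  as.integer(y > 0.5)
}

#' Analytical pinch force-equilibrium secure-grasp detector
#'
#' Voltage-cancellation baseline for precision pinch: a frame is secure iff
#' the index and thumb force voltages are both sufficiently non-zero
#' (greater than `floor * v_max`) and sufficiently equal (within `rel_tol`
#' of each other, relative to the larger of the two).
#'
#' @param frames Numeric vector of 10 channel voltages or an n x 10 matrix
#'   (columns f1..f5 force thumb..little, then x1..x5 flex).
#' @param rel_tol Relative force-balance tolerance (default 0.10).
#' @param floor Minimum voltage as a fraction of `v_max` (default 0.10).
#' @param v_max Sensor saturation voltage (V).
#' @return Integer 0/1 vector, one per frame.
#' @export
analytical_pinch_detect <- function(frames, rel_tol = 0.10, floor = 0.10,
                                    v_max = 3.3) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1)
  v_thumb <- frames[, 1]
  v_index <- frames[, 2]
  hi <- pmax(v_index, v_thumb)
  as.integer(v_index > floor * v_max & v_thumb > floor * v_max &
               abs(v_index - v_thumb) <= rel_tol * hi)
}

#' Evaluate a trained detector on a labeled dataset
#'
#' Computes, per split: mean cross-entropy (nats), percent classification
#' error after rounding, mean squared error of the continuous output, and
#' mean squared error of the rounded output. On the grip-stratified secure
#' test frames it computes the true-positive rate of the network and of
#' the analytical pinch detector (the analytical rule is also applied to
#' the other grips to show where voltage cancellation breaks down).
#'
#' @param model A trained `ann_model`.
#' @param dataset The `labeled_dataset` the model was trained on.
#' @return Object of class `evaluation_report`: `split_metrics`
#'   (data.frame), `tp` (data.frame grip / n_secure / ann_tp /
#'   analytical_tp, rates in percent), `flagged` (grips with no secure
#'   test frames).
#' @export
evaluate_ann <- function(model, dataset) {
  stopifnot(inherits(model, "ann_model"), inherits(dataset, "labeled_dataset"))
  eps <- model$config$eps
  split_metrics <- do.call(rbind, lapply(c("train", "val", "test"), function(s) {
    idx <- dataset$split == s
    y <- dataset$labels[idx]
    yhat <- predict(model, dataset$features[idx, , drop = FALSE])
    yr <- round_output(yhat)
    data.frame(split = s,
               ce = cross_entropy(yhat, y, eps),
               pe = 100 * mean(yr != y),
               mse_continuous = mean((yhat - y)^2),
               mse_rounded = mean((yr - y)^2))
  }))

  v_max <- dataset$meta$v_max
  if (is.null(v_max)) v_max <- 3.3
  grips <- setdiff(unique(dataset$grip), "none")
  flagged <- character(0)
  tp <- do.call(rbind, lapply(grips, function(g) {
    idx <- dataset$split == "test" & dataset$grip == g & dataset$labels == 1
    n <- sum(idx)
    if (n == 0) {
      flagged <<- c(flagged, g)
      return(data.frame(grip = g, n_secure = 0L,
                        ann_tp = NA_real_, analytical_tp = NA_real_))
    }
    feats <- dataset$features[idx, , drop = FALSE]
    data.frame(grip = g, n_secure = n,
               ann_tp = 100 * mean(round_output(predict(model, feats)) == 1),
               analytical_tp = 100 * mean(
                 analytical_pinch_detect(feats, v_max = v_max) == 1))
  }))

  structure(list(split_metrics = split_metrics, tp = tp, flagged = flagged),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(transform(x$split_metrics,
                  ce = signif(ce, 4), pe = signif(pe, 4),
                  mse_continuous = signif(mse_continuous, 4),
                  mse_rounded = signif(mse_rounded, 4)), row.names = FALSE)
  cat("true-positive rates (%), test split:\n")
  print(transform(x$tp, ann_tp = signif(ann_tp, 4),
                  analytical_tp = signif(analytical_tp, 4)),
        row.names = FALSE)
  if (length(x$flagged)) {
    cat("flagged (no secure test frames):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
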