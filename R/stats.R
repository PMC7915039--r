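#' Per-subject block series of one performance metric
#'
#' Holds one subject's per-trial metric values for the pre-training,
#' training, and post-training blocks of one session. The session design
#' uses 15/30/15 trials; shorter series are accepted for desk-scale use.
#'
#' @param pre,training,post Numeric per-trial values (finite, >= 0 expected
#'   for the raw metrics).
#' @param subject,feedback_mode,metric Optional labels.
#' @return Object of class `block_series`.
#' @export
block_series <- function(pre, training, post, subject = NA,
                         feedback_mode = NA, metric = NA) {
  abort_if(!length(pre), "pre block must be non-empty")
  vals <- c(pre, training, post)
  abort_if(any(!is.finite(vals)), "block values must be finite")
  structure(list(pre = pre, training = training, post = post,
                 subject = subject, feedback_mode = feedback_mode,
                 metric = metric, normalized = FALSE, pre_mean = NA_real_),
            class = "block_series")
}

#' Intra-subject normalization by the pre-training mean
#'
#' Divides every value in all three blocks by the subject's pre-training
#' block mean, removing inter-subject baseline differences before pooling.
#' The pre block is normalized too (its normalized mean is exactly 1) so
#' all blocks share one scale; set `include_pre = FALSE` to normalize only
#' the training and post blocks.
#'
#' @param series A [block_series()].
#' @param include_pre Normalize the pre block as well (default `TRUE`).
#' @return A normalized `block_series` (with `pre_mean` recorded).
#' @export
normalize_subject <- function(series, include_pre = TRUE) {
  stopifnot(inherits(series, "block_series"))
  m <- mean(series$pre)
  abort_if(!is.finite(m) || m <= 0,
           "pre-block mean must be positive (got %g)", m)
  out <- series
  if (include_pre) out$pre <- series$pre / m
  out$training <- series$training / m
  out$post <- series$post / m
  out$normalized <- TRUE
  out$pre_mean <- m
  out
}

#' De-normalize to real-world units with the group pre-training mean
#'
#' @param x Normalized values.
#' @param group_pre_mean Group mean pre-training value of the metric (> 0).
#' @return Values in metric units.
#' @export
denormalize_group <- function(x, group_pre_mean) {
  abort_if(group_pre_mean <= 0, "group pre-training mean must be > 0")
  x * group_pre_mean
}

#' Intra-training rate (regression slope across training trials)
#'
#' Ordinary-least-squares slope of the metric on sequential trial number
#' across the training block. A negative slope is the desirable outcome
#' (the metric declines with practice).
#'
#' @param values Per-trial metric values in trial order.
#' @return Slope in metric units per trial.
#' @export
intra_training_rate <- function(values) {
  abort_if(length(values) < 2, "need at least 2 trials for a slope")
  k <- seq_along(values)
  unname(lm.fit(cbind(1, k), values)$coefficients[2])
}

#' Post-training effect (post mean minus pre mean)
#'
#' Change in the block-mean metric from pre-training to the post-training
#' retention block; negative is improvement. (The block-difference tables
#' report the opposite orientation, pre minus post, which is labeled where
#' used.)
#'
#' @param pre,post Per-trial values of the two blocks.
#' @return Difference in metric units.
#' @export
post_training_effect <- function(pre, post) {
  abort_if(!length(pre) || !length(post), "both blocks must be non-empty")
  mean(post) - mean(pre)
}

#' One-factor repeated-measures ANOVA
#'
#' Within-subject ANOVA with subject as the blocking factor, fitted with
#' `stats::aov` and an `Error(subject)` stratum (sphericity assumed).
#' Pairwise condition differences use the pooled within-subject error term:
#' standard error `sqrt(2 * MS_error / n)` and Tukey studentized-range
#' post hoc p-values.
#'
#' @param values Numeric responses, one per subject x condition cell.
#' @param subject Subject identifier per value.
#' @param condition Condition (e.g. trial-block) per value.
#' @return List of class `rm_anova`: `F`, `p`, `df`, `ms_error`,
#'   `df_error`, `n_subjects`, `means`, `pairwise` (data.frame with
#'   level1, level2, `diff` = mean(level1) - mean(level2), `se`,
#'   `p_tukey`), `degenerate`.
#' @export
rm_anova <- function(values, subject, condition) {
  subject <- factor(subject)
  condition <- factor(condition)
  tab <- table(subject, condition)
  abort_if(any(tab != 1),
           "design must be balanced with one value per subject x condition cell")
  n <- nlevels(subject)
  k <- nlevels(condition)
  abort_if(k < 2 || n < 2, "need >= 2 subjects and >= 2 conditions")

  fit <- aov(values ~ condition + Error(subject))
  within <- summary(fit)[["Error: Within"]][[1]]
  F_stat <- within["condition", "F value"]
  p <- within["condition", "Pr(>F)"]
  ms_error <- within["Residuals", "Mean Sq"]
  df_error <- within["Residuals", "Df"]
  ss_cond <- within["condition", "Sum Sq"]
  ss_err <- within["Residuals", "Sum Sq"]
  scale <- sum(values^2) + 1e-300
  degenerate <- !is.finite(F_stat) || ss_err <= 1e-12 * scale
  if (degenerate) {                          # error stratum numerically empty
    if (ss_cond <= 1e-12 * scale) {
      F_stat <- 0; p <- 1
    } else {
      F_stat <- Inf; p <- 0
    }
    ms_error <- 0
  }

  means <- tapply(values, condition, mean)
  pairs <- t(combn(levels(condition), 2))
  diff <- means[pairs[, 1]] - means[pairs[, 2]]
  se <- sqrt(2 * ms_error / n)
  q <- abs(diff) / sqrt(ms_error / n)
  p_tukey <- if (degenerate || ms_error <= 0) rep(NA_real_, nrow(pairs)) else
    ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)

  structure(list(F = F_stat, p = p, df = c(k - 1, df_error),
                 ms_error = ms_error, df_error = df_error,
                 n_subjects = n, means = means,
                 pairwise = data.frame(level1 = pairs[, 1],
                                       level2 = pairs[, 2],
                                       diff = unname(diff), se = se,
                                       p_tukey = unname(p_tukey)),
                 degenerate = degenerate),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df[1], x$df[2], x$F, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' One-way (between-groups) ANOVA
#'
#' Standard between/within sums-of-squares decomposition via
#' `stats::oneway.test` with equal variances.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @return List: `F`, `p`, `df`, `means`, `degenerate` (TRUE when both the
#'   between- and within-group variances are exactly zero).
#' @export
oneway_anova <- function(groups) {
  abort_if(length(groups) < 2, "need at least 2 groups")
  abort_if(any(lengths(groups) < 2), "each group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  ss_between <- sum(lengths(groups) * (means - mean(y))^2)
  if (ss_within == 0 && ss_between == 0) {
    return(list(F = NA_real_, p = NA_real_,
                df = c(length(groups) - 1, length(y) - length(groups)),
                means = means, degenerate = TRUE))
  }
  if (ss_within == 0) {
    return(list(F = Inf, p = 0,
                df = c(length(groups) - 1, length(y) - length(groups)),
                means = means, degenerate = TRUE))
  }
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter), means = means, degenerate = FALSE)
}

#' Tukey HSD post hoc comparisons with optional Bonferroni scaling
#'
#' Pairwise honest-significant-difference p-values from the studentized
#' range distribution (via `stats::TukeyHSD`), optionally multiplied by the
#' number of metric families tested (capped at 1) when several families of
#' comparisons are run.
#'
#' @param groups List of numeric vectors.
#' @param bonferroni_families Number of families; 1 leaves the Tukey
#'   p-values unchanged.
#' @return data.frame: `pair`, `diff`, `p_tukey`, `p_adjusted`.
#' @export
tukey_posthoc <- function(groups, bonferroni_families = 1) {
  abort_if(length(groups) < 2, "need at least 2 groups")
  abort_if(bonferroni_families < 1, "bonferroni_families must be >= 1")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  th <- TukeyHSD(aov(y ~ g))$g
  data.frame(pair = rownames(th), diff = th[, "diff"],
             p_tukey = th[, "p adj"],
             p_adjusted = pmin(1, th[, "p adj"] * bonferroni_families),
             row.names = NULL)
}

#' One-sample t-test against a reference value
#'
#' Two-sided Student t-test of the sample mean against `mu`. Zero-variance
#' input is flagged rather than tested.
#'
#' @param values Numeric sample (n >= 2).
#' @param mu Reference value (default 0).
#' @return List: `t`, `df`, `p`, `mean`, `degenerate`.
#' @export
one_sample_ttest <- function(values, mu = 0) {
  abort_if(length(values) < 2, "need at least 2 values")
  if (sd(values) <= 1e-12 * max(abs(values), 1)) {
    return(list(t = NA_real_, df = length(values) - 1, p = NA_real_,
                mean = mean(values), degenerate = TRUE))
  }
  tt <- tryCatch(t.test(values, mu = mu), error = function(e) NULL)
  if (is.null(tt)) {                         # (essentially) zero variance
    return(list(t = NA_real_, df = length(values) - 1, p = NA_real_,
                mean = mean(values), degenerate = TRUE))
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(values), degenerate = FALSE)
}

#' Two-sample t-test
#'
#' Two-sided pooled-variance (Student) t-test of two independent samples.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return List: `t`, `df`, `p`, `means`, `degenerate`.
#' @export
two_sample_ttest <- function(a, b) {
  abort_if(length(a) < 2 || length(b) < 2, "need at least 2 values per sample")
  if (sd(c(a - mean(a), b - mean(b))) <= 1e-12 * max(abs(c(a, b)), 1)) {
    return(list(t = if (isTRUE(all.equal(mean(a), mean(b)))) 0 else NA_real_,
                df = length(a) + length(b) - 2, p = NA_real_,
                means = c(mean(a), mean(b)), degenerate = TRUE))
  }
  tt <- tryCatch(t.test(a, b, var.equal = TRUE), error = function(e) NULL)
  if (is.null(tt)) {                         # (essentially) zero variance
    return(list(t = if (mean(a) == mean(b)) 0 else NA_real_,
                df = length(a) + length(b) - 2, p = NA_real_,
                means = c(mean(a), mean(b)), degenerate = TRUE))
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       means = c(mean(a), mean(b)), degenerate = FALSE)
}
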