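#' Full outcome and statistics report for a scored study
#'
#' Runs the complete analysis battery on a per-trial metrics table:
#' \enumerate{
#'   \item intra-subject normalization of each metric by the subject's
#'     session pre-training mean, then de-normalization to real-world units
#'     with the group pre-training mean;
#'   \item per subject / mode / metric outcome measures: the intra-training
#'     rate (OLS slope across the 30 training trials) and the post-training
#'     effect (post mean minus pre mean) — negative is improvement for both;
#'   \item repeated-measures ANOVA per metric on the de-normalized block
#'     means across the mode-by-block cells, with within-mode pairwise
#'     block differences (reported in the pre-minus-later orientation used
#'     by the block-difference tables) and Tukey post hoc p-values from the
#'     pooled error term;
#'   \item one-way ANOVA across feedback modes for each outcome and metric,
#'     with Tukey HSD post hoc (optionally Bonferroni-scaled across metric
#'     families);
#'   \item one-sample t-tests of each outcome against zero per mode and
#'     metric.
#' }
#'
#' @param metrics data.frame with columns `subject`, `feedback_mode`,
#'   `block`, `trial`, `time_s`, `path_m`, `error_m` (e.g. the `trials`
#'   table of a [generate_study()] result, or the output of
#'   [score_study()]).
#' @param bonferroni_families Family count for the Tukey post hoc scaling
#'   (default 1 = plain Tukey).
#' @param include_pre Normalize the pre block too (default `TRUE`; set
#'   `FALSE` for the literal convention in which only training and post
#'   values are normalized).
#' @return Object of class `stats_report` with elements
#'   `group_pre_means`, `block_means`, `rm` (per metric: `rm_anova` fit and
#'   the within-mode pairwise table), `outcomes` (per subject/mode/metric
#'   slopes and effects), `outcome_anova`, `outcome_posthoc`,
#'   `one_sample`, `settings`.
#' @export
build_report <- function(metrics, bonferroni_families = 1,
                         include_pre = TRUE) {
  need <- c("subject", "feedback_mode", "block", "trial",
            "time_s", "path_m", "error_m")
  abort_if(!all(need %in% names(metrics)),
           "metrics table must have columns: %s", paste(need, collapse = ", "))
  blocks_ord <- c("pre", "training", "post")
  modes <- intersect(c("NF", "IF", "IBF"), unique(metrics$feedback_mode))
  abort_if(!all(metrics$block %in% blocks_ord), "unknown block labels")
  sm_key <- paste(metrics$subject, metrics$feedback_mode, sep = "|")
  for (key in unique(sm_key)) {
    have <- unique(metrics$block[sm_key == key])
    abort_if(!all(blocks_ord %in% have),
             "incomplete study: session %s is missing a block", key)
  }
  metric_names <- c("time_s", "path_m", "error_m")

  group_pre_means <- vapply(metric_names, function(m)
    mean(metrics[[m]][metrics$block == "pre"]), numeric(1))

  rm_list <- list()
  block_means_all <- list()
  outcome_rows <- list()

  for (m in metric_names) {
    x <- metrics[[m]]
    gpm <- group_pre_means[[m]]
    pre_mean_sub <- tapply(x[metrics$block == "pre"],
                           sm_key[metrics$block == "pre"], mean)
    abort_if(any(pre_mean_sub <= 0),
             "non-positive subject pre-training mean for %s", m)
    f <- gpm / pre_mean_sub[sm_key]
    denorm <- x * ifelse(metrics$block == "pre" & !include_pre, 1, f)

    d <- data.frame(subject = metrics$subject,
                    feedback_mode = metrics$feedback_mode,
                    block = metrics$block, y = denorm)
    bm <- aggregate(y ~ subject + feedback_mode + block, d, mean)
    lv <- as.vector(t(outer(modes, blocks_ord, paste, sep = ".")))
    cell <- factor(paste(bm$feedback_mode, bm$block, sep = "."), levels = lv)
    fit <- rm_anova(bm$y, bm$subject, cell)

    pw <- fit$pairwise
    parts1 <- strsplit(pw$level1, ".", fixed = TRUE)
    parts2 <- strsplit(pw$level2, ".", fixed = TRUE)
    same_mode <- vapply(seq_len(nrow(pw)), function(i)
      parts1[[i]][1] == parts2[[i]][1], logical(1))
    within_mode <- pw[same_mode, ]
    within_mode$feedback_mode <- vapply(parts1[same_mode], `[`, "", 1)
    within_mode$block1 <- vapply(parts1[same_mode], `[`, "", 2)
    within_mode$block2 <- vapply(parts2[same_mode], `[`, "", 2)
    within_mode <- within_mode[, c("feedback_mode", "block1", "block2",
                                   "diff", "se", "p_tukey")]
    rownames(within_mode) <- NULL

    rm_list[[m]] <- list(fit = fit, block_pairs = within_mode)
    bm$metric <- m
    block_means_all[[m]] <- bm

    # per-session outcomes on the normalized scale, de-normalized at the end
    for (key in unique(sm_key)) {
      rows <- sm_key == key
      pre_m <- pre_mean_sub[[key]]
      tr_rows <- rows & metrics$block == "training"
      ord <- order(metrics$trial[tr_rows])
      slope_norm <- intra_training_rate((x[tr_rows] / pre_m)[ord])
      delta_norm <- post_training_effect(x[rows & metrics$block == "pre"] / pre_m,
                                         x[rows & metrics$block == "post"] / pre_m)
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      outcome_rows[[length(outcome_rows) + 1L]] <-
        data.frame(subject = parts[1], feedback_mode = parts[2], metric = m,
                   intra_training_rate = denormalize_group(slope_norm, gpm),
                   post_training_effect = denormalize_group(delta_norm, gpm))
    }
  }
  outcomes <- do.call(rbind, outcome_rows)

  outcome_names <- c("intra_training_rate", "post_training_effect")
  anova_rows <- list()
  posthoc_rows <- list()
  one_sample_rows <- list()
  for (m in metric_names) {
    for (oc in outcome_names) {
      sub <- outcomes[outcomes$metric == m, ]
      groups <- split(sub[[oc]], factor(sub$feedback_mode, levels = modes))
      ow <- oneway_anova(groups)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        metric = m, outcome = oc, F = ow$F, p = ow$p,
        t(setNames(ow$means, paste0("mean_", names(ow$means)))),
        degenerate = ow$degenerate)
      if (!ow$degenerate) {
        tk <- tukey_posthoc(groups, bonferroni_families)
        tk$metric <- m
        tk$outcome <- oc
        posthoc_rows[[length(posthoc_rows) + 1L]] <- tk
      }
      for (md in modes) {
        tt <- one_sample_ttest(groups[[md]])
        one_sample_rows[[length(one_sample_rows) + 1L]] <- data.frame(
          metric = m, outcome = oc, feedback_mode = md,
          mean = tt$mean, t = tt$t, p = tt$p, degenerate = tt$degenerate)
      }
    }
  }

  structure(list(group_pre_means = group_pre_means,
                 block_means = do.call(rbind, block_means_all),
                 rm = rm_list,
                 outcomes = outcomes,
                 outcome_anova = do.call(rbind, anova_rows),
                 outcome_posthoc = if (length(posthoc_rows))
                   do.call(rbind, posthoc_rows) else NULL,
                 one_sample = do.call(rbind, one_sample_rows),
                 settings = list(bonferroni_families = bonferroni_families,
                                 include_pre = include_pre, modes = modes)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report>\n")
  cat("group pre-training means:",
      sprintf("%s = %.4g", names(x$group_pre_means), x$group_pre_means),
      "\n")
  cat("\nrepeated-measures ANOVA (mode x block cells within subject):\n")
  for (m in names(x$rm)) {
    f <- x$rm[[m]]$fit
    cat(sprintf("  %-8s F(%d, %d) = %.4g, p = %.4g%s\n", m,
                f$df[1], f$df[2], f$F, f$p,
                if (f$degenerate) " [degenerate]" else ""))
  }
  cat("\none-way ANOVA on outcomes across feedback modes:\n")
  oa <- x$outcome_anova
  oa$F <- signif(oa$F, 4); oa$p <- signif(oa$p, 4)
  print(oa, row.names = FALSE)
  cat("\none-sample t-tests of outcomes against zero:\n")
  os <- x$one_sample
  os$mean <- signif(os$mean, 4); os$t <- signif(os$t, 4)
  os$p <- signif(os$p, 4)
  print(os, row.names = FALSE)
  invisible(x)
}
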