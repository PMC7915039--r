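test_that("intra-subject normalization divides by the pre-block mean", {
  bs <- block_series(pre = rep(2, 15), training = rep(2, 30), post = rep(2, 15))
  nb <- normalize_subject(bs)
  expect_true(all(c(nb$pre, nb$training, nb$post) == 1))

  bs2 <- block_series(pre = c(1.5, 2.5), training = c(1.5), post = c(2))
  nb2 <- normalize_subject(bs2)
  expect_equal(nb2$training, 0.75)           # 1.5 / pre mean 2.0
  expect_equal(mean(nb2$pre), 1)             # by construction

  expect_error(normalize_subject(block_series(pre = c(0, 0), training = 1,
                                              post = 1)), "positive")
})

test_that("normalize / de-normalize round-trips exactly", {
  set.seed(42)
  for (i in 1:20) {
    bs <- block_series(pre = runif(15, 0.5, 3), training = runif(30, 0.5, 3),
                       post = runif(15, 0.5, 3))
    nb <- normalize_subject(bs)
    expect_equal(denormalize_group(nb$training, nb$pre_mean), bs$training,
                 tolerance = 1e-12)
    expect_equal(denormalize_group(nb$pre, nb$pre_mean), bs$pre,
                 tolerance = 1e-12)
  }
  expect_equal(denormalize_group(1, 1.48), 1.48)
  expect_equal(denormalize_group(0.9, 0.25), 0.225)
})

test_that("the de-normalized group pre-training mean equals the raw one", {
  set.seed(11)
  subjects <- lapply(1:17, function(i) runif(15, 0.5, 3) * runif(1, 0.5, 2))
  group_pre <- mean(unlist(subjects))
  denorm <- unlist(lapply(subjects, function(p)
    denormalize_group(p / mean(p), group_pre)))
  expect_equal(mean(denorm), group_pre, tolerance = 1e-12)
})

test_that("the intra-training rate is the OLS slope on trial number", {
  expect_equal(intra_training_rate(rep(3, 30)), 0)
  k <- 1:30
  expect_equal(intra_training_rate(2.0 - 0.01 * k), -0.01, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    y <- rnorm(30)
    expect_equal(intra_training_rate(y), oracle_slope(y), tolerance = 1e-12)
  }
  expect_error(intra_training_rate(1), "2 trials")
})

test_that("the post-training effect is the block-mean difference", {
  expect_equal(post_training_effect(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(post_training_effect(rep(1.50, 15), rep(1.41, 15)), -0.09,
               tolerance = 1e-12)
  set.seed(2)
  pre <- runif(15); post <- runif(15)
  expect_equal(post_training_effect(pre, post),
               post_training_effect(sample(pre), sample(post)))
})

test_that("repeated-measures ANOVA matches hand-partitioned sums of squares", {
  # 3 subjects x 3 blocks, written out by hand
  y <- c(5.1, 4.2, 3.9,
         6.0, 5.1, 4.6,
         5.5, 4.8, 4.1)
  subj <- rep(c("a", "b", "c"), each = 3)
  blk <- rep(c("pre", "train", "post"), 3)
  got <- rm_anova(y, subj, blk)
  want <- oracle_rm(y, subj, blk)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$ms_error, want$ms_error, tolerance = 1e-10)
  # pairwise SEs use the pooled error term
  expect_equal(got$pairwise$se, rep(sqrt(2 * want$ms_error / 3), 3),
               tolerance = 1e-10)
})

test_that("repeated-measures ANOVA handles degenerate designs", {
  # subjects constant across blocks: no condition and no error variance
  y <- rep(c(1, 2, 3), each = 3)
  got <- rm_anova(y, rep(c("a", "b", "c"), each = 3), rep(c("p", "t", "q"), 3))
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)
  expect_true(got$degenerate)
  expect_error(rm_anova(1:5, c("a", "a", "b", "b", "c"),
                        c("x", "y", "x", "y", "x")), "balanced")
})

test_that("repeated-measures ANOVA agrees with the oracle on random designs", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    k <- sample(3:4, 1)
    y <- rnorm(n * k)
    subj <- rep(seq_len(n), each = k)
    cond <- rep(letters[seq_len(k)], n)
    got <- rm_anova(y, subj, cond)
    want <- oracle_rm(y, subj, cond)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("one-way ANOVA matches hand computation and is location invariant", {
  groups <- list(a = c(4.1, 3.9, 4.4, 4.0, 4.2),
                 b = c(5.0, 5.2, 4.8, 5.1, 4.9),
                 c = c(4.5, 4.6, 4.4, 4.7, 4.3))
  got <- oneway_anova(groups)
  want <- oracle_oneway(groups)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  shifted <- lapply(groups, function(v) v + 100)
  expect_equal(oneway_anova(shifted)$F, got$F, tolerance = 1e-8)

  # equal means with internal variance give F = 0
  eq <- list(c(1, 2, 3), c(0, 2, 4))
  expect_equal(oneway_anova(eq)$F, 0, tolerance = 1e-12)
  # fully constant input is flagged
  expect_true(oneway_anova(list(c(1, 1), c(1, 1)))$degenerate)
  expect_error(oneway_anova(list(1:3)), "2 groups")
})

test_that("Tukey HSD matches the studentized-range oracle", {
  set.seed(17)
  for (i in 1:20) {
    groups <- lapply(1:3, function(j) rnorm(sample(4:8, 1), mean = j * 0.3))
    names(groups) <- letters[1:3]
    got <- tukey_posthoc(groups)
    want <- oracle_tukey(groups)
    expect_equal(got$p_tukey, unname(want), tolerance = 1e-6)
    # one family leaves the p-values unchanged
    expect_equal(got$p_adjusted, got$p_tukey)
    # several families scale, capped at 1
    got3 <- tukey_posthoc(groups, bonferroni_families = 3)
    expect_equal(got3$p_adjusted, pmin(1, got$p_tukey * 3), tolerance = 1e-12)
  }
  # two identical groups are indistinguishable
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_gt(tukey_posthoc(g)$p_tukey, 1 - 1e-9)
  expect_error(tukey_posthoc(list(1:3)), "2 groups")
})

test_that("t-tests follow hand arithmetic and flag degenerate input", {
  sym <- c(-2, -1, 0, 1, 2)
  got <- one_sample_ttest(sym)
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)

  got2 <- one_sample_ttest(c(1, 2, 3))
  expect_equal(got2$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(got2$p, oracle_t1(c(1, 2, 3))$p, tolerance = 1e-12)

  expect_true(one_sample_ttest(rep(1, 5))$degenerate)

  a <- c(1.2, 0.8, 1.1, 0.9)
  got3 <- two_sample_ttest(a, a)
  expect_equal(got3$t, 0)
  set.seed(3)
  b <- rnorm(6, 0.5)
  got4 <- two_sample_ttest(a, b)
  want4 <- oracle_t2(a, b)
  expect_equal(got4$t, want4$t, tolerance = 1e-12)
  expect_equal(got4$p, want4$p, tolerance = 1e-12)
  expect_true(two_sample_ttest(rep(1, 3), rep(1, 3))$degenerate)
})

test_that("the report recovers injected learning effects without noise", {
  p <- learning_params(
    slope = rbind(NF = c(0.0067, 2.64e-4, 2.4e-5),
                  IF = c(-0.0023, -1.15e-4, -1.32e-5),
                  IBF = c(-0.005, -2.58e-4, -8.63e-6)),
    noise_sd = c(time_s = 0, path_m = 0, error_m = 0))
  st <- generate_study(5, p, seed = 7)
  rep <- build_report(st$trials)
  oc <- rep$outcomes
  for (mode in c("NF", "IF", "IBF")) {
    beta <- oc[oc$feedback_mode == mode & oc$metric == "time_s",
               "intra_training_rate"]
    expect_equal(beta, rep(p$slope[mode, "time_s"], 5), tolerance = 1e-6)
    delta <- oc[oc$feedback_mode == mode & oc$metric == "path_m",
                "post_training_effect"]
    expect_equal(delta, rep(p$post_offset[mode, "path_m"], 5),
                 tolerance = 1e-6)
  }
  # sign conventions: injected improvements appear negative
  expect_lt(mean(oc[oc$feedback_mode == "IBF" & oc$metric == "time_s",
                    "intra_training_rate"]), 0)
  expect_gt(mean(oc[oc$feedback_mode == "NF" & oc$metric == "time_s",
                    "intra_training_rate"]), 0)
  # de-normalized group pre-training means equal the configured baselines
  expect_equal(unname(rep$group_pre_means), unname(p$baseline),
               tolerance = 1e-9)
})

test_that("a study with no effects and no noise yields all-zero outcomes", {
  p <- learning_params(
    slope = rbind(NF = c(0, 0, 0), IF = c(0, 0, 0), IBF = c(0, 0, 0)),
    post_offset = rbind(NF = c(0, 0, 0), IF = c(0, 0, 0), IBF = c(0, 0, 0)),
    noise_sd = c(time_s = 0, path_m = 0, error_m = 0))
  st <- generate_study(4, p, seed = 21)
  rep <- build_report(st$trials)
  expect_true(all(abs(rep$outcomes$intra_training_rate) < 1e-12))
  expect_true(all(abs(rep$outcomes$post_training_effect) < 1e-12))
  expect_true(all(rep$one_sample$degenerate))
})

test_that("the report battery reproduces the expected effect structure", {
  st <- generate_study(17, seed = 2021)
  rep <- build_report(st$trials)
  oa <- rep$outcome_anova
  # feedback modes differ on completion-time outcomes
  expect_lt(oa[oa$metric == "time_s" &
                 oa$outcome == "intra_training_rate", "p"], 0.05)
  os <- rep$one_sample
  ibf_t <- os[os$metric == "time_s" & os$outcome == "intra_training_rate" &
                os$feedback_mode == "IBF", ]
  nf_t <- os[os$metric == "time_s" & os$outcome == "intra_training_rate" &
               os$feedback_mode == "NF", ]
  expect_lt(ibf_t$mean, 0)                   # IBF improves
  expect_gt(nf_t$mean, 0)                    # NF drifts worse
  expect_error(build_report(st$trials[st$trials$block != "post", ]),
               "incomplete")
})
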