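# Independent reference implementations used as oracles: naive loops and
# hand-written closed forms, deliberately kept apart from the package code.

# per-frame loop version of the secure band rule
naive_label <- function(feats, means, active, tol) {
  out <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    ok <- TRUE
    for (c in seq_along(means)) {
      if (!active[c]) next
      if (abs(feats[i, c] - means[c]) > tol * means[c]) { ok <- FALSE; break }
    }
    out[i] <- as.integer(ok)
  }
  out
}

# OLS slope, closed form
oracle_slope <- function(y) {
  k <- seq_along(y)
  sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
}

# one-way ANOVA from partitioned sums of squares
oracle_oneway <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  N <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

# one-factor repeated-measures ANOVA from partitioned sums of squares
oracle_rm <- function(y, subj, cond) {
  subj <- factor(subj); cond <- factor(cond)
  n <- nlevels(subj); k <- nlevels(cond)
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  ss_subj <- k * sum((tapply(y, subj, mean) - gm)^2)
  ss_cond <- n * sum((tapply(y, cond, mean) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE),
       ms_error = ss_err / df2, df2 = df2)
}

# Tukey-Kramer pairwise p-values from group summaries
oracle_tukey <- function(groups) {
  k <- length(groups)
  N <- sum(lengths(groups))
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1)) / (N - k)
  pairs <- combn(k, 2)
  apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(msw / 2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
    q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / se
    ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
  })
}

oracle_t1 <- function(x, mu = 0) {
  t <- (mean(x) - mu) / (sd(x) / sqrt(length(x)))
  list(t = t, p = 2 * pt(-abs(t), length(x) - 1))
}

oracle_t2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# central finite-difference gradient of the network loss
oracle_fd_grad <- function(w, X, y, n_in, n_hid, h = 1e-6) {
  vapply(seq_along(w), function(i) {
    wp <- w; wm <- w
    wp[i] <- w[i] + h
    wm[i] <- w[i] - h
    (graspglove:::ann_loss_grad(wp, X, y, n_in, n_hid, want_grad = FALSE)$loss -
     graspglove:::ann_loss_grad(wm, X, y, n_in, n_hid, want_grad = FALSE)$loss) /
      (2 * h)
  }, numeric(1))
}
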