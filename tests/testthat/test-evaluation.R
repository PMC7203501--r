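test_that("AUC equals the exhaustive pair-counting oracle", {
  set.seed(101)
  for (k in 1:50) {
    n <- sample(20:80, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- sample(round(rnorm(n), 1))   # ties on purpose
    r <- roc_auc_delong(s, y)
    xs <- s[y == 1]; ys <- s[y == 0]
    conc <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    expect_equal(r$auc, conc / (length(xs) * length(ys)),
                 tolerance = 1e-12)
  }
})

test_that("ROC limits, rank invariance, Youden behaviour", {
  y <- c(rep(0, 50), rep(1, 50))
  s <- c(rnorm(50, 0), rnorm(50, 10))
  r <- roc_auc_delong(s, y)
  expect_equal(r$auc, 1)
  expect_equal(r$youden$j, 1)
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(all(r$ci >= 0 & r$ci <= 1))
  # monotone transform leaves everything but the cutoff value unchanged
  r2 <- roc_auc_delong(exp(s / 3), y)
  expect_equal(r2$auc, r$auc)
  expect_equal(r2$var_auc, r$var_auc, tolerance = 1e-12)
  expect_equal(r2$youden$sensitivity, r$youden$sensitivity)
  # null: AUC near 0.5 at n = 2000
  set.seed(17)
  y0 <- rbinom(2000, 1, 0.3)
  s0 <- rnorm(2000)
  r0 <- roc_auc_delong(s0, y0)
  expect_lt(abs(r0$auc - 0.5), 3 * sqrt(r0$var_auc))
  expect_error(roc_auc_delong(s0, rep(1, 2000)), "both classes")
})

test_that("paired DeLong: identical and rank-equivalent scores give delta 0", {
  set.seed(19)
  y <- rbinom(300, 1, 0.2)
  s <- rnorm(300) + y
  d <- delong_paired_test(s, s, y)
  expect_equal(d$delta, 0)
  expect_equal(d$p_value, 1)
  d2 <- delong_paired_test(s, 3 * s - 7, y)   # monotone transform
  expect_equal(d2$delta, 0)
  expect_error(delong_paired_test(s, s[-1], y[-1]), "length mismatch")
})

test_that("DeLong variance of the AUC difference matches the bootstrap", {
  set.seed(23)
  n <- 500
  y <- rbinom(n, 1, 0.3)
  base <- rnorm(n) + 1.2 * y
  sa <- base + rnorm(n, sd = 0.6)
  sb <- base + rnorm(n, sd = 0.8)
  d <- delong_paired_test(sa, sb, y)
  auc_of <- function(s, y) {
    r <- rank(s)
    m <- sum(y == 1)
    (sum(r[y == 1]) - m * (m + 1) / 2) / (m * sum(y == 0))
  }
  B <- 2000
  dd <- numeric(B)
  for (b in seq_len(B)) {
    ix <- sample.int(n, replace = TRUE)
    if (length(unique(y[ix])) < 2) { dd[b] <- NA; next }
    dd[b] <- auc_of(sa[ix], y[ix]) - auc_of(sb[ix], y[ix])
  }
  expect_equal(d$var_delta, var(dd, na.rm = TRUE), tolerance = 0.15)
  # single-curve variance against the bootstrap too
  r <- roc_auc_delong(sa, y)
  da <- numeric(B)
  for (b in seq_len(B)) {
    ix <- sample.int(n, replace = TRUE)
    da[b] <- if (length(unique(y[ix])) < 2) NA else auc_of(sa[ix], y[ix])
  }
  expect_equal(r$var_auc, var(da, na.rm = TRUE), tolerance = 0.15)
})

test_that("PR: perfect scorer, null scorer, and the step-function oracle", {
  y <- c(rep(1, 20), rep(0, 180))
  s <- c(rnorm(20, 10), rnorm(180, 0))
  expect_equal(pr_curve(s, y)$average_precision, 1)
  # brute-force oracle on a small set with ties
  set.seed(29)
  y2 <- rbinom(40, 1, 0.4); y2[1:2] <- c(0, 1)
  s2 <- round(rnorm(40), 1)
  pr <- pr_curve(s2, y2)
  th <- sort(unique(s2), decreasing = TRUE)
  prec <- vapply(th, function(t) sum(y2[s2 >= t]) / sum(s2 >= t), 0)
  rec <- vapply(th, function(t) sum(y2[s2 >= t]) / sum(y2), 0)
  oracle <- sum(diff(c(0, rec)) * prec)
  expect_equal(pr$average_precision, oracle, tolerance = 1e-12)
})

test_that("cross-validated PR of a random scorer sits at prevalence", {
  set.seed(31)
  n <- 2000
  df <- data.frame(noise = rnorm(n),
                   event = ifelse(rbinom(n, 1, 0.115) == 1, "+", "-"),
                   set = "training")
  fml <- structure(list(weights = c(noise = 1), intercept = 0),
                   class = "score_formula")
  pr <- pr_curve_cv(df, fml, n_folds = 10, seed = 1)
  se <- sd(pr$fold_ap) / sqrt(sum(!is.na(pr$fold_ap)))
  expect_lt(abs(pr$mean_precision - 0.115), 3 * se + 0.01)
  expect_equal(pr$n_skipped, 0)
})

test_that("folds without events are skipped with a warning", {
  set.seed(37)
  df <- data.frame(x = rnorm(60),
                   event = c(rep("+", 3), rep("-", 57)), set = "training")
  fml <- structure(list(weights = c(x = 1), intercept = 0),
                   class = "score_formula")
  w <- capture_warnings(pr <- pr_curve_cv(df, fml, n_folds = 10, seed = 2))
  expect_gt(length(w), 0)
  expect_true(all(grepl("no events", w)))
  expect_gt(pr$n_skipped, 0)
  expect_equal(sum(!is.na(pr$fold_ap)) + pr$n_skipped, 10)
})

test_that("net benefit matches the closed forms and the confusion-matrix oracle", {
  # perfect predictor at prevalence 0.2: NB = prevalence at any pt
  y <- c(rep(1, 40), rep(0, 160))
  d <- dca_net_benefit(as.numeric(y), y, thresholds = 0.1)
  expect_equal(d$net_benefit, 0.2)
  # treat-all crosses zero at pt = prevalence
  expect_equal(d$treat_all, 0.2 - 0.8 * 0.1 / 0.9, tolerance = 1e-12)
  dp <- dca_net_benefit(as.numeric(y), y, thresholds = 0.2 - 1e-9)
  expect_equal(dp$treat_all, 0, tolerance = 1e-6)
  expect_true(all(dp$treat_none == 0))
  # random probabilities vs hand-computed confusion matrices
  set.seed(41)
  p <- runif(400)
  y2 <- rbinom(400, 1, p)
  th <- seq(0.05, 0.95, length.out = 11)
  d2 <- dca_net_benefit(p, y2, thresholds = th, is_probability = TRUE)
  for (i in seq_along(th)) {
    act <- p >= th[i]
    tp <- sum(act & y2 == 1); fp <- sum(act & y2 == 0)
    expect_equal(d2$net_benefit[i],
                 tp / 400 - fp / 400 * th[i] / (1 - th[i]),
                 tolerance = 1e-12)
  }
  # model net benefit never exceeds prevalence
  expect_true(all(d2$net_benefit <= mean(y2) + 1e-12))
  expect_error(dca_net_benefit(p, y2, thresholds = c(0, 0.5)), "in \\(0, 1\\)")
})

test_that("t-test: identical groups, permutation oracle, summary-stat path", {
  x <- rnorm(30)
  t0 <- ttest_groups(x, x)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # permutation oracle on shifted normals
  set.seed(43)
  a <- rnorm(25, 0.6); b <- rnorm(30, 0)
  tt <- ttest_groups(a, b)
  pooled <- c(a, b)
  B <- 10000
  ref <- replicate(B, {
    ix <- sample.int(55, 25)
    abs(ttest_groups(pooled[ix], pooled[-ix])$statistic)
  })
  p_perm <- mean(ref >= abs(tt$statistic))
  expect_lt(abs(tt$p_value - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / B) +
              0.002)
  # summary path identical to raw path
  ts <- ttest_groups(list(n = 25, mean = mean(a), sd = sd(a)),
                     list(n = 30, mean = mean(b), sd = sd(b)))
  expect_equal(ts$statistic, tt$statistic, tolerance = 1e-12)
  expect_equal(ts$p_value, tt$p_value, tolerance = 1e-12)
  # agrees with the stock implementation
  expect_equal(tt$p_value, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(ttest_groups(a, b, welch = TRUE)$p_value,
               t.test(a, b)$p.value, tolerance = 1e-12)
  expect_error(ttest_groups(rep(1, 5), rep(1, 6)), "zero variance")
})

test_that("chi-square matches the reference dilation table and a simulation null", {
  tab <- matrix(c(13, 21, 31, 231), 2, byrow = TRUE)
  ct <- chi2_2x2(tab)
  expect_equal(ct$statistic, 16.6, tolerance = 0.01)
  expect_lt(ct$p_value, 0.001)
  # proportional table -> statistic 0
  expect_equal(chi2_2x2(matrix(c(10, 20, 20, 40), 2))$statistic, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
  # null calibration by multinomial simulation at n = 60
  set.seed(47)
  B <- 1e5
  pr <- c(0.2, 0.3, 0.2, 0.3)   # independent margins 0.5/0.5 x 0.4/0.6
  pr <- outer(c(0.5, 0.5), c(0.4, 0.6))
  draws <- rmultinom(B, 60, as.vector(pr))
  stats <- apply(draws, 2, function(cnt) {
    m <- matrix(cnt, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
    chi2_2x2(m)$statistic
  })
  # upper tail of the simulated null vs the chi-square(1) reference
  q95 <- quantile(stats, 0.95, na.rm = TRUE)
  expect_equal(unname(q95), qchisq(0.95, 1), tolerance = 0.08)
})
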