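#' ROC curve, AUC with DeLong variance, and Youden cut-off
#'
#' AUC via the Mann-Whitney statistic with midranks for ties; the variance
#' follows DeLong's structural-components construction, giving a Wald 95%
#' confidence interval truncated to `[0, 1]`. The optimal cut-off maximizes
#' the Youden index `J = sensitivity + specificity - 1` over the observed
#' thresholds; ties break towards higher specificity.
#'
#' @param scores numeric risk scores (higher = more likely event).
#' @param labels event labels: logical, 0/1, or `"+"`/`"-"`.
#' @return object of class `roc_result`: `auc`, `var_auc`, `ci` (95%),
#'   `curve` (data.frame threshold/fpr/tpr), `youden` (list: cutoff,
#'   sensitivity, specificity, j).
#' @export
roc_auc_delong <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(y) != length(scores)) stop("roc_auc_delong: length mismatch")
  if (length(unique(y)) < 2)
    stop("roc_auc_delong: both classes must be present")
  comp <- .delong_components(scores, y)
  auc <- comp$auc
  v <- comp$var
  se <- sqrt(v)
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)

  # ROC curve over observed thresholds (descending)
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & y == 1) / n1, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & y == 0) / n0, 0)
  curve <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  j <- tpr - fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.min(fpr[best])]
  youden <- list(cutoff = th[best], sensitivity = tpr[best],
                 specificity = 1 - fpr[best], j = j[best])
  structure(list(auc = auc, var_auc = v, ci = ci, curve = curve,
                 youden = youden, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff %.3g (se %.2f, sp %.2f)\n",
              x$auc, x$ci[1], x$ci[2], x$youden$cutoff,
              x$youden$sensitivity, x$youden$specificity))
  invisible(x)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("labels must be binary")
    return(as.integer(labels))
  }
  as.integer(as.character(labels) %in% c("+", "1", "TRUE", "yes", "event"))
}

# DeLong structural components: V10 (per event), V01 (per non-event),
# midrank-based; returns AUC and its variance
.delong_components <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  # psi(x, y) = 1[x > y] + 0.5 * 1[x == y], computed via midranks
  r_all <- rank(c(xs, ys), ties.method = "average")
  r_x <- rank(xs, ties.method = "average")
  r_y <- rank(ys, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  list(auc = auc, var = s10 / m + s01 / n, v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects,
#' accounting for their correlation through the covariance of the DeLong
#' structural components. Two-sided normal p-value and a 95% CI for the
#' AUC difference.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @param labels event labels (shared).
#' @return object of class `paired_delong`: `auc_a`, `auc_b`, `delta`,
#'   `var_delta`, `z`, `p_value`, `ci`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  y <- .as_binary(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y))
    stop("delong_paired_test: length mismatch")
  if (length(unique(y)) < 2)
    stop("delong_paired_test: both classes must be present")
  ca <- .delong_components(scores_a, y)
  cb <- .delong_components(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- if (m > 1) cov(ca$v10, cb$v10) else 0
  s01 <- if (n > 1) cov(ca$v01, cb$v01) else 0
  var_d <- ca$var + cb$var - 2 * (s10 / m + s01 / n)
  delta <- ca$auc - cb$auc
  z <- if (var_d > 0) delta / sqrt(var_d) else 0
  p <- if (var_d > 0) 2 * pnorm(-abs(z)) else 1
  ci <- delta + c(-1, 1) * qnorm(0.975) * sqrt(max(var_d, 0))
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                 var_delta = var_d, z = z, p_value = p, ci = ci),
            class = "paired_delong")
}

#' @export
print.paired_delong <- function(x, ...) {
  cat(sprintf("dAUC %.3f (%.3f vs %.3f), z %.2f, p %.3g, 95%% CI %.3f-%.3f\n",
              x$delta, x$auc_a, x$auc_b, x$z, x$p_value, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Precision-recall curve and average precision
#'
#' Average precision as the step-interpolated area under the
#' precision-recall curve: `sum (R_i - R_{i-1}) P_i` over descending score
#' thresholds.
#'
#' @param scores numeric risk scores.
#' @param labels event labels.
#' @return list with `curve` (data.frame recall/precision per threshold)
#'   and `average_precision`.
#' @export
pr_curve <- function(scores, labels) {
  y <- .as_binary(labels)
  if (sum(y) == 0) stop("pr_curve: no events")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  # evaluate at the last index of each distinct score
  last <- c(diff(ss) != 0, TRUE)
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = recall, precision = precision,
                          threshold = ss[last]),
       average_precision = ap)
}

#' Cross-validated precision-recall evaluation
#'
#' Splits the cohort into event-stratified folds and computes a
#' precision-recall curve and average precision on each held-out fold. For
#' a fixed `score_formula` the score is simply evaluated on the fold; with
#' `refit = TRUE` the LASSO model is refitted on the remaining folds at
#' the given lambda rule and the held-out fold is scored by it. The summary
#' `mean_precision` is the unweighted mean of per-fold average precision.
#'
#' @param table cohort data.frame.
#' @param formula a `score_formula`, or a function `(train_df) ->
#'   function(df) -> scores` when `refit = TRUE` behaviour is customized.
#' @param n_folds folds (default 10).
#' @param seed fold-assignment seed.
#' @param set cohort set to evaluate (`"training"`, `"validation"`,
#'   `"all"`).
#' @param refit refit the model per fold rather than applying a fixed
#'   formula.
#' @param rule lambda rule for per-fold refits.
#' @return object of class `pr_cv_result`: `fold_ap` (per-fold average
#'   precision, NA for skipped folds), `mean_precision`, `curves`
#'   (per-fold data.frames), `n_skipped`.
#' @export
pr_curve_cv <- function(table, formula, n_folds = 10, seed = 1L,
                        set = c("all", "training", "validation"),
                        refit = FALSE, rule = "1se") {
  set <- match.arg(set)
  rows <- if (set == "all") rep(TRUE, nrow(table)) else table$set == set
  df <- table[rows, , drop = FALSE]
  y <- .as_binary(df$event)
  foldid <- .stratified_folds(y, n_folds, seed)
  fold_ap <- rep(NA_real_, n_folds)
  curves <- vector("list", n_folds)
  n_skipped <- 0L
  for (k in seq_len(n_folds)) {
    hold <- foldid == k
    if (sum(y[hold]) == 0) {
      n_skipped <- n_skipped + 1L
      warning("pr_curve_cv: fold ", k, " has no events; skipped")
      next
    }
    sc <- if (isTRUE(refit)) {
      fit_k <- fit_lasso_cv(df[!hold, , drop = FALSE], n_folds = n_folds,
                            seed = seed, set = "all")
      fml <- extract_formula(fit_k, rule)
      .predict_formula_df(fml, df[hold, , drop = FALSE])
    } else if (is.function(formula)) {
      scorer <- formula(df[!hold, , drop = FALSE])
      scorer(df[hold, , drop = FALSE])
    } else {
      .predict_formula_df(formula, df[hold, , drop = FALSE])
    }
    pr <- pr_curve(sc, y[hold])
    fold_ap[k] <- pr$average_precision
    curves[[k]] <- pr$curve
  }
  structure(list(fold_ap = fold_ap,
                 mean_precision = mean(fold_ap, na.rm = TRUE),
                 curves = curves, n_skipped = n_skipped,
                 prevalence = mean(y)),
            class = "pr_cv_result")
}

# formula application tolerant of dilation/sex encodings
.predict_formula_df <- function(formula, df) {
  need <- names(formula$weights)
  for (f in intersect(need, names(df))) {
    if (f == "sex") df[[f]] <- as.numeric(df[[f]] == "male")
    else if (is.logical(df[[f]])) df[[f]] <- as.numeric(df[[f]])
  }
  apply_formula(formula, df)
}

#' @export
print.pr_cv_result <- function(x, ...) {
  cat(sprintf("mean precision %.3f over %d folds (%d skipped), prevalence %.3f\n",
              x$mean_precision, length(x$fold_ap), x$n_skipped,
              x$prevalence))
  invisible(x)
}

#' Decision-curve net benefit
#'
#' Net benefit of acting on the model at threshold probability `pt`:
#' `TP/n - (FP/n) * pt / (1 - pt)`, next to the treat-all and treat-none
#' references. Raw (non-probability) scores are mapped to event
#' probabilities by a one-variable logistic recalibration fitted on the
#' evaluated data; binary flags are used directly as a treat-if-positive
#' policy.
#'
#' @param scores numeric scores, probabilities, or a logical/binary flag.
#' @param labels event labels.
#' @param thresholds probability thresholds in (0, 1).
#' @param is_probability treat `scores` as probabilities (skip
#'   recalibration).
#' @return object of class `dca_curve`: data.frame with `threshold`,
#'   `net_benefit`, `treat_all`, `treat_none`.
#' @export
dca_net_benefit <- function(scores, labels,
                            thresholds = seq(0.01, 0.99, by = 0.01),
                            is_probability = FALSE) {
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("dca_net_benefit: thresholds must be in (0, 1)")
  y <- .as_binary(labels)
  n <- length(y)
  binary <- is.logical(scores) || all(scores %in% c(0, 1))
  p <- if (binary) as.numeric(scores)
  else if (is_probability) scores
  else {
    # logistic recalibration: score -> event probability
    fit <- glm(y ~ s, family = binomial(), data = data.frame(y = y,
                                                             s = scores))
    predict(fit, type = "response")
  }
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    act <- p >= pt
    tp <- sum(act & y == 1); fp <- sum(act & y == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  structure(data.frame(threshold = thresholds, net_benefit = nb,
                       treat_all = ta, treat_none = 0),
            class = c("dca_curve", "data.frame"))
}

#' Two-sample t-test from raw vectors or summary statistics
#'
#' Two-sided Student's t-test between groups; `welch = TRUE` gives the
#' unequal-variance variant. Accepts raw vectors or `(n, mean, sd)`
#' summaries, which follow the same formulas exactly.
#'
#' @param a,b numeric vectors, or lists `list(n =, mean =, sd =)`.
#' @param welch use the unequal-variance (Welch) variant.
#' @return list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
ttest_groups <- function(a, b, welch = FALSE) {
  summ <- function(x) {
    if (is.list(x)) list(n = x$n, m = x$mean, s = x$sd)
    else list(n = length(x), m = mean(x), s = sd(x))
  }
  sa <- summ(a); sb <- summ(b)
  if (sa$n < 2 || sb$n < 2) stop("ttest_groups: need n >= 2 per group")
  if (sa$s == 0 && sb$s == 0)
    stop("ttest_groups: zero variance in both groups")
  if (welch) {
    se2a <- sa$s^2 / sa$n; se2b <- sb$s^2 / sb$n
    tstat <- (sa$m - sb$m) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (sa$n - 1) + se2b^2 / (sb$n - 1))
  } else {
    sp2 <- ((sa$n - 1) * sa$s^2 + (sb$n - 1) * sb$s^2) /
      (sa$n + sb$n - 2)
    tstat <- (sa$m - sb$m) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  }
  list(statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df),
       mean_a = sa$m, mean_b = sb$m)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction (df = 1), matching large-sample usage;
#' set `correct = TRUE` for the Yates-corrected variant.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_2x2 <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop("chi2_2x2: need a 2x2 table of nonnegative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi2_2x2: zero margin")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - E)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat, df = 1, p_value = pchisq(stat, 1,
                                                  lower.tail = FALSE),
       expected = E)
}

#' Full performance report for a score against a comparator
#'
#' ROC/AUC with DeLong CI and Youden cut-off for the score and for the
#' dilation flag, their paired DeLong comparison, cross-validated PR
#' curves, and decision curves, per cohort set.
#'
#' @param cohort cohort data.frame.
#' @param formula a `score_formula` (default: the published score).
#' @param seed fold seed for the PR cross-validation.
#' @return nested list by set (`training`, `validation`) with elements
#'   `roc_score`, `roc_dilation`, `delong`, `pr_score`, `pr_dilation`,
#'   `dca_score`, `dca_dilation`.
#' @export
evaluate_sets <- function(cohort, formula = paper_formula(), seed = 1L) {
  out <- list()
  for (st in intersect(c("training", "validation"), unique(cohort$set))) {
    df <- cohort[cohort$set == st, , drop = FALSE]
    sc <- .predict_formula_df(formula, df)
    dil <- as.numeric(df$dilation)
    y <- df$event
    out[[st]] <- list(
      roc_score = roc_auc_delong(sc, y),
      roc_dilation = roc_auc_delong(dil, y),
      delong = delong_paired_test(sc, dil, y),
      pr_score = pr_curve_cv(df, formula, seed = seed),
      pr_dilation = pr_curve_cv(df, .dilation_formula(), seed = seed),
      dca_score = dca_net_benefit(sc, y),
      dca_dilation = dca_net_benefit(dil, y))
  }
  out
}

# treat-if-dilated "formula": weight 1 on the dilation indicator
.dilation_formula <- function() {
  structure(list(weights = c(dilation = 1), intercept = 0, lambda = NA),
            class = "score_formula")
}
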