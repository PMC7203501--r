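#' Fit an L1-penalized logistic risk model with cross-validation
#'
#' Fits the LASSO logistic solution path on the modelled predictors of a
#' cohort table (the morphometric features plus dilation, age and sex) and
#' estimates the cross-validated binomial deviance on `n_folds`
#' event-stratified folds. Predictors are standardized internally;
#' coefficients are returned on the original scale. The lambda grid is 100
#' log-spaced values from the smallest all-zero-slopes lambda down to
#' `1e-3` of it.
#'
#' @param table cohort data.frame (see [simulate_cohort()]); only rows of
#'   the requested `set` are used.
#' @param n_folds folds for cross-validation (default 10).
#' @param seed integer; drives the stratified fold assignment.
#' @param set which set to fit on (`"training"` by default; `"all"` uses
#'   every row).
#' @param features predictor columns (default: the 15 morphometric
#'   features plus `dilation`, `age`, `sex` where present).
#' @return object of class `lasso_fit`: `lambda` (descending grid), `beta`
#'   (features x lambda, original scale), `a0` (intercepts), `cvm`/`cvsd`
#'   (mean CV deviance and its SE per lambda), `lambda_min`, `lambda_1se`,
#'   `foldid`, `seed`, `feature_names`.
#' @export
fit_lasso_cv <- function(table, n_folds = 10, seed = 1L,
                         set = c("training", "validation", "all"),
                         features = NULL) {
  set <- match.arg(set)
  rows <- if (set == "all") rep(TRUE, nrow(table)) else table$set == set
  df <- table[rows, , drop = FALSE]
  if (is.null(features))
    features <- intersect(c(morphometric_features(), "dilation", "age",
                            "sex"), names(df))
  y <- as.integer(df$event == "+")
  if (length(unique(y)) < 2)
    stop("fit_lasso_cv: outcome is constant in the selected set")
  if (sum(y) < n_folds / 2)
    warning("fit_lasso_cv: fewer than ", ceiling(n_folds / 2),
            " events; CV folds will be event-poor")

  X <- .model_matrix(df, features)
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    warning("fit_lasso_cv: dropping constant feature(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }

  foldid <- .stratified_folds(y, n_folds, seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          nlambda = 100, lambda.min.ratio = 1e-3,
                          standardize = TRUE)
  fit <- cv$glmnet.fit
  lam <- fit$lambda
  idx <- match(lam, cv$lambda)
  cvm <- cv$cvm[idx]; cvsd <- cv$cvsd[idx]
  structure(list(lambda = lam,
                 beta = as.matrix(fit$beta),
                 a0 = as.numeric(fit$a0),
                 cvm = cvm, cvsd = cvsd,
                 lambda_min = select_lambda_from_curve(lam, cvm, cvsd,
                                                      "min"),
                 lambda_1se = select_lambda_from_curve(lam, cvm, cvsd,
                                                      "1se"),
                 foldid = foldid, seed = as.integer(seed),
                 feature_names = colnames(X), glmnet_cv = cv),
            class = "lasso_fit")
}

# numeric model matrix: logical -> 0/1, sex -> male indicator
.model_matrix <- function(df, features) {
  cols <- lapply(features, function(f) {
    v <- df[[f]]
    if (f == "sex") as.numeric(v == "male")
    else if (is.logical(v)) as.numeric(v)
    else as.numeric(v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- features
  X
}

# event-stratified fold assignment, deterministic given seed
.stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  foldid <- integer(length(y))
  for (g in unique(y)) {
    ix <- which(y == g)
    foldid[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  foldid
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- colSums(x$beta != 0)
  cat(sprintf(
    "<lasso_fit: %d lambdas, lambda_min %.4g (%d nonzero), lambda_1se %.4g (%d nonzero)>\n",
    length(x$lambda), x$lambda_min, nz[which(x$lambda == x$lambda_min)],
    x$lambda_1se, nz[which(x$lambda == x$lambda_1se)]))
  invisible(x)
}

#' Select the penalty from a cross-validation curve
#'
#' `"min"` picks the lambda minimizing the mean CV deviance; `"1se"` picks
#' the largest lambda whose mean deviance is within one standard error of
#' that minimum.
#'
#' @param fit a [fit_lasso_cv()] result.
#' @param rule `"min"` or `"1se"`.
#' @return the selected lambda.
#' @export
select_lambda <- function(fit, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  select_lambda_from_curve(fit$lambda, fit$cvm, fit$cvsd, rule)
}

#' @rdname select_lambda
#' @param lambda,cvm,cvsd the CV table: penalty grid, mean loss, SE of the
#'   mean loss.
#' @export
select_lambda_from_curve <- function(lambda, cvm, cvsd,
                                     rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (length(lambda) == 0) stop("select_lambda: empty lambda grid")
  i_min <- which.min(cvm)
  if (rule == "min") return(lambda[i_min])
  ok <- cvm <= cvm[i_min] + cvsd[i_min]
  max(lambda[ok])
}

#' Extract the linear score formula at a penalty
#'
#' Returns the nonzero coefficients at `lambda` as a named weight map on
#' the original (scaled-unit) feature scales, plus the intercept.
#'
#' @param fit a [fit_lasso_cv()] result.
#' @param lambda a value in the fit's lambda grid (or `"1se"`/`"min"`).
#' @param drop_intercept discard the intercept (the published formula
#'   carries none).
#' @return object of class `score_formula`: list with `weights` (named
#'   numeric) and `intercept`.
#' @export
extract_formula <- function(fit, lambda = "1se", drop_intercept = FALSE) {
  if (is.character(lambda)) lambda <- select_lambda(fit, lambda)
  i <- which(abs(fit$lambda - lambda) < 1e-12)
  if (length(i) != 1) stop("extract_formula: lambda not in the fitted grid")
  b <- fit$beta[, i]
  w <- b[b != 0]
  structure(list(weights = w,
                 intercept = if (drop_intercept) 0 else fit$a0[i],
                 lambda = lambda),
            class = "score_formula")
}

#' The published three-parameter risk score
#'
#' The reference score for short-term adverse events in non-high-risk
#' acute pulmonary embolism, selected by the 1-SE rule at lambda 0.0668:
#' `0.92 x MPA bifurcation area + 0.50 x MPA outlet hydraulic diameter +
#' 0.10 x MPA outlet CSA`, with inputs in scaled units (areas in 100 mm^2,
#' diameter in 10 mm) and no intercept.
#'
#' @return a `score_formula`.
#' @export
paper_formula <- function() {
  structure(list(weights = c("MPA bifurcation area" = 0.92,
                             "MPA outlet hydraulic diameter" = 0.50,
                             "MPA outlet CSA" = 0.10),
                 intercept = 0,
                 lambda = 0.0668),
            class = "score_formula")
}

#' @export
print.score_formula <- function(x, ...) {
  terms <- sprintf("%.2f x %s", x$weights, names(x$weights))
  cat("score =", if (length(terms)) paste(terms, collapse = " + ")
      else "0", "\n")
  if (!is.null(x$intercept) && x$intercept != 0)
    cat("  + intercept", format(x$intercept), "\n")
  invisible(x)
}

#' Apply a score formula to feature data
#'
#' Pure linear combination of the named features, in the formula's scaled
#' units. Scores are returned at full precision; the reference figures
#' display them rounded to 2 decimals.
#'
#' @param formula a `score_formula` (e.g. [paper_formula()]).
#' @param features a named vector, a list, or a data.frame with one column
#'   per formula feature.
#' @return numeric score(s).
#' @export
apply_formula <- function(formula, features) {
  w <- formula$weights
  if (is.data.frame(features)) {
    missing <- setdiff(names(w), names(features))
    if (length(missing))
      stop("apply_formula: missing feature(s): ",
           paste(missing, collapse = ", "))
    X <- as.matrix(features[, names(w), drop = FALSE])
    drop(X %*% w) + formula$intercept
  } else {
    v <- unlist(features)
    missing <- setdiff(names(w), names(v))
    if (length(missing))
      stop("apply_formula: missing feature(s): ",
           paste(missing, collapse = ", "))
    sum(w * v[names(w)]) + formula$intercept
  }
}

#' Serialize / deserialize a score formula as JSON
#' @param formula a `score_formula`.
#' @param path file path.
#' @return invisibly `path` (write); a `score_formula` (read).
#' @export
write_formula <- function(formula, path) {
  jsonlite::write_json(list(weights = as.list(formula$weights),
                            intercept = formula$intercept,
                            lambda = formula$lambda),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_formula
#' @export
read_formula <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(weights = unlist(x$weights),
                 intercept = x$intercept %||% 0,
                 lambda = x$lambda),
            class = "score_formula")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
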