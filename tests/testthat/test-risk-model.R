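test_that("the penalty limit zeroes every slope and the path is sane", {
  co <- simulate_cohort(cohort_spec(seed = 31))
  fit <- fit_lasso_cv(co, seed = 1)
  expect_true(all(fit$beta[, 1] == 0))             # lambda_max: all zero
  expect_gte(fit$lambda_1se, fit$lambda_min)
  nz <- colSums(fit$beta != 0)
  # sparsity broadly non-increasing in lambda (allow path wobble)
  expect_lt(mean(diff(nz) < -1), 0.05)
  expect_true(all(diff(fit$lambda) < 0))
})

test_that("1-SE and min selection match an independent scan of the CV table", {
  co <- simulate_cohort(cohort_spec(seed = 32))
  fit <- fit_lasso_cv(co, seed = 2)
  # independent table scan
  i_min <- which.min(fit$cvm)
  expect_equal(select_lambda(fit, "min"), fit$lambda[i_min])
  thr <- fit$cvm[i_min] + fit$cvsd[i_min]
  expect_equal(select_lambda(fit, "1se"),
               max(fit$lambda[fit$cvm <= thr]))
  # and the reference implementation's own rule
  expect_equal(select_lambda(fit, "min"), fit$glmnet_cv$lambda.min)
  expect_equal(select_lambda(fit, "1se"), fit$glmnet_cv$lambda.1se)
  # synthetic curves: monotone-decreasing CV -> 1se >= min; flat -> largest
  lam <- rev(seq(0.01, 1, length.out = 20))
  expect_gte(select_lambda_from_curve(lam, seq(2, 1, length.out = 20),
                                      rep(0.05, 20), "1se"),
             select_lambda_from_curve(lam, seq(2, 1, length.out = 20),
                                      rep(0.05, 20), "min"))
  expect_equal(select_lambda_from_curve(lam, rep(1, 20), rep(0.1, 20),
                                        "1se"), max(lam))
  expect_error(select_lambda_from_curve(numeric(0), numeric(0),
                                        numeric(0)), "empty")
})

test_that("extract_formula returns the path coefficients verbatim", {
  co <- simulate_cohort(cohort_spec(seed = 33))
  fit <- fit_lasso_cv(co, seed = 3)
  lam <- select_lambda(fit, "1se")
  fml <- extract_formula(fit, lam)
  i <- which(fit$lambda == lam)
  b <- fit$beta[, i]
  expect_equal(fml$weights, b[b != 0])
  expect_equal(fml$intercept, fit$a0[i])
  # all-zero lambda_max fit -> empty formula
  empty <- extract_formula(fit, fit$lambda[1])
  expect_length(empty$weights, 0)
  expect_error(extract_formula(fit, 123), "not in the fitted grid")
})

test_that("errors: constant outcome; warnings: constant feature dropped", {
  co <- simulate_cohort(cohort_spec(seed = 34))
  co$event <- "-"
  expect_error(fit_lasso_cv(co, set = "all"), "constant")
  co2 <- simulate_cohort(cohort_spec(seed = 35))
  co2$age <- 60
  expect_warning(fit_lasso_cv(co2, seed = 1), "constant feature")
})

test_that("scaling a feature by c scales its coefficient by 1/c", {
  co <- simulate_cohort(cohort_spec(n_total = 600, seed = 36))
  fit1 <- fit_lasso_cv(co, seed = 4, set = "all")
  co2 <- co
  co2$`MPA bifurcation area` <- co2$`MPA bifurcation area` * 10
  fit2 <- fit_lasso_cv(co2, seed = 4, set = "all")
  # identical folds and internal standardization: same path, rescaled
  b1 <- fit1$beta["MPA bifurcation area", ]
  b2 <- fit2$beta["MPA bifurcation area", ]
  nz <- b1 != 0 & b2 != 0
  expect_gt(sum(nz), 5)
  expect_equal(b2[nz], b1[nz] / 10, tolerance = 1e-6)
})

test_that("the published formula reproduces all worked-example scores", {
  fml <- paper_formula()
  fx <- make_fig3_fixture()
  got <- sprintf("%.2f", apply_formula(fml, fx))
  expect_identical(got, sprintf("%.2f", fx$expected_score))
  # single-case and degenerate inputs
  expect_equal(apply_formula(fml, c("MPA bifurcation area" = 0.84,
                                    "MPA outlet hydraulic diameter" = 2.94,
                                    "MPA outlet CSA" = 7.68)),
               3.0108, tolerance = 1e-12)
  expect_equal(apply_formula(fml, c("MPA bifurcation area" = 0,
                                    "MPA outlet hydraulic diameter" = 0,
                                    "MPA outlet CSA" = 0)), 0)
  expect_error(apply_formula(fml, c("MPA outlet CSA" = 7.68)),
               "missing feature")
})

test_that("formula JSON round-trips", {
  fml <- paper_formula()
  tf <- tempfile(fileext = ".json")
  write_formula(fml, tf)
  back <- read_formula(tf)
  expect_equal(back$weights, fml$weights)
  expect_equal(back$intercept, 0)
})

test_that("sign recovery on sparse synthetic truth at the min rule", {
  # n = 500 cohorts from a known 3-feature logistic model; lambda_min
  # coefficients must recover the true signs (scaled down from the n = 1000
  # acceptance-suite version; see test-acceptance.R for the full check)
  ok <- 0; reps <- 15
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    n <- 500
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    eta <- -2 + 1.2 * X[, 1] - 1.0 * X[, 2] + 0.8 * X[, 3]
    y <- rbinom(n, 1, plogis(eta))
    df <- as.data.frame(X)
    df$event <- ifelse(y == 1, "+", "-")
    df$set <- "training"
    fit <- fit_lasso_cv(df, seed = r, features = paste0("f", 1:10))
    b <- fit$beta[, which(fit$lambda == fit$lambda_min)]
    if (b["f1"] > 0 && b["f2"] < 0 && b["f3"] > 0) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.95)
})

test_that("permuted labels select nothing at the 1-SE rule", {
  nz <- integer(20)
  for (r in seq_len(20)) {
    co <- simulate_cohort(cohort_spec(seed = 6000 + r))
    set.seed(7000 + r)
    co$event <- sample(co$event)
    fit <- suppressWarnings(fit_lasso_cv(co, seed = r, set = "all"))
    nz[r] <- sum(fit$beta[, which(fit$lambda == fit$lambda_1se)] != 0)
  }
  expect_equal(median(nz), 0)
})
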