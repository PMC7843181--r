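test_that("stepwise picks the true predictor and ignores noise", {
  set.seed(61)
  x <- cbind(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
  y <- 2 * x[, "x1"]
  fit <- stepwise_forward(x, y)
  expect_equal(fit$selected, "x1")
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 1e-8)
})

test_that("stepwise rarely admits pure-noise candidates", {
  # with 2 candidates at alpha = 0.05 the familywise entry probability is
  # about 1 - 0.95^2 ~ 0.10; over 100 reseeded runs the empty-model rate
  # should stay clearly above 0.75
  set.seed(62)
  empty <- 0L
  for (r in 1:100) {
    x <- cbind(x1 = rnorm(50), x2 = rnorm(50))
    y <- rnorm(50)
    if (length(stepwise_forward(x, y)$selected) == 0L) empty <- empty + 1L
  }
  expect_gt(empty, 75L)
})

test_that("a duplicated predictor enters only once", {
  set.seed(63)
  x1 <- rnorm(80)
  x <- cbind(x1 = x1, x2 = x1, x3 = rnorm(80))
  y <- x1 + rnorm(80, sd = 0.2)
  fit <- stepwise_forward(x, y)
  expect_length(intersect(fit$selected, c("x1", "x2")), 1L)
  expect_equal(fit$selected[1], "x1")  # tie broken by column order
})

test_that("zero-variance candidates are skipped with a warning", {
  set.seed(64)
  x <- cbind(x1 = rnorm(50), flat = rep(1, 50))
  y <- x[, 1] + rnorm(50, sd = 0.1)
  expect_warning(fit <- stepwise_forward(x, y), "flat")
  expect_equal(fit$selected, "x1")
})

test_that("PLS handles noiseless linear and collinear designs", {
  set.seed(65)
  x <- matrix(rnorm(300), 60, 5)
  y <- drop(x %*% c(1, -2, 0.5, 0, 0))
  fit <- pls_fit(x, y, ncomp = 5)   # full rank: exact on a noiseless design
  expect_lt(max(abs(predict(fit, x) - y)), 1e-6)
  expect_gte(loo_r2(x, y, function(x, y) pls_fit(x, y, ncomp = 3)), 0.99)
  # rank-2 design: 5 columns spanned by 2
  base <- matrix(rnorm(120), 60, 2)
  xc <- base %*% matrix(rnorm(10), 2, 5)
  yc <- drop(base %*% c(1, 1))
  fitc <- pls_fit(xc, yc, ncomp = 2)
  expect_lt(max(abs(predict(fitc, xc) - yc)), 1e-6)
  expect_error(pls_fit(xc, yc, ncomp = 4), "rank")
})

test_that("PLS on pure noise has no held-out predictive power", {
  set.seed(66)
  x <- matrix(rnorm(300), 60, 5)
  y <- rnorm(60)
  fit <- pls_fit(x, y)          # LOO grid selection
  r2 <- max(fit$loo_grid)
  expect_lte(r2, 0.05)
})

test_that("SVR respects its tube and degrades gracefully", {
  set.seed(67)
  x <- matrix(rnorm(120), ncol = 1)
  y <- drop(x) + rnorm(120, sd = 0.02)    # noise well inside epsilon
  fit <- svr_fit(x, y, epsilon = 0.1)
  expect_gte(loo_r2(x, y, svr_fit, epsilon = 0.1), 0.9)
  fit0 <- svr_fit(x, y, epsilon = 0)      # epsilon = 0 is legal
  expect_length(predict(fit0, x), 120L)
  expect_error(svr_fit(x, y, epsilon = -1), "epsilon")
  y_noise <- rnorm(120)
  expect_lte(loo_r2(matrix(rnorm(240), ncol = 2), y_noise, svr_fit), 0.05)
})

test_that("LOO R2 of the mean-only predictor matches its closed form", {
  # predicting with mean(y[-i]) gives residual (n/(n-1)) (y_i - mean(y)),
  # hence R2 = 1 - (n/(n-1))^2 exactly
  set.seed(68)
  y <- rnorm(40)
  x <- matrix(rnorm(40), ncol = 1)
  mean_fitter <- function(x, y) structure(list(mu = mean(y)),
                                          class = "mean_fit")
  assign("predict.mean_fit",
         function(object, newdata, ...) rep(object$mu, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.mean_fit", envir = globalenv()))
  n <- length(y)
  expect_equal(loo_r2(x, y, mean_fitter), 1 - (n / (n - 1))^2,
               tolerance = 1e-12)
  expect_error(loo_r2(x, rep(1, 40), mean_fitter), "constant")
})

test_that("all three baselines solve an easy linear problem", {
  set.seed(69)
  x <- matrix(rnorm(240), 80, 3)
  colnames(x) <- paste0("x", 1:3)
  y <- drop(x %*% c(1, 2, -1)) + rnorm(80, sd = 0.05)
  expect_gte(loo_r2(x, y, stepwise_forward), 0.95)
  expect_gte(loo_r2(x, y, function(x, y) pls_fit(x, y, ncomp = 3)), 0.95)
  expect_gte(loo_r2(x, y, svr_fit), 0.95)
})

test_that("a population R2 of 0.13 lands in the weak LOO band", {
  # signal fraction fixed analytically: var(beta x) / var(y) = 0.13
  set.seed(70)
  n <- 300
  x <- matrix(rnorm(2 * n), ncol = 2)
  colnames(x) <- c("x1", "x2")
  y <- sqrt(0.13) * x[, 1] + sqrt(0.87) * rnorm(n)
  r2 <- loo_r2(x, y, stepwise_forward)
  expect_gte(r2, 0.05)
  expect_lte(r2, 0.25)
})

test_that("baseline_report returns a coherent record", {
  set.seed(71)
  x <- matrix(rnorm(150), 50, 3)
  colnames(x) <- paste0("x", 1:3)
  y <- x[, 1] + rnorm(50, sd = 0.3)
  rep <- baseline_report(x, y, "stepwise", response = "demo")
  expect_s3_class(rep, "regression_report")
  expect_true("x1" %in% rep$predictors)
  expect_lte(rep$loo_r2, 1)
  expect_true(all(c("variable", "F", "critical") %in% names(rep$fit$steps)))
})
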