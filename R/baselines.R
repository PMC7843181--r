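# Conventional regression baselines run for contrast with the ellipse
# analysis: forward stepwise with F-to-enter, PLS1, and epsilon-insensitive
# SVR, all validated by leave-one-out R-squared.  In the weak-correlation
# regime these sit near R2 ~ 0.1 while the integrated ellipse correlation
# still ranks block relationships correctly.

#' Forward stepwise regression with F-test entry
#'
#' Starting from the intercept-only model, at every step the candidate
#' predictor with the largest partial-F statistic enters provided that F
#' exceeds the critical value `qf(1 - alpha, 1, df_residual)`; the
#' procedure stops when no candidate passes.  Ties are broken by column
#' order; zero-variance candidates are skipped with a warning.  There is
#' no elimination phase.
#'
#' @param x Numeric predictor matrix or data frame (columns named).
#' @param y Numeric response.
#' @param alpha Entry significance level (default 0.05).
#' @return An object of class `stepwise_fit`: `coefficients` (named, incl.
#'   intercept), `selected` (entry order), `steps` (data frame of
#'   variable, F, critical value per step), `alpha`, plus a `predict`
#'   method.
#' @export
stepwise_forward <- function(x, y, alpha = 0.05) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) != nrow(x)", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (n <= ncol(x) + 2L)
    stop("need n > number of predictors + 2", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s) skipped: ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  candidates <- colnames(x)[sds > 0]
  selected <- character()
  design <- matrix(1, n, 1L)            # intercept
  rss_cur <- sum((y - mean(y))^2)
  steps <- list()
  repeat {
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    df_res <- n - ncol(design) - 1L     # residual df after adding one term
    if (df_res < 1L) break
    best_f <- -Inf; best_v <- NA_character_; best_rss <- NA_real_
    for (v in pool) {
      fit <- stats::lm.fit(cbind(design, x[, v]), y)
      rss <- sum(fit$residuals^2)
      f <- if (rss <= 0) Inf else (rss_cur - rss) / (rss / df_res)
      if (f > best_f) { best_f <- f; best_v <- v; best_rss <- rss }
    }
    crit <- stats::qf(1 - alpha, 1L, df_res)
    if (best_f <= crit) break
    selected <- c(selected, best_v)
    design <- cbind(design, x[, best_v])
    steps[[length(steps) + 1L]] <-
      data.frame(step = length(selected), variable = best_v, F = best_f,
                 critical = crit, stringsAsFactors = FALSE)
    if (best_rss <= .Machine$double.eps * rss_cur) { rss_cur <- best_rss; break }
    rss_cur <- best_rss
  }
  coefs <- if (length(selected)) {
    fit <- stats::lm.fit(design, y)
    stats::setNames(fit$coefficients, c("(Intercept)", selected))
  } else c("(Intercept)" = mean(y))
  structure(list(coefficients = coefs, selected = selected,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(step = integer(),
                                         variable = character(),
                                         F = numeric(),
                                         critical = numeric()),
                 alpha = alpha),
            class = "stepwise_fit")
}

#' @export
predict.stepwise_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  b <- object$coefficients
  if (length(object$selected) == 0L)
    return(rep(b[["(Intercept)"]], nrow(newdata)))
  drop(b[["(Intercept)"]] +
         newdata[, object$selected, drop = FALSE] %*% b[object$selected])
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> alpha = %.3g, %d predictor(s) entered\n",
              x$alpha, length(x$selected)))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Partial least squares (PLS1) regression
#'
#' Univariate-response PLS in regression mode.  When `ncomp` is `NULL` the
#' component count is chosen by a leave-one-out grid over
#' `1..max_ncomp`: predictions for every component count are obtained in a
#' single pass and the count with the highest held-out R-squared is kept.
#'
#' @param x Predictor matrix.
#' @param y Numeric response.
#' @param ncomp Number of components, or `NULL` to select by LOO.
#' @param max_ncomp Upper end of the LOO grid (capped at `ncol(x)` and
#'   `n - 2`).
#' @return Object of class `pls_fit`: the underlying model, `ncomp`,
#'   `loo_grid` (per-count LOO R-squared, when selected), with a `predict`
#'   method.
#' @export
pls_fit <- function(x, y, ncomp = NULL, max_ncomp = 10L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  n <- nrow(x)
  rank_cap <- min(ncol(x), n - 2L, qr(scale(x, scale = FALSE))$rank)
  loo_grid <- NULL
  if (is.null(ncomp)) {
    grid_max <- min(max_ncomp, rank_cap)
    pred <- matrix(NA_real_, n, grid_max)
    for (i in seq_len(n)) {
      f <- mixOmics::pls(x[-i, , drop = FALSE], y[-i], ncomp = grid_max,
                         mode = "regression", scale = FALSE)
      p <- predict(f, x[i, , drop = FALSE])$predict
      pred[i, ] <- p[1L, 1L, ]
    }
    sst <- sum((y - mean(y))^2)
    loo_grid <- 1 - colSums((pred - y)^2) / sst
    ncomp <- which.max(loo_grid)
  } else if (ncomp > rank_cap) {
    stop("ncomp = ", ncomp, " exceeds the predictor rank (", rank_cap, ")",
         call. = FALSE)
  }
  model <- mixOmics::pls(x, y, ncomp = ncomp, mode = "regression",
                         scale = FALSE)
  structure(list(model = model, ncomp = as.integer(ncomp),
                 loo_grid = loo_grid, vars = colnames(x)),
            class = "pls_fit")
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$vars
  p <- predict(object$model, newdata)$predict
  p[, 1L, object$ncomp]
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d component(s)%s\n", x$ncomp,
              if (!is.null(x$loo_grid))
                sprintf(" (LOO-selected; best R2 = %.3f)", max(x$loo_grid))
              else ""))
  invisible(x)
}

#' Epsilon-insensitive support vector regression
#'
#' Linear-kernel SVR on standardized inputs by default: residuals smaller
#' than `epsilon` incur no loss, and the flattest function within the tube
#' is sought subject to the `cost` penalty on violations.
#'
#' @param x Predictor matrix.
#' @param y Numeric response.
#' @param epsilon Tube half-width, `>= 0` (default 0.1).
#' @param cost Regularization (inverse) constant, `> 0`.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @return Object of class `svr_fit` wrapping the e1071 model, with
#'   `n_support` (support-vector count) and a `predict` method.
#' @export
svr_fit <- function(x, y, epsilon = 0.1, cost = 1, kernel = c("linear",
                                                              "radial")) {
  kernel <- match.arg(kernel)
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("'epsilon' must be >= 0", call. = FALSE)
  x <- as.matrix(x)
  model <- e1071::svm(x, as.numeric(y), type = "eps-regression",
                      kernel = kernel, epsilon = epsilon, cost = cost,
                      scale = TRUE)
  structure(list(model = model, epsilon = epsilon, cost = cost,
                 kernel = kernel, n_support = nrow(model$SV)),
            class = "svr_fit")
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  unname(predict(object$model, as.matrix(newdata)))
}

#' @export
print.svr_fit <- function(x, ...) {
  cat(sprintf("<svr_fit> kernel = %s, epsilon = %.3g, %d support vectors\n",
              x$kernel, x$epsilon, x$n_support))
  invisible(x)
}

#' Leave-one-out R-squared of a fitting procedure
#'
#' Refits the procedure on every leave-one-out split and scores the
#' held-out predictions: `1 - SSE_pred / SST`, with SST about the full
#' response mean.  Can be negative when the procedure predicts worse than
#' the mean.
#'
#' @param x Predictor matrix.
#' @param y Numeric response (non-constant).
#' @param fitter Function `(x, y) -> model`; the model must have a
#'   `predict(model, newdata)` method.  Convenience strings
#'   `"stepwise"`, `"pls"`, `"svr"` select the package baselines with
#'   default settings.
#' @param ... Passed on to the fitter.
#' @return Numeric LOO R-squared.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- x[, 1] + rnorm(100, sd = 0.1)
#' loo_r2(x, y, "stepwise")
#' @export
loo_r2 <- function(x, y, fitter, ...) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3L) stop("need n >= 3 for leave-one-out", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant response: LOO R-squared undefined",
                     call. = FALSE)
  if (is.character(fitter))
    fitter <- switch(match.arg(fitter, c("stepwise", "pls", "svr")),
                     stepwise = stepwise_forward,
                     pls = function(x, y, ...) pls_fit(x, y, ...),
                     svr = svr_fit)
  pred <- vapply(seq_len(n), function(i) {
    fit <- fitter(x[-i, , drop = FALSE], y[-i], ...)
    as.numeric(predict(fit, x[i, , drop = FALSE]))[1L]
  }, 0)
  1 - sum((pred - y)^2) / sst
}

#' Run one baseline end to end and report it
#'
#' Fits the chosen method on the full data and evaluates it by
#' leave-one-out.  For PLS the component count is chosen once on the full
#' data by its internal LOO grid and then held fixed across the outer LOO
#' splits (a nested grid at every split would square the cost).
#'
#' @param x Predictor matrix.
#' @param y Response vector.
#' @param method `"stepwise"`, `"pls"` or `"svr"`.
#' @param response Name of the response (for the report).
#' @param ... Method settings (`alpha`, `ncomp`, `epsilon`, `cost`, ...).
#' @return Object of class `regression_report`: `method`, `response`,
#'   `fit`, `predictors`, `loo_r2`.
#' @export
baseline_report <- function(x, y, method = c("stepwise", "pls", "svr"),
                            response = "y", ...) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  fit <- switch(method,
                stepwise = stepwise_forward(x, y, ...),
                pls = pls_fit(x, y, ...),
                svr = svr_fit(x, y, ...))
  r2 <- switch(method,
               stepwise = loo_r2(x, y, stepwise_forward, ...),
               pls = loo_r2(x, y, function(x, y) pls_fit(x, y,
                                                         ncomp = fit$ncomp)),
               svr = loo_r2(x, y, svr_fit, ...))
  predictors <- switch(method,
                       stepwise = fit$selected,
                       pls = colnames(x),
                       svr = colnames(x))
  structure(list(method = method, response = response, fit = fit,
                 predictors = predictors, loo_r2 = r2),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %s ~ %s: LOO R2 = %.4f\n", x$response,
              x$method, x$loo_r2))
  invisible(x)
}
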