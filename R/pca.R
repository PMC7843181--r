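# Per-block PCA by singular value decomposition, and the shared
# retained-dimension rule: each block keeps the smallest number of leading
# components whose cumulative explained-variance fraction reaches the
# threshold sigma; the global dimension is the maximum of these per-block
# minima, capped at each block's own component count when scores are
# extracted.

#' Fit a PCA model to one block by SVD
#'
#' Columns are mean-centred and the centred matrix is decomposed as
#' `A = U D V'`.  Loadings are the columns of `V` with a deterministic sign
#' convention (the largest-magnitude element of each loading is positive);
#' the explained-variance fraction of component j is `d_j^2 / sum(d^2)`.
#' No rescaling happens here: correlation-matrix PCA is obtained by
#' z-scoring beforehand (see [preprocess()]).
#'
#' @param x Numeric matrix or data frame, samples in rows (`n >= 2`), no
#'   missing values.
#' @param name Optional block name carried through to results.
#' @return An object of class `pca_model`: `center`, `loadings`
#'   (m x r, orthonormal columns), `sdev`, `singular_values`
#'   (non-increasing), `explained_ratio` (sums to 1), `n`, `name`.
#' @examples
#' m <- fit_pca(cbind(x = rnorm(50), y = rnorm(50)))
#' cumsum(m$explained_ratio)
#' @export
fit_pca <- function(x, name = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (anyNA(x)) stop("missing values in PCA input; preprocess first",
                     call. = FALSE)
  n <- nrow(x); m <- ncol(x)
  if (n < 2L) stop("need at least 2 samples for PCA", call. = FALSE)
  if (m < 1L) stop("need at least 1 variable", call. = FALSE)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  sv <- svd(xc, nu = 0L, nv = min(n, m))
  d <- sv$d[seq_len(ncol(sv$v))]
  tot <- sum(d^2)
  if (tot <= 0) stop("block has zero total variance", call. = FALSE)
  # deterministic sign: largest |loading| element positive per component
  v <- sv$v
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  rownames(v) <- colnames(x)
  colnames(v) <- paste0("PC", seq_len(ncol(v)))
  structure(list(name = name, center = center, loadings = v,
                 singular_values = d, sdev = d / sqrt(n - 1),
                 explained_ratio = d^2 / tot, n = n, n_vars = m),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cum <- cumsum(x$explained_ratio)
  cat(sprintf("<pca_model>%s %d samples x %d variables\n",
              if (!is.null(x$name)) paste0(" [", x$name, "]") else "",
              x$n, x$n_vars))
  cat("  explained ratio:",
      paste(sprintf("%.3f", utils::head(x$explained_ratio, 6L)),
            collapse = " "),
      if (length(x$explained_ratio) > 6L) "..." else "", "\n")
  cat("  cumulative:    ",
      paste(sprintf("%.3f", utils::head(cum, 6L)), collapse = " "),
      if (length(cum) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Fit PCA models to every numeric block of a collection
#'
#' @param bc A preprocessed `block_collection`.
#' @return Named list of [fit_pca()] models, one per independent/dependent
#'   block.
#' @export
fit_block_pca <- function(bc) {
  stopifnot(inherits(bc, "block_collection"))
  nms <- block_names(bc, role = c("independent", "dependent"))
  stats::setNames(lapply(nms, function(nm) fit_pca(block_data(bc, nm),
                                                   name = nm)), nms)
}

#' Shared retained-dimension selection across blocks
#'
#' For each block the minimum number of leading components whose cumulative
#' explained-variance fraction reaches `sigma` is found; the global
#' dimension `k` is the maximum of these per-block minima, so every block's
#' retained scores explain at least `sigma` of its variance.  When
#' extracting scores, a low-rank block cannot supply more components than
#' it has: its extraction dimension is `min(k, components)`.
#'
#' @param models List of `pca_model` objects (e.g. from [fit_block_pca()]).
#' @param sigma Cumulative variance threshold in (0, 1]; 0.8 is the usual
#'   operating value.
#' @return An object of class `k_selection`: `k` (global), `sigma`, and a
#'   per-block data frame `table` with `k_min` (per-block minimum),
#'   `k_extract` (capped global k) and the cumulative explained fraction at
#'   each.
#' @export
select_k <- function(models, sigma = 0.8) {
  if (inherits(models, "pca_model")) models <- list(models)
  if (!length(models) || !all(vapply(models, inherits, TRUE, "pca_model")))
    stop("'models' must be a list of pca_model objects", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 || sigma > 1)
    stop("'sigma' must lie in (0, 1]", call. = FALSE)
  k_min <- vapply(models, function(m) {
    cum <- cumsum(m$explained_ratio)
    as.integer(which(cum >= sigma - 1e-12)[1L])
  }, 0L)
  k <- max(k_min)
  k_extract <- pmin(k, vapply(models, function(m)
    length(m$explained_ratio), 0L))
  cum_at <- function(m, kk) cumsum(m$explained_ratio)[kk]
  tab <- data.frame(
    block = vapply(models, function(m) m$name %||% "?", ""),
    n_vars = vapply(models, `[[`, 0L, "n_vars"),
    k_min = k_min,
    cum_at_k_min = mapply(cum_at, models, k_min),
    k_extract = k_extract,
    cum_at_k_extract = mapply(cum_at, models, k_extract),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(k = k, sigma = sigma, table = tab), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> sigma = %.2f, global k = %d\n", x$sigma, x$k))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Project data onto a fitted PCA model
#'
#' Scores are the variance-carrying projection `(x - center) %*% V[, 1:k]`,
#' which on the training data equals the first `k` columns of `U D`.
#'
#' @param model A `pca_model`.
#' @param data Matrix or data frame with the model's variables (defaults
#'   must be supplied; there is no stored training copy).
#' @param k Number of leading components to keep (`1 <= k <=` available
#'   components).
#' @return An n x k score matrix with attributes `block` and
#'   `explained_cum` (cumulative explained-variance fraction at `k`).
#' @export
pca_scores <- function(model, data, k = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(k)) k <- ncol(model$loadings)
  if (k < 1L || k > ncol(model$loadings))
    stop("k = ", k, " out of range 1..", ncol(model$loadings), call. = FALSE)
  x <- as.matrix(data)
  if (ncol(x) != length(model$center))
    stop("data has ", ncol(x), " columns; model expects ",
         length(model$center), call. = FALSE)
  s <- sweep(x, 2L, model$center, "-") %*% model$loadings[, seq_len(k),
                                                          drop = FALSE]
  attr(s, "block") <- model$name
  attr(s, "explained_cum") <- cumsum(model$explained_ratio)[k]
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
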