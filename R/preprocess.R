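# Data-quality chain applied before any PCA/ellipse work, in fixed order:
# (1) delete rows with missing numeric cells, (2) box-plot (Tukey fence)
# outlier removal, (3) z-score each analysis column.  Each step returns the
# reduced collection plus a report; preprocess() chains all three.

#' Delete rows with missing values in analysis columns
#'
#' Removes every sample with at least one missing value in an independent-
#' or dependent-block column.  Missing values in description columns do not
#' trigger removal.
#'
#' @param bc A `block_collection`.
#' @return List with `collection` (rows kept, in original order) and
#'   `report` (class `preprocess_report`): `n_input`, `n_kept`, and
#'   `removed` (input row indices).
#' @export
drop_missing <- function(bc) {
  stopifnot(inherits(bc, "block_collection"))
  cols <- numeric_columns(bc)
  if (!length(cols)) stop("no numeric analysis columns", call. = FALSE)
  bad <- rowSums(is.na(bc$data[, cols, drop = FALSE])) > 0L
  report <- new_preprocess_report("drop_missing", nrow(bc$data),
                                  sum(!bad), removed = which(bad))
  if (all(bad))
    stop("all rows contain missing values; nothing left to analyse",
         call. = FALSE)
  list(collection = subset_rows(bc, !bad), report = report)
}

#' Box-plot (Tukey fence) outlier removal
#'
#' For each analysis column, quartiles Q1 and Q3 are computed by linear
#' interpolation of order statistics (the default "type 7" quantile rule)
#' and fences are set at `Q1 - fence * IQR` and `Q3 + fence * IQR` with
#' `IQR = Q3 - Q1`.  A row is removed when ANY analysis column falls
#' outside its fences (values on the fence are kept).  With
#' `per_class = TRUE`, fences are computed within each class instead of
#' globally.
#'
#' @param bc A `block_collection` (no missing values in analysis columns).
#' @param fence Positive fence multiplier; 1.5 is the box-plot convention.
#' @param per_class Compute fences within class rather than globally.
#' @return List with `collection` and `report`; the report records the
#'   fences and the removed row indices per column.
#' @export
iqr_outlier_filter <- function(bc, fence = 1.5, per_class = FALSE) {
  stopifnot(inherits(bc, "block_collection"), is.numeric(fence), fence > 0)
  cols <- numeric_columns(bc)
  x <- bc$data[, cols, drop = FALSE]
  if (anyNA(x))
    stop("missing values present; run drop_missing() first", call. = FALSE)
  if (nrow(x) < 4L)
    stop("need at least 4 rows for stable quartiles", call. = FALSE)

  groups <- if (per_class) split(seq_len(nrow(x)), bc$class_labels)
            else list(all = seq_len(nrow(x)))
  out_by_col <- stats::setNames(vector("list", length(cols)), cols)
  fences <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    q <- vapply(x[idx, , drop = FALSE],
                stats::quantile, numeric(2L), probs = c(0.25, 0.75),
                names = FALSE, type = 7L)
    iqr <- q[2L, ] - q[1L, ]
    lo <- q[1L, ] - fence * iqr
    hi <- q[2L, ] + fence * iqr
    fences[[g]] <- data.frame(column = cols, q1 = q[1L, ], q3 = q[2L, ],
                              lower = lo, upper = hi, row.names = NULL,
                              stringsAsFactors = FALSE)
    for (j in seq_along(cols)) {
      v <- x[idx, j]
      flag <- idx[v < lo[j] | v > hi[j]]
      out_by_col[[j]] <- c(out_by_col[[j]], flag)
    }
  }
  removed <- sort(unique(unlist(out_by_col)))
  report <- new_preprocess_report("iqr_outlier_filter", nrow(x),
                                  nrow(x) - length(removed),
                                  removed = removed)
  report$fence <- fence
  report$per_class <- per_class
  report$fences <- if (per_class) fences else fences[["all"]]
  report$removed_by_column <- lapply(out_by_col, sort)
  keep <- rep(TRUE, nrow(x)); keep[removed] <- FALSE
  list(collection = subset_rows(bc, keep), report = report)
}

#' Z-score normalization of analysis columns
#'
#' Transforms each independent/dependent column to `(x - mean) / sd` using
#' the sample (n - 1 denominator) standard deviation; `c(1, 2, 3)` maps to
#' `c(-1, 0, 1)`.  Column means and standard deviations are stored in the
#' report so the transform can be inverted.
#'
#' @param bc A `block_collection` without missing analysis values.
#' @return List with `collection` (standardized) and `report` carrying a
#'   `scaling` data frame (column, mu, sigma).
#' @export
zscore_normalize <- function(bc) {
  stopifnot(inherits(bc, "block_collection"))
  cols <- numeric_columns(bc)
  x <- bc$data[, cols, drop = FALSE]
  if (anyNA(x))
    stop("missing values present; run drop_missing() first", call. = FALSE)
  mu <- vapply(x, mean, 0)
  sigma <- vapply(x, stats::sd, 0)
  zero <- cols[sigma == 0 | is.na(sigma)]
  if (length(zero))
    stop("zero-variance column(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  for (j in seq_along(cols))
    bc$data[[cols[j]]] <- (x[[j]] - mu[j]) / sigma[j]
  report <- new_preprocess_report("zscore", nrow(x), nrow(x),
                                  removed = integer())
  report$scaling <- data.frame(column = cols, mu = unname(mu),
                               sigma = unname(sigma),
                               stringsAsFactors = FALSE)
  list(collection = bc, report = report)
}

#' Full preprocessing pipeline
#'
#' Applies, in this fixed order: [drop_missing()], [iqr_outlier_filter()]
#' (once; fences are not recomputed on the reduced data), then
#' [zscore_normalize()] fitted on the filtered rows only.
#'
#' @inheritParams iqr_outlier_filter
#' @return List with `collection` and `report`, the latter combining the
#'   three step reports plus the overall row counts `n_input`,
#'   `n_after_missing`, `n_after_outliers`.
#' @export
preprocess <- function(bc, fence = 1.5, per_class = FALSE) {
  s1 <- drop_missing(bc)
  s2 <- iqr_outlier_filter(s1$collection, fence = fence,
                           per_class = per_class)
  s3 <- zscore_normalize(s2$collection)
  report <- structure(list(
    n_input = s1$report$n_input,
    n_after_missing = s1$report$n_kept,
    n_after_outliers = s2$report$n_kept,
    steps = list(drop_missing = s1$report, iqr_outlier_filter = s2$report,
                 zscore = s3$report)
  ), class = "preprocess_report")
  list(collection = s3$collection, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  if (!is.null(x$steps)) {
    cat("<preprocess_report>\n")
    cat(sprintf("  input rows:          %d\n", x$n_input))
    cat(sprintf("  after missing-drop:  %d\n", x$n_after_missing))
    cat(sprintf("  after outlier-drop:  %d\n", x$n_after_outliers))
  } else {
    cat(sprintf("<preprocess_report> step %s: %d -> %d rows (%d removed)\n",
                x$step, x$n_input, x$n_kept, length(x$removed)))
  }
  invisible(x)
}

# internal ---------------------------------------------------------------

new_preprocess_report <- function(step, n_input, n_kept, removed) {
  structure(list(step = step, n_input = n_input, n_kept = n_kept,
                 removed = as.integer(removed)),
            class = "preprocess_report")
}

subset_rows <- function(bc, keep) {
  bc$data <- bc$data[keep, , drop = FALSE]
  rownames(bc$data) <- NULL
  bc$class_labels <- factor(bc$class_labels[keep], levels = bc$class_set)
  bc
}
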