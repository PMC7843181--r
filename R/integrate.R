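# Integrated cross-block correlation.  Each class p has, in each block, a
# similarity profile: the row S(p, .) describing how much of class p sits
# in every other class's ellipse region.  Correlating the profiles of two
# blocks class by class measures whether the blocks group the classes
# consistently — the quantity that remains informative when direct
# regression between the blocks explains almost nothing.

#' Correlation of two blocks' similarity profiles for one class
#'
#' Takes row `p` of each block's similarity matrix over the classes common
#' to both blocks and returns their Pearson (or Spearman) correlation.
#' The self entry S(p, p) measures within-class aggregation rather than
#' cross-class similarity and is excluded by default.
#'
#' @param sa,sb `similarity_matrix` objects for the two blocks.
#' @param class Class label (must be present in both matrices).
#' @param exclude_self Drop the S(p, p) entry before correlating
#'   (default `TRUE`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   profile has zero variance.
#' @export
per_class_correlation <- function(sa, sb, class, exclude_self = TRUE,
                                  method = c("pearson", "spearman")) {
  stopifnot(inherits(sa, "similarity_matrix"),
            inherits(sb, "similarity_matrix"))
  method <- match.arg(method)
  common <- intersect(sa$labels, sb$labels)
  if (!class %in% common)
    stop("class '", class, "' not present in both similarity matrices",
         call. = FALSE)
  cols <- if (exclude_self) setdiff(common, class) else common
  if (length(cols) < 3L)
    stop("fewer than 3 paired profile entries for class '", class, "'",
         call. = FALSE)
  a <- sa$values[class, cols]
  b <- sb$values[class, cols]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance similarity profile for class '", class,
            "'; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Integrated correlation analysis between blocks
#'
#' For each requested block pair, computes the per-class profile
#' correlations and their minimum, mean and maximum across classes.
#'
#' @param sims Named list of `similarity_matrix` objects (e.g.
#'   `block_similarity(bc)$similarity`).
#' @param pairs Either `NULL` (all unordered pairs) or a list of length-2
#'   character vectors / a 2-column character matrix of block names.
#' @inheritParams per_class_correlation
#' @return A list of `integration_result` objects (one per pair), each
#'   with `blocks`, `per_class` (named numeric), `summary`
#'   (min/mean/max, `NA` profiles ignored), `method`, `exclude_self`.
#' @export
integrate_blocks <- function(sims, pairs = NULL, exclude_self = TRUE,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(sims, "mcea_result")) sims <- sims$similarity
  if (length(sims) < 2L)
    stop("need at least 2 similarity matrices", call. = FALSE)
  nms <- names(sims)
  if (is.null(pairs)) {
    pairs <- utils::combn(nms, 2L, simplify = FALSE)
  } else {
    if (is.matrix(pairs)) pairs <- asplit(pairs, 1L)
    pairs <- lapply(pairs, as.character)
  }
  out <- lapply(pairs, function(pr) {
    if (length(pr) != 2L) stop("each pair must name two blocks",
                               call. = FALSE)
    bad <- setdiff(pr, nms)
    if (length(bad))
      stop("unknown block name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    sa <- sims[[pr[1L]]]; sb <- sims[[pr[2L]]]
    common <- intersect(sa$labels, sb$labels)
    r <- vapply(common, function(cl)
      per_class_correlation(sa, sb, cl, exclude_self = exclude_self,
                            method = method), 0)
    names(r) <- common
    structure(list(blocks = pr, per_class = r,
                   summary = c(min = min(r, na.rm = TRUE),
                               mean = mean(r, na.rm = TRUE),
                               max = max(r, na.rm = TRUE)),
                   method = method, exclude_self = exclude_self),
              class = "integration_result")
  })
  names(out) <- vapply(pairs, paste, "", collapse = ":")
  out
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("<integration_result> %s : %s (%s%s)\n", x$blocks[1L],
              x$blocks[2L], x$method,
              if (x$exclude_self) ", self excluded" else ""))
  cat(sprintf("  classes: %d   min %.4f   mean %.4f   max %.4f\n",
              sum(!is.na(x$per_class)), x$summary[["min"]],
              x$summary[["mean"]], x$summary[["max"]]))
  invisible(x)
}
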