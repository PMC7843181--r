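# The class-by-class similarity index of one block.  For classes p and q,
#
#   S(p, q) = #{ x in class p : x inside ellipsoid(p) AND ellipsoid(q) } / n_p
#
# i.e. the fraction of class p's samples in the overlap of the two
# confidence ellipsoids, normalised by class p's size.  S is asymmetric
# (the denominator follows p); the diagonal S(p, p) is the fraction of a
# class inside its own ellipsoid, a measure of aggregation that approaches
# the confidence level for Gaussian classes.

#' Similarity matrix of one block's score space
#'
#' Fits a confidence ellipsoid per class on the first `dims` score columns
#' and fills the full class-by-class matrix of overlap fractions.  Classes
#' with fewer than `dims + 2` samples cannot support a covariance estimate;
#' they are dropped from both rows and columns with a warning and listed in
#' the result.
#'
#' @param scores Numeric score matrix (samples x >= `dims` columns), e.g.
#'   from [pca_scores()].
#' @param labels Class label per row (factor or character).
#' @param level Ellipsoid confidence level in (0, 1).
#' @param dims Number of leading score dimensions to use (default 2, the
#'   usual plotting dimension; any value up to `ncol(scores)` is allowed).
#' @param block Optional block name carried through.
#' @return An object of class `similarity_matrix`: `values` (|d| x |d|,
#'   entries in `[0, 1]`), `counts` (integer numerators), `class_sizes`
#'   (denominators), `labels`, `level`, `dims`, `block`, `dropped`,
#'   `ellipsoids` (named list).
#' @examples
#' set.seed(1)
#' s <- matrix(rnorm(600), ncol = 2)
#' lab <- rep(c("a", "b", "c"), each = 100)
#' similarity_matrix(s, lab)$values
#' @export
similarity_matrix <- function(scores, labels, level = 0.95, dims = 2L,
                              block = NULL) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  if (length(labels) != nrow(scores))
    stop("length(labels) != nrow(scores)", call. = FALSE)
  dims <- as.integer(dims)
  if (dims < 1L || dims > ncol(scores))
    stop("'dims' must lie in 1..", ncol(scores), call. = FALSE)
  s <- scores[, seq_len(dims), drop = FALSE]
  idx <- split(seq_along(labels), labels, drop = TRUE)
  sizes <- lengths(idx)
  usable <- names(idx)[sizes >= dims + 2L]
  dropped <- setdiff(names(idx), usable)
  if (length(dropped))
    warning("class(es) with fewer than dims + 2 = ", dims + 2L,
            " samples dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  if (length(usable) < 2L)
    stop("fewer than 2 usable classes after the minimum-size filter",
         call. = FALSE)
  ells <- lapply(usable, function(cl)
    fit_ellipsoid(s[idx[[cl]], , drop = FALSE], level = level,
                  class_label = cl, block = block))
  names(ells) <- usable
  d <- length(usable)
  counts <- matrix(0L, d, d, dimnames = list(usable, usable))
  for (p in seq_len(d)) {
    pts <- s[idx[[usable[p]]], , drop = FALSE]
    inside_own <- ellipsoid_contains(ells[[p]], pts)
    for (q in seq_len(d)) {
      counts[p, q] <- if (q == p) sum(inside_own)
        else sum(inside_own & ellipsoid_contains(ells[[q]], pts))
    }
  }
  values <- counts / as.numeric(sizes[usable])
  structure(list(values = values, counts = counts,
                 class_sizes = sizes[usable], labels = usable,
                 level = level, dims = dims, block = block,
                 dropped = dropped, ellipsoids = ells),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix>%s %d classes, level = %.2f, dims = %d\n",
    if (!is.null(x$block)) paste0(" [", x$block, "]") else "",
    length(x$labels), x$level, x$dims))
  if (length(x$dropped))
    cat("  dropped classes:", paste(x$dropped, collapse = ", "), "\n")
  cat(sprintf("  diagonal (self-similarity): mean %.3f, range %.3f-%.3f\n",
              mean(diag(x$values)), min(diag(x$values)),
              max(diag(x$values))))
  invisible(x)
}

#' Write a similarity matrix to CSV (labels as header and first column)
#' @param sim A `similarity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  utils::write.csv(as.data.frame(sim$values), path, row.names = TRUE)
  invisible(path)
}

#' Per-block similarity analysis of a whole collection
#'
#' The full score-space chain for every numeric block: per-block PCA, the
#' shared retained-dimension rule at threshold `sigma`, score extraction at
#' each block's (rank-capped) retained dimension, and the class-by-class
#' similarity matrix on the first `dims` score columns.
#'
#' @param bc A preprocessed `block_collection` (no missing values; z-scored
#'   if correlation-scale PCA is wanted).
#' @param sigma Cumulative explained-variance threshold for [select_k()].
#' @param level Ellipsoid confidence level.
#' @param dims Ellipse analysis dimension (capped per block at the block's
#'   retained dimension).
#' @return An object of class `mcea_result`: `similarity` (named list of
#'   [similarity_matrix()] objects), `pca` (models), `k_selection`,
#'   `scores` (named list), and the parameters used.
#' @export
block_similarity <- function(bc, sigma = 0.8, level = 0.95, dims = 2L) {
  stopifnot(inherits(bc, "block_collection"))
  models <- fit_block_pca(bc)
  sel <- select_k(models, sigma = sigma)
  scores <- stats::setNames(vector("list", length(models)), names(models))
  sims <- stats::setNames(vector("list", length(models)), names(models))
  for (nm in names(models)) {
    k_b <- sel$table$k_extract[sel$table$block == nm]
    sc <- pca_scores(models[[nm]], block_data(bc, nm), k = k_b)
    scores[[nm]] <- sc
    sims[[nm]] <- similarity_matrix(sc, bc$class_labels, level = level,
                                    dims = min(dims, k_b), block = nm)
  }
  structure(list(similarity = sims, pca = models, k_selection = sel,
                 scores = scores, class_labels = bc$class_labels,
                 sigma = sigma, level = level, dims = dims),
            class = "mcea_result")
}

#' @export
print.mcea_result <- function(x, ...) {
  cat(sprintf("<mcea_result> %d blocks, sigma = %.2f, level = %.2f\n",
              length(x$similarity), x$sigma, x$level))
  print(x$k_selection)
  invisible(x)
}
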