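# Gaussian confidence ellipsoids in PCA score space.  For a class with
# score mean mu and covariance S, the region at confidence `level` is
# { x : (x - mu)' S^{-1} (x - mu) <= chi^2_k(level) }, the set a k-variate
# Gaussian occupies with probability `level`.  Membership is a squared
# Mahalanobis distance comparison; boundary points count as inside.

#' Fit a per-class confidence ellipsoid
#'
#' Centre and shape are the sample mean and sample covariance of the
#' class's scores; the squared radius is the chi-square quantile with `k`
#' degrees of freedom at `level`, so for Gaussian scores the ellipsoid
#' asymptotically contains a fraction `level` of the class.  Near-singular
#' covariances (condition number above 1e10) receive a small ridge
#' `1e-8 * trace/k` on the diagonal so that membership remains computable
#' for degenerate classes.
#'
#' @param scores Numeric matrix of class scores, `n_p` rows x `k` columns,
#'   with `n_p >= k + 2` so the covariance is estimable.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param class_label,block Optional identifiers carried through.
#' @return An object of class `confidence_ellipsoid`: `center`, `shape`
#'   (k x k covariance actually used), `level`, `radius2`, `k`, `n`,
#'   `class_label`, `block`, `ridged` (logical).
#' @examples
#' set.seed(1)
#' e <- fit_ellipsoid(matrix(rnorm(400), ncol = 2))
#' e$radius2                       # qchisq(0.95, 2) = 5.991...
#' @export
fit_ellipsoid <- function(scores, level = 0.95, class_label = NULL,
                          block = NULL) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  n <- nrow(scores)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)", call. = FALSE)
  if (n < k + 2L)
    stop("class too small for a ", k, "-D ellipsoid: n = ", n,
         " < k + 2 = ", k + 2L, call. = FALSE)
  center <- colMeans(scores)
  shape <- stats::cov(scores)
  ridged <- FALSE
  kap <- tryCatch(kappa(shape, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e10) {
    shape <- shape + diag(1e-8 * sum(diag(shape)) / k, k)
    ridged <- TRUE
  }
  structure(list(center = center, shape = shape, level = level,
                 radius2 = stats::qchisq(level, df = k), k = k, n = n,
                 class_label = class_label, block = block, ridged = ridged),
            class = "confidence_ellipsoid")
}

#' @export
print.confidence_ellipsoid <- function(x, ...) {
  cat(sprintf(
    "<confidence_ellipsoid>%s%s k = %d, level = %.2f, radius2 = %.3f, n = %d\n",
    if (!is.null(x$block)) paste0(" [", x$block, "]") else "",
    if (!is.null(x$class_label)) paste0(" class ", x$class_label) else "",
    x$k, x$level, x$radius2, x$n))
  invisible(x)
}

#' Ellipsoid membership of a set of points
#'
#' A point is inside when its squared Mahalanobis distance from the centre
#' is at most the ellipsoid's squared radius; points exactly on the
#' boundary count as inside.
#'
#' @param e A `confidence_ellipsoid`.
#' @param points Numeric matrix (or single vector) of dimension `e$k`.
#' @return Logical vector, one entry per row of `points`.
#' @export
ellipsoid_contains <- function(e, points) {
  stopifnot(inherits(e, "confidence_ellipsoid"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (ncol(points) != e$k)
    stop("points have dimension ", ncol(points), "; ellipsoid has k = ",
         e$k, call. = FALSE)
  stats::mahalanobis(points, e$center, e$shape) <= e$radius2
}

#' Overlap count between two class ellipsoids
#'
#' Counts the samples of class p that lie simultaneously inside their own
#' ellipsoid and inside class q's ellipsoid — the numerator of the
#' similarity index.  The count is taken over class p's samples only,
#' which is what makes the index asymmetric.
#'
#' @param e_p,e_q `confidence_ellipsoid` objects of equal dimension.
#' @param class_p_scores Score rows of class p (dimension `k`).
#' @return Integer count.
#' @export
overlap_count <- function(e_p, e_q, class_p_scores) {
  stopifnot(inherits(e_p, "confidence_ellipsoid"),
            inherits(e_q, "confidence_ellipsoid"))
  if (e_p$k != e_q$k)
    stop("ellipsoid dimensions differ: ", e_p$k, " vs ", e_q$k,
         call. = FALSE)
  sum(ellipsoid_contains(e_p, class_p_scores) &
      ellipsoid_contains(e_q, class_p_scores))
}
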