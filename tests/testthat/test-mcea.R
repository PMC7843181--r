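test_that("the 2-D ellipsoid radius is the chi-square quantile", {
  set.seed(21)
  e <- fit_ellipsoid(matrix(rnorm(2000), ncol = 2), level = 0.95)
  expect_equal(e$radius2, qchisq(0.95, 2))
  expect_equal(e$radius2, 5.991, tolerance = 1e-3)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.1)
  expect_error(fit_ellipsoid(matrix(rnorm(6), 3, 2)), "too small")
  expect_error(fit_ellipsoid(matrix(rnorm(20), 10, 2), level = 1),
               "level")
})

test_that("membership uses the squared Mahalanobis rule with closed boundary", {
  e <- structure(list(center = c(0, 0), shape = diag(2), level = 0.95,
                      radius2 = qchisq(0.95, 2), k = 2L, n = 100L,
                      class_label = NULL, block = NULL, ridged = FALSE),
                 class = "confidence_ellipsoid")
  expect_true(ellipsoid_contains(e, c(0, 0)))
  expect_false(ellipsoid_contains(e, c(3, 3)))      # squared distance 18
  r <- sqrt(e$radius2)
  expect_true(ellipsoid_contains(e, c(r, 0)))       # exactly on boundary
  expect_error(ellipsoid_contains(e, matrix(1, 2, 3)), "dimension")
})

test_that("vectorized membership equals a per-point quadratic-form loop", {
  set.seed(22)
  pts <- matrix(rnorm(400, sd = 2), ncol = 2)
  e <- fit_ellipsoid(matrix(rnorm(300), ncol = 2))
  fast <- ellipsoid_contains(e, pts)
  inv <- solve(e$shape)
  slow <- vapply(seq_len(nrow(pts)), function(i) {
    d <- pts[i, ] - e$center
    drop(t(d) %*% inv %*% d) <= e$radius2
  }, TRUE)
  expect_identical(fast, slow)
})

test_that("overlap counts match a hand brute-force on a small layout", {
  mk <- function(center) structure(
    list(center = center, shape = diag(2), level = 0.95, radius2 = 4,
         k = 2L, n = 10L, class_label = NULL, block = NULL,
         ridged = FALSE), class = "confidence_ellipsoid")
  e_p <- mk(c(0, 0)); e_q <- mk(c(1, 0))
  pts <- rbind(c(0, 0), c(1.5, 0), c(-1.5, 0), c(0, 1.9), c(5, 5))
  # by hand: inside e_p (d2 <= 4): rows 1-4; inside e_q: rows 1 (d2 = 1)
  # and 2 (d2 = 0.25); rows 3 (6.25), 4 (4.61), 5 (41) are outside e_q
  expect_equal(overlap_count(e_p, e_q, pts), 2L)
  expect_equal(overlap_count(e_p, e_p, pts),
               sum(ellipsoid_contains(e_p, pts)))
  e_far <- mk(c(100, 0))
  expect_equal(overlap_count(e_p, e_far, pts), 0L)
  e_3d <- structure(list(center = rep(0, 3), shape = diag(3), level = 0.95,
                         radius2 = 4, k = 3L, n = 10L, class_label = NULL,
                         block = NULL, ridged = FALSE),
                    class = "confidence_ellipsoid")
  expect_error(overlap_count(e_p, e_3d, pts), "differ")
})

test_that("similarity entries are counts over class size, in [0, 1]", {
  g <- gaussian_classes(rbind(c(0, 0), c(2, 0), c(8, 8)), n_per = 60,
                        seed = 23)
  sm <- similarity_matrix(g$scores, g$labels)
  expect_true(all(sm$values >= 0 & sm$values <= 1))
  # every value times its class size is an integer count
  recon <- sm$values * as.numeric(sm$class_sizes[rownames(sm$values)])
  expect_equal(recon, sm$counts, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(sm$counts)[1],
               sum(ellipsoid_contains(sm$ellipsoids[[1]],
                                      g$scores[g$labels == "c01", ])),
               ignore_attr = TRUE)
})

test_that("a duplicated class reproduces the self-similarity row exactly", {
  set.seed(24)
  a <- matrix(rnorm(200), ncol = 2)
  third <- matrix(rnorm(160, mean = 3), ncol = 2)
  scores <- rbind(a, a, third)
  labels <- c(rep("p", 100), rep("q", 100), rep("r", 80))
  sm <- similarity_matrix(scores, labels)
  expect_identical(sm$values["p", "q"], sm$values["p", "p"])
  expect_identical(sm$values["q", "p"], sm$values["q", "q"])
})

test_that("classes 50 pooled standard deviations apart never overlap", {
  g <- gaussian_classes(rbind(c(0, 0), c(50, 0)), n_per = 300, sd = 1,
                        seed = 25)
  sm <- similarity_matrix(g$scores, g$labels)
  expect_equal(sm$values["c01", "c02"], 0)
  expect_equal(sm$values["c02", "c01"], 0)
  expect_equal(sm$values["c01", "c01"], 0.95, tolerance = 0.03)
})

test_that("two samples of one distribution are mutually similar near the level", {
  set.seed(26)
  s <- matrix(rnorm(20000), ncol = 2)
  lab <- rep(c("p", "q"), each = 5000)
  sm <- similarity_matrix(s, lab)
  expect_equal(sm$values["p", "q"], 0.95, tolerance = 0.02)
  expect_equal(sm$values["p", "p"], 0.95, tolerance = 0.02)
})

test_that("the index is asymmetric for nested classes of unequal size", {
  set.seed(27)
  small <- matrix(rnorm(60, sd = 0.3), ncol = 2)          # tight class p
  big <- matrix(rnorm(600, sd = 3), ncol = 2)             # broad class q
  sm <- similarity_matrix(rbind(small, big),
                          c(rep("p", 30), rep("q", 300)))
  # p sits inside q's large ellipse; q mostly misses p's small one
  expect_gt(sm$values["p", "q"], sm$values["q", "p"])
})

test_that("similarity values are invariant under invertible affine maps", {
  g <- gaussian_classes(rbind(c(0, 0), c(1.5, 1), c(0, 2)), n_per = 150,
                        seed = 28)
  sm0 <- similarity_matrix(g$scores, g$labels)
  set.seed(29)
  for (rep in 1:3) {
    repeat {
      a <- matrix(rnorm(4), 2, 2)
      if (abs(det(a)) > 0.2) break
    }
    shift <- rnorm(2)
    mapped <- sweep(g$scores %*% a, 2, shift, "+")
    sm1 <- similarity_matrix(mapped, g$labels)
    expect_equal(sm1$values, sm0$values, tolerance = 1e-10)
  }
})

test_that("raising the confidence level never shrinks any similarity", {
  g <- gaussian_classes(rbind(c(0, 0), c(1, 0.5), c(2.5, 0)), n_per = 120,
                        seed = 30)
  levels <- c(0.8, 0.9, 0.95, 0.99)
  mats <- lapply(levels, function(lv)
    similarity_matrix(g$scores, g$labels, level = lv)$values)
  for (i in seq_along(levels)[-1])
    expect_true(all(mats[[i]] - mats[[i - 1]] >= -1e-12))
})

test_that("too-small classes are dropped from rows and columns with a warning", {
  g <- gaussian_classes(rbind(c(0, 0), c(2, 0)), n_per = 50, seed = 31)
  scores <- rbind(g$scores, matrix(rnorm(6), 3, 2))
  labels <- c(g$labels, rep("tiny", 3))
  expect_warning(sm <- similarity_matrix(scores, labels), "tiny")
  expect_equal(sm$dropped, "tiny")
  expect_equal(dim(sm$values), c(2L, 2L))
  # a single usable class cannot form a similarity matrix
  expect_error(
    suppressWarnings(similarity_matrix(
      rbind(matrix(rnorm(40), 20, 2), matrix(0, 2, 2)),
      c(rep("a", 20), "b", "b"))),
    "fewer than 2")
})
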