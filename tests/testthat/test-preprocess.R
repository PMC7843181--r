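test_that("rows with missing analysis values are deleted, labels kept aligned", {
  df <- data.frame(a = c(1, 2, NA, 4, 5), b = c(1, 2, 3, 4, 5),
                   label = letters[1:5])
  bc <- block_collection(df, tiny_config())
  out <- drop_missing(bc)
  expect_equal(n_samples(out$collection), 4L)
  expect_equal(out$report$removed, 3L)
  expect_equal(as.character(out$collection$class_labels),
               c("a", "b", "d", "e"))
})

test_that("missing description cells do not trigger row deletion", {
  df <- data.frame(a = 1:4 + 0, b = 1:4 + 0,
                   label = c("u", "u", "v", "v"), note = c("x", NA, "y", NA))
  cfg <- block_config(list(block_spec("X1", "independent", "a"),
                           block_spec("Y1", "dependent", "b"),
                           block_spec("D", "description",
                                      c("label", "note"))),
                      label_column = "label")
  bc <- block_collection(df, cfg)
  out <- drop_missing(bc)
  expect_equal(n_samples(out$collection), 4L)
  expect_length(out$report$removed, 0L)
})

test_that("box-plot filter removes exactly the out-of-fence rows", {
  # values [1,2,3,4,100]: Q1 = 2, Q3 = 4, IQR = 2, fences [-1, 7]
  df <- data.frame(a = c(1, 2, 3, 4, 100), b = rep(1:5 + 0),
                   label = rep(c("u", "v"), length.out = 5))
  bc <- block_collection(df, tiny_config())
  out <- iqr_outlier_filter(bc)
  expect_equal(out$report$removed, 5L)
  expect_equal(n_samples(out$collection), 4L)
  f <- out$report$fences
  expect_equal(f$q1[f$column == "a"], 2)
  expect_equal(f$q3[f$column == "a"], 4)
  expect_equal(f$upper[f$column == "a"], 7)
})

test_that("constant columns collapse their fences without removing anything", {
  df <- data.frame(a = rep(5, 5), b = 1:5 + 0,
                   label = rep(c("u", "v"), length.out = 5))
  bc <- block_collection(df, tiny_config())
  out <- iqr_outlier_filter(bc)
  expect_length(out$report$removed_by_column$a, 0L)
})

test_that("a row flagged by two columns is removed once, reported under both", {
  df <- data.frame(a = c(1, 2, 3, 4, 100), b = c(1, 2, 3, 4, 100),
                   label = rep(c("u", "v"), length.out = 5))
  bc <- block_collection(df, tiny_config())
  out <- iqr_outlier_filter(bc)
  expect_equal(out$report$removed, 5L)
  expect_equal(out$report$removed_by_column$a, 5L)
  expect_equal(out$report$removed_by_column$b, 5L)
})

test_that("z-score uses the sample standard deviation", {
  df <- data.frame(a = c(1, 2, 3), b = c(10, 20, 30), label = c("u", "v", "w"))
  bc <- block_collection(df, tiny_config())
  out <- zscore_normalize(bc)
  expect_equal(out$collection$data$a, c(-1, 0, 1))
  expect_equal(out$report$scaling$mu, c(2, 20))
  expect_equal(out$report$scaling$sigma, c(1, 10))
})

test_that("re-standardizing already-standardized data is a no-op", {
  set.seed(9)
  df <- data.frame(a = as.numeric(scale(rnorm(30))),
                   b = as.numeric(scale(rnorm(30))),
                   label = rep(c("u", "v"), 15))
  bc <- block_collection(df, tiny_config())
  out <- zscore_normalize(bc)
  expect_lt(max(abs(out$collection$data$a - df$a)), 1e-12)
})

test_that("zero-variance columns abort normalization with the column named", {
  df <- data.frame(a = c(7, 7, 7), b = 1:3 + 0, label = c("u", "v", "w"))
  bc <- block_collection(df, tiny_config())
  expect_error(zscore_normalize(bc), "a")
})

test_that("after the pipeline every column has mean 0 and sd 1", {
  bc <- generate_blocks(synth_config(n_classes = 5L,
                                     samples_per_class = 40L, seed = 2L))
  out <- preprocess(bc)
  x <- out$collection$data[, numeric_columns(out$collection)]
  expect_lt(max(abs(colMeans(x))), 1e-10)
  expect_lt(max(abs(vapply(x, sd, 0) - 1)), 1e-10)
  expect_true(out$report$n_input >= out$report$n_after_missing)
  expect_true(out$report$n_after_missing >= out$report$n_after_outliers)
})

test_that("pipeline equals missing-drop, one fence pass, then z-score", {
  bc <- generate_blocks(synth_config(n_classes = 4L,
                                     samples_per_class = 30L, seed = 3L))
  art <- inject_artifacts(bc, missing_rate = 0.01, outlier_rate = 0.02,
                          seed = 4L)
  auto <- preprocess(art$collection)
  s1 <- drop_missing(art$collection)
  s2 <- iqr_outlier_filter(s1$collection)
  s3 <- zscore_normalize(s2$collection)
  expect_equal(auto$collection$data, s3$collection$data)
})
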