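test_that("the default layout is 35 classes x 23 numeric columns", {
  bc <- generate_blocks(synth_config(samples_per_class = 10L, seed = 81L))
  expect_equal(n_samples(bc), 350L)
  expect_length(numeric_columns(bc), 23L)         # 14 + 4 + 5
  expect_equal(length(bc$class_set), 35L)
  expect_equal(block_names(bc, "independent"), c("climate", "altitude"))
  expect_equal(block_names(bc, "dependent"), "chemicals")
})

test_that("generation is a deterministic function of the seed", {
  cfg <- synth_config(n_classes = 6L, samples_per_class = 15L, seed = 82L)
  b1 <- generate_blocks(cfg)
  b2 <- generate_blocks(cfg)
  expect_identical(b1$data, b2$data)
  b3 <- generate_blocks(synth_config(n_classes = 6L,
                                     samples_per_class = 15L, seed = 83L))
  expect_false(identical(b1$data, b3$data))
  # the caller's RNG stream is not disturbed
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_blocks(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("uncoupled blocks have uncorrelated class means, coupled ones do not", {
  mean_r2 <- function(cpl) {
    cfg <- synth_config(seed = 84L, coupling = data.frame(
      source = "climate", target = "chemicals", strength = cpl))
    bc <- generate_blocks(cfg)
    m <- attr(bc, "class_means")
    mean(cor(m$climate, m$chemicals)^2)
  }
  expect_lt(mean_r2(0), 0.1)       # null E[r2] = 1/(d-1) ~ 0.03
  expect_gt(mean_r2(0.9), mean_r2(0))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_classes = 1L), "at least 2")
  expect_error(synth_config(coupling = data.frame(
    source = "climate", target = "chemicals", strength = 1.5)), "\\[0, 1\\]")
  expect_error(synth_config(coupling = data.frame(
    source = c("climate", "altitude"), target = "chemicals",
    strength = c(0.9, 0.9))), "exceeds 1")
  expect_error(synth_config(coupling = data.frame(
    source = "climate", target = "climate", strength = 0.5)), "itself")
  expect_error(synth_config(coupling = data.frame(
    source = "soil", target = "chemicals", strength = 0.5)), "unknown")
})

test_that("injected missing cells are counted exactly and flagged rows removed", {
  bc <- generate_blocks(synth_config(n_classes = 10L,
                                     samples_per_class = 35L, seed = 85L))
  art <- inject_artifacts(bc, missing_rate = 0.01, seed = 86L)
  n_cells <- n_samples(bc) * length(numeric_columns(bc))
  expect_equal(nrow(art$missing_cells), round(0.01 * n_cells))
  expect_equal(sum(is.na(art$collection$data[, numeric_columns(bc)])),
               nrow(art$missing_cells))
  # rate 0 is the identity
  same <- inject_artifacts(bc, missing_rate = 0, outlier_rate = 0)
  expect_identical(same$collection$data, bc$data)
  expect_error(inject_artifacts(bc, missing_rate = 0.7), "rates")
})

test_that("injected outliers are guaranteed victims of the box-plot filter", {
  bc <- generate_blocks(synth_config(n_classes = 8L,
                                     samples_per_class = 40L, seed = 87L))
  art <- inject_artifacts(bc, outlier_rate = 0.02, seed = 88L)
  out <- iqr_outlier_filter(art$collection)
  expect_true(all(art$outlier_rows %in% out$report$removed))
})

test_that("raising class separation drives the similarity matrix diagonal", {
  run <- function(within) {
    cfg <- synth_config(n_classes = 8L, samples_per_class = 60L,
                        within_sd = within, seed = 89L)
    bc <- generate_blocks(cfg)
    pp <- zscore_normalize(bc)$collection
    sm <- block_similarity(pp)$similarity$climate
    offdiag <- sm$values[row(sm$values) != col(sm$values)]
    c(off = mean(offdiag), diag = mean(diag(sm$values)))
  }
  tight <- run(0.2)    # well-separated classes
  loose <- run(2.0)    # heavily overlapping classes
  expect_lt(tight[["off"]], loose[["off"]])
  expect_equal(tight[["diag"]], 0.95, tolerance = 0.03)
})
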