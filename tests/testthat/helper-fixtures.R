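# Small fixture builders shared across the suite.  Everything is built in
# code; nothing is read from disk except files the helpers write to
# tempdir() themselves.

# a 6-row two-variable table with a label column
tiny_table <- function() {
  data.frame(a = c(1, 2, 3, 4, 5, 6),
             b = c(2.5, 3.5, 1.5, 4.5, 5.5, 6.5),
             label = c("u", "u", "v", "v", "w", "w"),
             stringsAsFactors = FALSE)
}

tiny_config <- function() {
  block_config(list(block_spec("X1", "independent", "a"),
                    block_spec("Y1", "dependent", "b"),
                    block_spec("D", "description", "label")),
               label_column = "label")
}

tiny_collection <- function() block_collection(tiny_table(), tiny_config())

write_tiny_csv <- function(df = tiny_table()) {
  path <- tempfile("tiny", fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# a collection with m numeric columns in one X block, built from a matrix
matrix_collection <- function(x, labels = rep(c("p", "q"),
                                              length.out = nrow(x))) {
  x <- as.matrix(x)
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  df <- as.data.frame(x)
  df$grp <- labels
  cfg <- block_config(list(block_spec("X1", "independent", colnames(x))),
                      label_column = "grp")
  block_collection(df, cfg)
}

# bare similarity_matrix object from a raw values matrix (for integration
# tests that need exact, hand-laid profiles)
fake_similarity <- function(values, block = "blk") {
  labels <- rownames(values)
  structure(list(values = values, counts = NULL,
                 class_sizes = stats::setNames(rep(100L, nrow(values)),
                                               labels),
                 labels = labels, level = 0.95, dims = 2L, block = block,
                 dropped = character(), ellipsoids = NULL),
            class = "similarity_matrix")
}

# gaussian score matrix with class labels, one cluster per class
gaussian_classes <- function(centers, n_per = 100L, sd = 1, seed = 1L) {
  set.seed(seed)
  k <- ncol(centers)
  s <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * k, sd = sd), n_per, k) +
      matrix(centers[i, ], n_per, k, byrow = TRUE)))
  list(scores = s,
       labels = rep(sprintf("c%02d", seq_len(nrow(centers))),
                    each = n_per))
}
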