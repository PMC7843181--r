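# Synthetic multi-block generator.  Emulates the structure the ellipse
# analysis assumes: samples fall into classes (locations); within each
# block every class is a Gaussian cluster; the BETWEEN-class structure of
# a target block can be coupled to that of source blocks.
#
# Class means have a low-rank factor structure: each class c carries a
# per-block latent vector u_b(c) in R^L (L = latent_dim), and the class
# mean in block b is u_b(c) %*% A_b with A_b a fixed unit-column L x m_b
# loading map drawn once per seed.  Coupling acts in latent space:
#
#   u_target(c) = sum_l rho_l * R_l u_source_l(c)
#                 + sqrt(1 - sum rho_l^2) * eta(c),
#
# with R_l a fixed random rotation and eta independent, so each strength
# rho is exactly the correlation between the source's (rotated) latent
# class structure and the target's.  Samples add isotropic within-class
# Gaussian noise to their class mean.  Coupling therefore lives at the
# class level — where the ellipse analysis looks for signal — and, because
# the between-class structure is rank-L, the leading L principal
# components of every block recover it; sample-level regressions see the
# same signal only attenuated through the within-class noise.

#' Configuration for the multi-block generator
#'
#' Defaults mirror the motivating field layout: 35 location classes and
#' three blocks of 14 (climate), 4 (altitude) and 5 (chemicals) variables,
#' with both independent blocks weakly coupled (0.35) to the dependent
#' one.  At the default noise ratio (`within_sd / between_sd` = 0.5) this
#' coupling puts ordinary regression of one chemical on the independent
#' blocks in the weak regime (leave-one-out R-squared around 0.1-0.2).
#'
#' @param n_classes Number of classes (default 35).
#' @param samples_per_class Rows per class (default 100).
#' @param block_dims Named integer vector of block dimensions.
#' @param roles Named character vector of block roles, aligned with
#'   `block_dims`.
#' @param coupling Data frame with columns `source`, `target`, `strength`
#'   (each strength in `[0, 1]`; the summed squared strengths into any one
#'   target must not exceed 1).
#' @param latent_dim Rank of the between-class structure (default 2,
#'   matching the default 2-D ellipse analysis).
#' @param between_sd Standard deviation of the latent class means
#'   (default 1).
#' @param within_sd Within-class sample noise (default 1).
#' @param label_column Name of the class-label column (default "county").
#' @param seed Integer seed; fixes the output bit-exactly.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 35L,
                         samples_per_class = 100L,
                         block_dims = c(climate = 14L, altitude = 4L,
                                        chemicals = 5L),
                         roles = c(climate = "independent",
                                   altitude = "independent",
                                   chemicals = "dependent"),
                         coupling = data.frame(
                           source = c("climate", "altitude"),
                           target = c("chemicals", "chemicals"),
                           strength = c(0.35, 0.35)),
                         latent_dim = 2L,
                         between_sd = 1,
                         within_sd = 1,
                         label_column = "county",
                         seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (samples_per_class < 1L) stop("samples_per_class must be >= 1",
                                   call. = FALSE)
  if (is.null(names(block_dims)) || any(block_dims < 1L))
    stop("'block_dims' must be a named vector of dims >= 1", call. = FALSE)
  if (!setequal(names(roles), names(block_dims)))
    stop("'roles' must name the same blocks as 'block_dims'", call. = FALSE)
  coupling <- as.data.frame(coupling)
  if (nrow(coupling)) {
    stopifnot(all(c("source", "target", "strength") %in% names(coupling)))
    bad <- setdiff(unique(c(coupling$source, coupling$target)),
                   names(block_dims))
    if (length(bad))
      stop("coupling refers to unknown block(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(coupling$strength < 0 | coupling$strength > 1))
      stop("coupling strengths must lie in [0, 1]", call. = FALSE)
    ss <- tapply(coupling$strength^2, coupling$target, sum)
    if (any(ss > 1 + 1e-12))
      stop("summed squared coupling into a target exceeds 1", call. = FALSE)
    if (any(coupling$source == coupling$target))
      stop("a block cannot be coupled to itself", call. = FALSE)
  }
  stopifnot(between_sd > 0, within_sd >= 0, latent_dim >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 block_dims = block_dims, roles = roles,
                 coupling = coupling, latent_dim = as.integer(latent_dim),
                 between_sd = between_sd,
                 within_sd = within_sd, label_column = label_column,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d classes x %d samples, seed %d\n",
              x$n_classes, x$samples_per_class, x$seed))
  cat("  blocks:", paste(sprintf("%s[%d,%s]", names(x$block_dims),
                                 x$block_dims, x$roles[names(x$block_dims)]),
                         collapse = " "), "\n")
  if (nrow(x$coupling))
    cat("  coupling:", paste(sprintf("%s->%s %.2f", x$coupling$source,
                                     x$coupling$target,
                                     x$coupling$strength),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic block collection
#'
#' Draws class means per block (coupled across blocks as configured, in an
#' order that puts sources before targets), adds within-class Gaussian
#' noise, and returns a ready-made `block_collection`.  Output is a
#' deterministic function of the config, including its seed.
#'
#' @param cfg A [synth_config()].
#' @return A `block_collection` with `n_classes * samples_per_class` rows;
#'   the true class means are attached as attribute `"class_means"` for
#'   parameter-recovery tests.
#' @export
generate_blocks <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  blocks <- names(cfg$block_dims)
  # topological order: sources before targets (couplings are acyclic by
  # construction in practice; a cycle is reported)
  order <- character()
  remaining <- blocks
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(b) {
      srcs <- cfg$coupling$source[cfg$coupling$target == b]
      all(srcs %in% order)
    }, TRUE)]
    if (!length(ready)) stop("coupling graph has a cycle", call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }

  d <- cfg$n_classes
  L <- cfg$latent_dim
  latents <- list()   # per-block d x L latent class coordinates
  means <- list()     # per-block d x m_b class means
  for (b in order) {
    m_b <- cfg$block_dims[[b]]
    edges <- cfg$coupling[cfg$coupling$target == b, , drop = FALSE]
    base <- matrix(0, d, L)
    for (i in seq_len(nrow(edges))) {
      src <- edges$source[i]
      rot <- qr.Q(qr(matrix(stats::rnorm(L * L), L, L)))  # random rotation
      base <- base + edges$strength[i] * (latents[[src]] %*% rot)
    }
    resid_scale <- sqrt(max(0, 1 - sum(edges$strength^2)))
    eta <- matrix(stats::rnorm(d * L, sd = cfg$between_sd), d, L)
    latents[[b]] <- base + resid_scale * eta
    a <- matrix(stats::rnorm(L * m_b), L, m_b)
    a <- sweep(a, 2L, sqrt(colSums(a^2)), "/")   # unit columns
    means[[b]] <- latents[[b]] %*% a
  }

  n <- d * cfg$samples_per_class
  class_id <- rep(seq_len(d), each = cfg$samples_per_class)
  lab <- sprintf("C%02d", class_id)
  cols <- list()
  specs <- list()
  for (b in blocks) {
    m_b <- cfg$block_dims[[b]]
    x <- means[[b]][class_id, , drop = FALSE] +
      matrix(stats::rnorm(n * m_b, sd = cfg$within_sd), n, m_b)
    colnames(x) <- paste0(b, "_", seq_len(m_b))
    cols[[b]] <- x
    specs[[b]] <- block_spec(b, cfg$roles[[b]], colnames(x))
  }
  df <- as.data.frame(do.call(cbind, cols))
  df[[cfg$label_column]] <- lab
  config <- block_config(specs, cfg$label_column)
  bc <- block_collection(df, config, quiet = TRUE)
  attr(bc, "class_means") <- means
  attr(bc, "class_latents") <- latents
  attr(bc, "config") <- config
  bc
}

#' Inject missing cells and outliers for preprocessing tests
#'
#' Blanks randomly chosen numeric cells at `missing_rate` and replaces
#' randomly chosen rows' cells with values far outside the Tukey fences at
#' `outlier_rate`, returning the ground truth of what was corrupted.
#' Injected outliers are placed at the column's upper fence plus ten fence
#' widths, which guarantees removal by [iqr_outlier_filter()] at the
#' default multiplier.
#'
#' @param bc A `block_collection`.
#' @param missing_rate Fraction of numeric cells to blank, in `[0, 0.5)`.
#' @param outlier_rate Fraction of rows to corrupt, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List with `collection`, `missing_cells` (data frame row/column)
#'   and `outlier_rows` (integer vector).
#' @export
inject_artifacts <- function(bc, missing_rate = 0, outlier_rate = 0,
                             seed = 1L) {
  stopifnot(inherits(bc, "block_collection"))
  if (missing_rate < 0 || missing_rate >= 0.5 ||
      outlier_rate < 0 || outlier_rate >= 0.5)
    stop("rates must lie in [0, 0.5)", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  cols <- numeric_columns(bc)
  n <- nrow(bc$data)
  outlier_rows <- integer()
  if (outlier_rate > 0) {
    outlier_rows <- sort(sample.int(n, max(1L, round(outlier_rate * n))))
    for (i in outlier_rows) {
      j <- sample(cols, 1L)
      v <- bc$data[[j]]
      q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7L)
      iqr <- max(q[2L] - q[1L], stats::sd(v, na.rm = TRUE), 1e-6)
      bc$data[i, j] <- q[2L] + 1.5 * iqr + 10 * iqr
    }
  }
  missing_cells <- data.frame(row = integer(), column = character(),
                              stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    total <- n * length(cols)
    pick <- sort(sample.int(total, round(missing_rate * total)))
    ri <- ((pick - 1L) %% n) + 1L
    ci <- cols[((pick - 1L) %/% n) + 1L]
    for (t in seq_along(pick)) bc$data[ri[t], ci[t]] <- NA_real_
    missing_cells <- data.frame(row = ri, column = ci,
                                stringsAsFactors = FALSE)
  }
  list(collection = bc, missing_cells = missing_cells,
       outlier_rows = outlier_rows)
}

# save/restore the global RNG state so generation is reproducible without
# disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
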