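# Rendering of the three standard views: a score scatter for one target
# class with both confidence ellipses and marginal density curves, a
# class-by-class similarity heatmap, and a radar chart comparing one
# class's similarity profile across blocks.  Figures are presentation
# only; every tested number comes from the CSV/JSON outputs.

ellipse_path <- function(e, n = 181L) {
  stopifnot(e$k == 2L)
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta), sin(theta)) * sqrt(e$radius2)
  ch <- chol(e$shape)
  xy <- t(e$center + t(ch) %*% circ)
  data.frame(x = xy[, 1L], y = xy[, 2L])
}

#' Target-class ellipse plot with marginal densities
#'
#' Scatter of the first two score dimensions: the target class against all
#' remaining samples, with the two 2-D confidence ellipses (target vs
#' rest) and, along the top and right margins, per-group density curves of
#' the first and second score dimension.  Point colour encodes class and
#' whether the point falls inside the target ellipse.
#'
#' @param scores Score matrix with at least 2 columns.
#' @param labels Class label per row.
#' @param target Target class label.
#' @param level Confidence level for both ellipses.
#' @param file Optional output path (`.png`/`.svg`/`.pdf`); written with
#'   `ggsave` when given.
#' @return The assembled plot (patchwork object), invisibly when `file`
#'   is given.
#' @export
render_ellipse_plot <- function(scores, labels, target, level = 0.95,
                                file = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L)
    stop("ellipse plot needs at least 2 score dimensions", call. = FALSE)
  labels <- as.character(labels)
  if (!target %in% labels)
    stop("class '", target, "' not present", call. = FALSE)
  s <- scores[, 1:2, drop = FALSE]
  is_t <- labels == target
  e_t <- fit_ellipsoid(s[is_t, , drop = FALSE], level = level,
                       class_label = target)
  e_r <- fit_ellipsoid(s[!is_t, , drop = FALSE], level = level,
                       class_label = "rest")
  inside_t <- ellipsoid_contains(e_t, s)
  df <- data.frame(pc1 = s[, 1L], pc2 = s[, 2L],
                   group = ifelse(is_t, target, "other"),
                   membership = interaction(
                     ifelse(is_t, target, "other"),
                     ifelse(inside_t, "inside", "outside")))
  main <- ggplot2::ggplot(df, ggplot2::aes(pc1, pc2)) +
    ggplot2::geom_point(ggplot2::aes(colour = membership),
                        alpha = 0.6, size = 0.9) +
    ggplot2::geom_path(data = ellipse_path(e_t),
                       ggplot2::aes(x, y), colour = "red") +
    ggplot2::geom_path(data = ellipse_path(e_r),
                       ggplot2::aes(x, y), colour = "blue") +
    ggplot2::labs(x = "PC1", y = "PC2", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
  top <- ggplot2::ggplot(df, ggplot2::aes(pc1, colour = group)) +
    ggplot2::geom_density() + ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
  right <- ggplot2::ggplot(df, ggplot2::aes(pc2,
                                            colour = group)) +
    ggplot2::geom_density() + ggplot2::coord_flip() +
    ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
  p <- top + patchwork::plot_spacer() + main + right +
    patchwork::plot_layout(ncol = 2L, widths = c(4, 1), heights = c(1, 4))
  save_or_return(p, file, width = 7, height = 7)
}

#' Similarity heatmap
#'
#' Class-by-class heatmap of one block's similarity matrix; the row is the
#' normalizing class p, so the matrix is drawn as is, without
#' symmetrization.  The diagonal carries the per-class aggregation values.
#'
#' @param sim A `similarity_matrix`.
#' @param file Optional output path.
#' @return ggplot object, invisibly when `file` is given.
#' @export
render_heatmap <- function(sim, file = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- as.data.frame(as.table(sim$values), stringsAsFactors = FALSE)
  names(df) <- c("p", "q", "S")
  df$p <- factor(df$p, levels = rev(sim$labels))
  df$q <- factor(df$q, levels = sim$labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(q, p,
                                        fill = S)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "S(p,q)",
                  title = sim$block %||% "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
  save_or_return(p, file, width = 7, height = 6)
}

#' Radar chart of one class's similarity profile across blocks
#'
#' One spoke per other class; the radial axis is INVERTED by default (1 at
#' the centre, 0 at the rim), so classes similar to the target plot near
#' the centre.  `standard_scale = TRUE` restores the conventional
#' orientation.
#'
#' @param target Target class label.
#' @param sims Named list of `similarity_matrix` objects (one per block).
#' @param standard_scale Use the conventional 0-at-centre radial scale.
#' @param file Optional output path.
#' @return ggplot object, invisibly when `file` is given.
#' @export
render_radar <- function(target, sims, standard_scale = FALSE,
                         file = NULL) {
  if (inherits(sims, "similarity_matrix")) sims <- list(sims)
  rows <- list()
  for (nm in seq_along(sims)) {
    sim <- sims[[nm]]
    if (!target %in% sim$labels)
      stop("class '", target, "' absent from block '",
           sim$block %||% nm, "'", call. = FALSE)
    others <- setdiff(sim$labels, target)
    rows[[nm]] <- data.frame(block = sim$block %||% paste0("block", nm),
                             class = others,
                             S = sim$values[target, others],
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$r <- if (standard_scale) df$S else 1 - df$S
  df$class <- factor(df$class, levels = sort(unique(df$class)))
  p <- ggplot2::ggplot(df, ggplot2::aes(class, r,
                                        group = block)) +
    ggplot2::geom_polygon(fill = NA, colour = "steelblue") +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::scale_y_continuous(
      limits = c(0, 1),
      labels = if (standard_scale) ggplot2::waiver()
               else function(b) format(1 - b)) +
    ggplot2::facet_wrap(~block) +
    ggplot2::labs(title = paste("similarity profile of", target),
                  y = if (standard_scale) "S(target, q)"
                      else "S(target, q), inverted", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
  save_or_return(p, file, width = 9, height = 4)
}

save_or_return <- function(p, file, width, height) {
  if (is.null(file)) return(p)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(p)
}

utils::globalVariables(c("pc1", "pc2", "membership", "x", "y",
                         "group", "q", "S", "r", "block", "class"))
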