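#' Define a variable block
#'
#' A block is a named, ordered group of columns measured on the same samples,
#' playing one of three roles: `"independent"` (predictor blocks such as
#' climate or altitude), `"dependent"` (response blocks such as leaf
#' chemistry), or `"description"` (sample metadata, one column of which
#' carries the class label used to partition samples).
#'
#' @param name Short block identifier (e.g. `"climate"`).
#' @param role One of `"independent"`, `"dependent"`, `"description"`.
#' @param columns Character vector of column names, in order. Must be
#'   non-empty and free of duplicates.
#' @return An object of class `block_spec`.
#' @seealso [block_config()], [read_block_table()]
#' @export
block_spec <- function(name, role = c("independent", "dependent", "description"),
                       columns) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(columns) || length(columns) == 0L)
    stop("block '", name, "': 'columns' must be a non-empty character vector",
         call. = FALSE)
  if (anyDuplicated(columns))
    stop("block '", name, "': duplicated column names within the block",
         call. = FALSE)
  structure(list(name = name, role = role, columns = columns),
            class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("<block_spec> %s (%s): %d column(s)\n", x$name, x$role,
              length(x$columns)))
  invisible(x)
}

#' Assemble a block configuration
#'
#' Collects [block_spec()] objects into the partition of a sample table into
#' independent-variable blocks, dependent-variable blocks and a description
#' block, and designates the class-label column.  Blocks must be
#' column-disjoint: no column may belong to two blocks.  If `label_column`
#' does not belong to any description block, a one-column description block
#' is appended automatically.
#'
#' @param blocks List of [block_spec()] objects.
#' @param label_column Name of the column holding the class label.
#' @return An object of class `block_config`: list with elements `blocks`
#'   and `label_column`.
#' @export
block_config <- function(blocks, label_column) {
  if (inherits(blocks, "block_spec")) blocks <- list(blocks)
  if (!length(blocks) || !all(vapply(blocks, inherits, TRUE, "block_spec")))
    stop("'blocks' must be a list of block_spec objects", call. = FALSE)
  stopifnot(is.character(label_column), length(label_column) == 1L)
  nms <- vapply(blocks, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicated block names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  all_cols <- unlist(lapply(blocks, `[[`, "columns"))
  if (anyDuplicated(all_cols)) {
    dup <- unique(all_cols[duplicated(all_cols)])
    stop("column(s) assigned to more than one block: ",
         paste(dup, collapse = ", "), " (blocks must be disjoint)",
         call. = FALSE)
  }
  desc_cols <- unlist(lapply(blocks[vapply(blocks, `[[`, "", "role") ==
                                      "description"], `[[`, "columns"))
  if (!label_column %in% desc_cols) {
    if (label_column %in% all_cols)
      stop("label column '", label_column,
           "' is assigned to a non-description block", call. = FALSE)
    blocks <- c(blocks, list(block_spec("description", "description",
                                        label_column)))
  }
  structure(list(blocks = blocks, label_column = label_column),
            class = "block_config")
}

#' Read a block configuration from YAML
#'
#' The expected layout is a `blocks` mapping (block name to `role` and
#' `columns`) plus a top-level `label` key naming the class-label column:
#'
#' ```yaml
#' blocks:
#'   climate:  {role: independent, columns: [sunshine, tmean, ...]}
#'   altitude: {role: independent, columns: [alt_min, alt_max, ...]}
#'   chemicals: {role: dependent, columns: [sugar, nicotine, ...]}
#'   description: {role: description, columns: [county]}
#' label: county
#' ```
#'
#' @param path Path to a YAML file.
#' @return A [block_config()] object.
#' @export
read_block_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$blocks) || is.null(y$label))
    stop("config must contain 'blocks' and 'label' entries", call. = FALSE)
  blocks <- lapply(names(y$blocks), function(nm) {
    b <- y$blocks[[nm]]
    if (is.null(b$role) || is.null(b$columns))
      stop("block '", nm, "' must declare 'role' and 'columns'", call. = FALSE)
    block_spec(nm, b$role, as.character(unlist(b$columns)))
  })
  block_config(blocks, as.character(y$label))
}

#' Write a block configuration to YAML
#'
#' @param config A [block_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_block_config <- function(config, path) {
  stopifnot(inherits(config, "block_config"))
  blocks <- lapply(config$blocks, function(b)
    list(role = b$role, columns = as.list(b$columns)))
  names(blocks) <- vapply(config$blocks, `[[`, "", "name")
  yaml::write_yaml(list(blocks = blocks, label = config$label_column), path)
  invisible(path)
}

#' Construct a block collection from a data frame
#'
#' The central container of the package: a sample table partitioned into
#' disjoint variable blocks, with a per-row class label taken from the
#' configured label column.  Numeric (independent/dependent) block columns
#' are coerced to numeric; values that fail to parse become `NA` and are
#' handled later by [drop_missing()].
#'
#' @param data A data frame containing at least every configured column.
#' @param config A [block_config()] object.
#' @param quiet Suppress the note about ignored extra columns.
#' @return An object of class `block_collection`: list with `data` (the
#'   configured columns, in block order), `blocks`, `label_column`,
#'   `class_labels` (factor) and `class_set` (its levels).
#' @export
block_collection <- function(data, config, quiet = FALSE) {
  stopifnot(is.data.frame(data), inherits(config, "block_config"))
  want <- unlist(lapply(config$blocks, `[[`, "columns"))
  missing_cols <- setdiff(want, names(data))
  if (length(missing_cols))
    stop("configured column(s) absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(data), want)
  if (length(extra) && !quiet)
    message("ignoring ", length(extra), " non-configured column(s): ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
  data <- data[, want, drop = FALSE]
  for (b in config$blocks) {
    if (b$role == "description") next
    for (cl in b$columns) {
      v <- data[[cl]]
      if (!is.numeric(v)) {
        parsed <- suppressWarnings(as.numeric(as.character(v)))
        n_bad <- sum(is.na(parsed) & !is.na(v) & trimws(as.character(v)) != "")
        if (n_bad && !quiet)
          message("column '", cl, "': ", n_bad,
                  " non-numeric value(s) set to NA")
        data[[cl]] <- parsed
      }
    }
  }
  lab <- data[[config$label_column]]
  keep <- !is.na(lab) & trimws(as.character(lab)) != ""
  if (!all(keep)) {
    warning(sum(!keep), " row(s) without a class label dropped", call. = FALSE)
    data <- data[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  lab <- factor(as.character(lab))
  rownames(data) <- NULL
  structure(list(data = data, blocks = config$blocks,
                 label_column = config$label_column,
                 class_labels = lab, class_set = levels(lab)),
            class = "block_collection")
}

#' Read a delimited sample table into a block collection
#'
#' The delimiter is inferred from the file extension (`.csv` comma,
#' `.tsv`/`.txt` tab) unless `delim` is given.  Empty cells and the literal
#' string `NA` are read as missing.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param config A [block_config()] object (or path to a YAML config).
#' @param delim Optional single-character delimiter override.
#' @inheritParams block_collection
#' @return A `block_collection`.
#' @export
read_block_table <- function(path, config, delim = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  if (is.character(config)) config <- read_block_config(config)
  if (is.null(delim)) {
    ext <- tolower(tools::file_ext(path))
    delim <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  block_collection(raw, config, quiet = quiet)
}

#' Write a block collection back to CSV
#'
#' Inverse of [read_block_table()]: writing and re-reading with the same
#' configuration reproduces the numeric values and labels exactly (values
#' are written at full precision).
#'
#' @param bc A `block_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(bc, path) {
  stopifnot(inherits(bc, "block_collection"))
  out <- bc$data
  for (j in names(out))           # full precision so round-trips are exact
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.block_collection <- function(x, ...) {
  roles <- vapply(x$blocks, `[[`, "", "role")
  cat(sprintf("<block_collection> %d samples, %d classes\n",
              nrow(x$data), length(x$class_set)))
  for (b in x$blocks)
    cat(sprintf("  %-12s %-12s %d column(s)\n", b$name, b$role,
                length(b$columns)))
  invisible(x)
}

# -- accessors -----------------------------------------------------------

#' Number of samples in a block collection
#' @param bc A `block_collection`.
#' @return Integer row count.
#' @export
n_samples <- function(bc) nrow(bc$data)

#' Block names, optionally filtered by role
#' @param bc A `block_collection`.
#' @param role Optional role filter.
#' @return Character vector of block names.
#' @export
block_names <- function(bc, role = NULL) {
  nms <- unname(vapply(bc$blocks, `[[`, "", "name"))
  if (is.null(role)) return(nms)
  nms[unname(vapply(bc$blocks, `[[`, "", "role")) %in% role]
}

#' Extract one block's data as a numeric matrix
#' @param bc A `block_collection`.
#' @param name Block name.
#' @return Numeric matrix (samples x block columns); description blocks are
#'   returned as a data frame.
#' @export
block_data <- function(bc, name) {
  i <- match(name, block_names(bc))
  if (is.na(i)) stop("unknown block: ", name, call. = FALSE)
  b <- bc$blocks[[i]]
  d <- bc$data[, b$columns, drop = FALSE]
  if (b$role == "description") return(d)
  as.matrix(d)
}

#' Names of all numeric (independent + dependent) analysis columns
#' @param bc A `block_collection`.
#' @return Character vector.
#' @export
numeric_columns <- function(bc) {
  unlist(lapply(bc$blocks, function(b)
    if (b$role %in% c("independent", "dependent")) b$columns else character()))
}

#' Validate the block partition and class structure
#'
#' Reports column counts per role (number of independent, dependent and
#' description variables), per-block sizes and per-class sample counts, and
#' fails when the class structure cannot support an ellipse analysis:
#' fewer than two distinct classes, or any class smaller than
#' `min_class_size`.
#'
#' @param bc A `block_collection`.
#' @param min_class_size Minimum rows required per class (default 1).
#' @return An object of class `partition_report` (list), invisibly printed
#'   with its own method.
#' @export
validate_partition <- function(bc, min_class_size = 1L) {
  stopifnot(inherits(bc, "block_collection"))
  roles <- vapply(bc$blocks, `[[`, "", "role")
  ncols <- vapply(bc$blocks, function(b) length(b$columns), 0L)
  counts <- table(bc$class_labels)
  if (length(counts) < 2L)
    stop("analysis infeasible: fewer than 2 distinct classes (|d| = ",
         length(counts), ")", call. = FALSE)
  small <- names(counts)[counts < min_class_size]
  if (length(small))
    stop("class(es) below minimum size ", min_class_size, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  structure(list(
    n = nrow(bc$data),
    n_classes = length(counts),
    columns_per_role = c(independent = sum(ncols[roles == "independent"]),
                         dependent = sum(ncols[roles == "dependent"]),
                         description = sum(ncols[roles == "description"])),
    blocks = data.frame(block = vapply(bc$blocks, `[[`, "", "name"),
                        role = roles, columns = ncols,
                        stringsAsFactors = FALSE),
    class_counts = as.data.frame(counts, responseName = "n",
                                 stringsAsFactors = FALSE)
  ), class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf("<partition_report> n = %d, |d| = %d classes\n", x$n,
              x$n_classes))
  cat(sprintf("  columns: %d independent, %d dependent, %d description\n",
              x$columns_per_role[["independent"]],
              x$columns_per_role[["dependent"]],
              x$columns_per_role[["description"]]))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}
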