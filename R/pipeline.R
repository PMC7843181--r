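# End-to-end orchestration: preprocess -> per-block PCA -> per-class
# ellipsoids and similarity matrices -> integrated cross-block
# correlations, with all numeric outputs written as CSV/JSON and a run
# manifest recording parameters and files.

#' One-call analysis of a block collection
#'
#' Runs the full chain in memory: optional preprocessing (missing-value
#' deletion, box-plot outlier removal, z-scoring), per-block PCA with the
#' shared retained-dimension rule, per-class confidence ellipsoids and
#' similarity matrices, and the pairwise integrated correlations.
#'
#' @param bc A `block_collection` (raw or already clean).
#' @param sigma Cumulative explained-variance threshold (default 0.8).
#' @param level Ellipsoid confidence level (default 0.95).
#' @param dims Ellipse analysis dimension (default 2).
#' @param fence Box-plot fence multiplier for preprocessing.
#' @param preprocess Logical; run the preprocessing chain first
#'   (default `TRUE`).
#' @param pairs Block pairs for integration (`NULL` = all).
#' @param exclude_self Drop S(p, p) from profiles before correlating.
#' @param method Correlation method for integration.
#' @return A list of class `mcea_analysis`: `preprocess` (report or
#'   `NULL`), `mcea` (the `mcea_result`), `integration` (list of
#'   `integration_result`).
#' @export
mcea_analysis <- function(bc, sigma = 0.8, level = 0.95, dims = 2L,
                          fence = 1.5, preprocess = TRUE, pairs = NULL,
                          exclude_self = TRUE,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  prep <- NULL
  if (preprocess) {
    pp <- mcea::preprocess(bc, fence = fence)
    bc <- pp$collection
    prep <- pp$report
  }
  res <- block_similarity(bc, sigma = sigma, level = level, dims = dims)
  integ <- integrate_blocks(res$similarity, pairs = pairs,
                            exclude_self = exclude_self, method = method)
  structure(list(preprocess = prep, mcea = res, integration = integ),
            class = "mcea_analysis")
}

#' @export
print.mcea_analysis <- function(x, ...) {
  cat("<mcea_analysis>\n")
  if (!is.null(x$preprocess)) print(x$preprocess)
  print(x$mcea$k_selection)
  for (ir in x$integration) print(ir)
  invisible(x)
}

#' Run the pipeline on files and write all outputs
#'
#' File-level front end used by the command-line interface: reads the
#' table and block configuration, runs [mcea_analysis()], and writes per
#' block a similarity CSV plus a JSON sidecar of raw counts and dropped
#' classes, per pair an integration JSON and per-class CSV, and a
#' `manifest.json` echoing the parameters and listing every file written.
#'
#' @param data Path to the CSV/TSV table, or a `block_collection`.
#' @param config Path to the YAML block config, or a `block_config`
#'   (ignored when `data` is already a collection).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer seed recorded in the manifest and set
#'   before the run (the analysis itself is deterministic; the seed
#'   matters only if stochastic steps are added around it).
#' @inheritParams mcea_analysis
#' @return The run manifest (class `run_manifest`), invisibly.
#' @export
run_pipeline <- function(data, config = NULL, out_dir = ".", sigma = 0.8,
                         level = 0.95, dims = 2L, fence = 1.5,
                         preprocess = TRUE, pairs = NULL,
                         exclude_self = TRUE, method = "pearson",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_path <- NA_character_
  if (inherits(data, "block_collection")) {
    bc <- data
  } else {
    input_path <- data
    bc <- read_block_table(data, config)
  }
  params <- list(sigma = sigma, level = level, dims = dims, fence = fence,
                 preprocess = preprocess, exclude_self = exclude_self,
                 method = method, seed = seed)
  files <- character()
  stage <- "preprocess"
  manifest_path <- file.path(out_dir, "manifest.json")
  res <- tryCatch({
    ana <- mcea_analysis(bc, sigma = sigma, level = level, dims = dims,
                         fence = fence, preprocess = preprocess,
                         pairs = pairs, exclude_self = exclude_self,
                         method = method)
    stage <- "write"
    for (nm in names(ana$mcea$similarity)) {
      sim <- ana$mcea$similarity[[nm]]
      f <- file.path(out_dir, paste0("similarity_", nm, ".csv"))
      write_similarity(sim, f)
      g <- file.path(out_dir, paste0("similarity_", nm, "_counts.json"))
      jsonlite::write_json(list(block = nm, counts = sim$counts,
                                class_sizes = as.list(sim$class_sizes),
                                dropped = sim$dropped, level = sim$level,
                                dims = sim$dims),
                           g, auto_unbox = TRUE, digits = NA)
      files <- c(files, f, g)
    }
    kf <- file.path(out_dir, "k_selection.csv")
    utils::write.csv(ana$mcea$k_selection$table, kf, row.names = FALSE)
    files <- c(files, kf)
    for (nm in names(ana$integration)) {
      ir <- ana$integration[[nm]]
      slug <- gsub(":", "_", nm, fixed = TRUE)
      f <- file.path(out_dir, paste0("integration_", slug, ".json"))
      jsonlite::write_json(list(blocks = ir$blocks,
                                summary = as.list(ir$summary),
                                method = ir$method,
                                exclude_self = ir$exclude_self),
                           f, auto_unbox = TRUE, digits = NA)
      g <- file.path(out_dir, paste0("integration_", slug, "_classes.csv"))
      utils::write.csv(data.frame(class = names(ir$per_class),
                                  correlation = unname(ir$per_class)),
                       g, row.names = FALSE)
      files <- c(files, f, g)
    }
    ana
  }, error = function(e) e)

  ok <- !inherits(res, "error")
  manifest <- structure(list(
    input = input_path, out_dir = out_dir, parameters = params,
    package_version = as.character(utils::packageVersion("mcea")),
    success = ok,
    failed_stage = if (ok) NA_character_ else stage,
    error = if (ok) NA_character_ else conditionMessage(res),
    files = basename(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!ok) stop("pipeline failed at stage '", stage, "': ",
                conditionMessage(res), call. = FALSE)
  attr(manifest, "analysis") <- res
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s (%d files in %s)\n",
              if (x$success) "success" else paste("FAILED at",
                                                  x$failed_stage),
              length(x$files), x$out_dir))
  invisible(x)
}
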