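#' Build a tensor from a long-format table
#'
#' The long format has `D` integer index columns (1-based) followed by one
#' value column; rows may arrive in any order but every cell must be present
#' exactly once.
#'
#' @param df Data frame with `D + 1` columns (indices then value), or the
#'   path of a comma-delimited file with headers.
#' @param dims Optional shape; inferred as the per-column index maxima when
#'   omitted.
#' @return Dense numeric array.
#' @export
tensor_from_long <- function(df, dims = NULL) {
  if (is.character(df)) df <- utils::read.csv(df)
  df <- as.data.frame(df)
  D <- ncol(df) - 1L
  if (D < 2L) stop("long format needs at least two index columns plus a value")
  idx <- as.matrix(df[, seq_len(D), drop = FALSE])
  if (any(idx != round(idx)) || any(idx < 1)) stop("indices must be positive integers")
  idx <- matrix(as.integer(idx), ncol = D)
  vals <- df[[D + 1L]]
  if (!is.numeric(vals) || any(!is.finite(vals))) stop("non-numeric or non-finite value entries")
  if (is.null(dims)) dims <- apply(idx, 2L, max)
  dims <- as.integer(dims)
  if (any(idx > matrix(dims, nrow(idx), D, byrow = TRUE))) stop("index exceeds dims")
  n <- prod(dims)
  mult <- cumprod(c(1L, dims[-D]))
  lin <- as.vector((idx - 1L) %*% mult) + 1L
  if (anyDuplicated(lin)) stop("duplicate cell in long-format input")
  if (length(lin) < n) stop("incomplete tensor: ", n - length(lin), " cell(s) missing")
  out <- numeric(n)
  out[lin] <- as.double(vals)
  array(out, dim = dims)
}

#' Convert a tensor to a long-format tibble
#'
#' @param x Dense numeric array.
#' @return Tibble with 1-based index columns `i1..iD` and a `value` column.
#' @export
tensor_to_long <- function(x) {
  dims <- dim(x)
  idx <- do.call(expand.grid, lapply(dims, seq_len))
  names(idx) <- paste0("i", seq_along(dims))
  out <- tibble::as_tibble(idx)
  out$value <- as.vector(x)
  out
}

#' Read a tensor from disk
#'
#' @param path File path.
#' @param format `"long"` (comma-delimited long table) or `"dense"` (an RDS
#'   array container written by [write_tensor()]).
#' @param dims Optional shape for the long format.
#' @return Dense numeric array.
#' @export
read_tensor <- function(path, format = c("long", "dense"), dims = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "long") return(tensor_from_long(path, dims))
  x <- readRDS(path)
  as_tensor(x)
}

#' Write a tensor to disk
#'
#' @param x Dense numeric array.
#' @param path Output path.
#' @param format See [read_tensor()].
#' @return `path`, invisibly.
#' @export
write_tensor <- function(x, path, format = c("long", "dense")) {
  format <- match.arg(format)
  if (format == "long") {
    utils::write.csv(tensor_to_long(x), path, row.names = FALSE)
  } else {
    saveRDS(x, path)
  }
  invisible(path)
}

write_labels <- function(labels, dir, prefix = "labels") {
  paths <- character(length(labels))
  for (d in seq_along(labels)) {
    paths[d] <- file.path(dir, sprintf("%s_mode%d.csv", prefix, d))
    utils::write.csv(data.frame(index = seq_along(labels[[d]]),
                                label = labels[[d]]),
                     paths[d], row.names = FALSE)
  }
  invisible(paths)
}

read_labels <- function(dir, prefix = "labels") {
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_mode[0-9]+\\.csv$"),
                           full.names = TRUE))
  if (!length(files)) stop("no label tables under ", dir)
  ord <- order(as.integer(sub(".*_mode([0-9]+)\\.csv$", "\\1", files)))
  lapply(files[ord], function(f) utils::read.csv(f)$label)
}

#' Compare two label-table directories by ARI
#'
#' Reads per-mode label tables (as written by [coco_run()] or
#' [write_labels()]) from two directories and reports the adjusted Rand
#' index per mode.
#'
#' @param dir_a,dir_b Directories holding `labels_mode<d>.csv` tables.
#' @param prefix_a,prefix_b File-name prefixes.
#' @return Tibble with columns `mode`, `ari`.
#' @export
evaluate_labels <- function(dir_a, dir_b, prefix_a = "labels",
                            prefix_b = "labels") {
  la <- read_labels(dir_a, prefix_a)
  lb <- read_labels(dir_b, prefix_b)
  if (length(la) != length(lb)) stop("mode count mismatch")
  tibble::tibble(mode = seq_along(la),
                 ari = vapply(seq_along(la), function(d) {
                   adjusted_rand_index(la[[d]], lb[[d]])
                 }, 0))
}

#' Run the full co-clustering pipeline and write artifacts
#'
#' Reads the input tensor, builds weights, fits the eBIC-tuned path and
#' writes: the weights edge table, the path summary, the per-mode label
#' tables at the selected gamma, the co-cluster means, and a reproducibility
#' record (config echo, seed, package version, wall time). Configuration may
#' be given as a YAML file path or a named list with entries `input`
#' (path), `input_format`, `output` (directory), `seed`, `grid_size`,
#' `gammas`, plus optional `weights` and `solver` sublists passed to
#' [weight_config()] and [solver_config()].
#'
#' @param config Named list or YAML file path.
#' @return Invisibly, the fitted `"coco"` object.
#' @export
coco_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$input), !is.null(config$output))
  t0 <- proc.time()[["elapsed"]]
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  x <- read_tensor(config$input,
                   format = if (is.null(config$input_format)) "long" else config$input_format)
  wcfg <- do.call(weight_config, as.list(config$weights %||% list()))
  scfg <- do.call(solver_config, as.list(config$solver %||% list()))
  gammas <- if (!is.null(config$gammas)) sort(as.double(config$gammas)) else NULL
  grid_size <- if (is.null(config$grid_size)) 30L else as.integer(config$grid_size)
  res <- coco(x, weights = wcfg, gammas = gammas, grid_size = grid_size,
              control = scfg)
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(graph_edge_table(res$path$graph),
                   file.path(out, "weights.csv"), row.names = FALSE)
  utils::write.csv(res$path$summary, file.path(out, "path_summary.csv"),
                   row.names = FALSE)
  write_labels(res$clustering$labels, out)
  write_tensor(res$clustering$means, file.path(out, "co_cluster_means.csv"),
               format = "long")
  record <- list(seed = seed,
                 config = config,
                 gamma_star = res$gamma_star,
                 package_version = as.character(utils::packageVersion("cocotensor")),
                 wall_time_s = proc.time()[["elapsed"]] - t0)
  yaml::write_yaml(record, file.path(out, "run_record.yaml"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
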