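# Delimited-text readers/writers for every exchange format the pipeline
# uses. Everything is TSV with a header row, UTF-8.

#' Write and read item responses
#'
#' Respondents x items table as tab-delimited text with a header row of
#' item labels.
#'
#' @param data An [item_response_matrix] (or matrix / data frame).
#' @param path File path.
#' @return `read_responses()` returns an [item_response_matrix];
#'   `write_responses()` returns `path` invisibly.
#' @export
write_responses <- function(data, path) {
  data <- as_item_response_matrix(data)
  utils::write.table(data$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  item_response_matrix(as.matrix(x))
}

#' Write and read a square correlation matrix
#'
#' Tab-delimited square matrix with variable labels as both header row and
#' first column — the format needed to ingest an externally published
#' correlation matrix. The sample size travels in a sidecar file
#' `<path>.meta` (`n: <int>`), or can be passed explicitly on read.
#'
#' @param corr A [correlation_matrix].
#' @param path File path.
#' @param n Sample size override on read; default taken from the sidecar
#'   when present.
#' @param method Method tag to record on read.
#' @return `read_correlation_matrix()` returns a [correlation_matrix].
#' @export
write_correlation_matrix <- function(corr, path) {
  stopifnot(inherits(corr, "correlation_matrix"))
  m <- corr$matrix
  df <- data.frame(item = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.na(corr$n))
    writeLines(paste0("n: ", corr$n), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_correlation_matrix
#' @export
read_correlation_matrix <- function(path, n = NULL,
                                    method = "user_supplied") {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  labels <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- labels
  if (is.null(n)) {
    meta <- paste0(path, ".meta")
    if (file.exists(meta)) {
      lines <- readLines(meta)
      hit <- grep("^n\\s*:", lines, value = TRUE)
      if (length(hit)) n <- as.integer(sub("^n\\s*:\\s*", "", hit[1]))
    }
  }
  correlation_matrix(m, n = if (is.null(n)) NA_integer_ else n,
                     method = method, labels = labels)
}

#' Write a network as a square weighted-adjacency matrix
#'
#' @param net A `network_model` or `true_network`.
#' @param path File path.
#' @export
write_network_matrix <- function(net, path) {
  w <- if (inherits(net, "true_network")) net$partial else net$weights
  df <- data.frame(item = rownames(w), w, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a network as a long-format edge list
#'
#' Columns `item_a`, `item_b`, `weight`, sorted by absolute weight
#' descending.
#'
#' @param net A `network_model` or `true_network`.
#' @param path File path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(edge_list(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write a community partition
#'
#' Two-column tab-delimited text: `item`, `community`.
#'
#' @param partition A [community_partition].
#' @param path File path.
#' @return `read_partition()` returns a [community_partition].
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(item = names(partition),
               community = unclass(partition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE,
                         colClasses = "character")
  community_partition(x[[1]], x[[2]])
}

#' Serialize a synthetic spec to a plain-text config
#'
#' `key: value` lines (vectors comma-separated); thresholds are written
#' per item as `threshold.<label>`.
#'
#' @param spec A [synthetic_spec()].
#' @param path File path.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  kv <- c(
    paste0("n: ", spec$n),
    paste0("community_sizes: ", paste(spec$community_sizes, collapse = ",")),
    paste0("category_counts: ", paste(spec$category_counts, collapse = ",")),
    paste0("category_start: ", paste(spec$category_start, collapse = ",")),
    paste0("density: ", spec$density),
    paste0("weight_range: ", paste(spec$weight_range, collapse = ",")),
    paste0("negative_fraction: ", spec$negative_fraction),
    paste0("preset: ", spec$preset),
    paste0("labels: ", paste(spec$labels, collapse = ",")),
    if (!is.null(spec$seed)) paste0("seed: ", spec$seed),
    vapply(spec$labels, function(l)
      paste0("threshold.", l, ": ",
             paste(format(spec$thresholds[[l]], digits = 10),
                   collapse = ",")),
      character(1)))
  writeLines(kv, path)
  invisible(path)
}

# Parse "key: value" lines into a named list of character values.
.read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  setNames(as.list(vals), keys)
}
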