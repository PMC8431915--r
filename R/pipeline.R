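#' Cronbach's alpha of a set of items
#'
#' `alpha = (k/(k-1)) * (1 - sum(item variances) / variance(sum score))`.
#' Undefined (NA) for fewer than two items or a constant sum score.
#'
#' @param values Respondents x items numeric matrix.
#' @return Scalar alpha, or `NA` when undefined.
#' @export
cronbach_alpha <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2L) return(NA_real_)
  total_var <- stats::var(rowSums(values))
  if (!is.finite(total_var) || total_var == 0) return(NA_real_)
  (k / (k - 1)) * (1 - sum(apply(values, 2, stats::var)) / total_var)
}

#' Descriptive statistics per item and per community scale
#'
#' Item means and standard deviations, plus per community the sum score's
#' mean and SD and Cronbach's alpha (reported `NA` for single-item
#' communities).
#'
#' @param data An [item_response_matrix] (or matrix / data frame).
#' @param partition A [community_partition] covering every item.
#' @return List with data frames `items` (`item`, `community`, `mean`,
#'   `sd`) and `scales` (`community`, `n_items`, `mean`, `sd`, `alpha`).
#' @export
descriptives <- function(data, partition) {
  data <- as_item_response_matrix(data)
  comm <- .node_communities(data$labels, partition)
  items <- data.frame(item = data$labels,
                      community = comm,
                      mean = colMeans(data$values),
                      sd = apply(data$values, 2, stats::sd),
                      row.names = NULL, stringsAsFactors = FALSE)
  groups <- unique(comm)
  scales <- do.call(rbind, lapply(groups, function(g) {
    v <- data$values[, comm == g, drop = FALSE]
    total <- rowSums(v)
    data.frame(community = g, n_items = ncol(v),
               mean = mean(total), sd = stats::sd(total),
               alpha = cronbach_alpha(v),
               stringsAsFactors = FALSE)
  }))
  rownames(scales) <- NULL
  list(items = items, scales = scales)
}

#' Sample-size advisory for a partial-correlation network
#'
#' A p-node Gaussian graphical model has `p(p-1)/2` candidate edges and
#' `p(p+1)/2` free parameters (edges plus node variances); the
#' three-respondents-per-parameter rule of thumb gives the advised minimum
#' sample.
#'
#' @param p Number of nodes.
#' @return List with `nodes`, `candidate_edges`, `free_parameters`,
#'   `minimum_n`.
#' @export
sample_size_advisory <- function(p) {
  p <- as.integer(p)
  stopifnot(p >= 1L)
  list(nodes = p,
       candidate_edges = (p * (p - 1L)) %/% 2L,
       free_parameters = (p * (p + 1L)) %/% 2L,
       minimum_n = 3L * ((p * (p + 1L)) %/% 2L))
}

#' Network with one community collapsed to its total score
#'
#' Replaces the items of one community by their respondent-wise sum score
#' and re-runs the full estimation (Spearman, PD repair, EBIC graphical
#' lasso) on the reduced variable set — e.g. a total-uncertainty node
#' alongside the individual anxiety items. The total node takes the
#' position of the collapsed community's first item.
#'
#' @param data An [item_response_matrix] (or matrix / data frame).
#' @param partition A [community_partition].
#' @param collapse Community label to collapse (>= 2 items).
#' @param label Label for the total-score node; default
#'   `"<collapse>_total"`.
#' @param gamma,n_points,min_ratio,floor,tol,max_iter Estimation settings.
#' @return A `network_model` on `p - k + 1` nodes.
#' @export
aggregate_community_network <- function(data, partition, collapse,
                                        label = paste0(collapse, "_total"),
                                        gamma = 0.5, n_points = 100L,
                                        min_ratio = 0.01, floor = 1e-4,
                                        tol = 1e-6, max_iter = 200L) {
  data <- as_item_response_matrix(data)
  comm <- .node_communities(data$labels, partition)
  in_comm <- comm == collapse
  if (sum(in_comm) < 2L)
    stop("community ", collapse, " has fewer than 2 items; nothing to collapse")
  total <- rowSums(data$values[, in_comm, drop = FALSE])
  first <- which(in_comm)[1]
  keep <- which(!in_comm)
  new_order <- sort(c(first, keep))
  values <- matrix(0L, nrow(data$values), length(new_order))
  new_labels <- character(length(new_order))
  for (i in seq_along(new_order)) {
    j <- new_order[i]
    if (j == first) {
      values[, i] <- as.integer(total)
      new_labels[i] <- label
    } else {
      values[, i] <- data$values[, j]
      new_labels[i] <- data$labels[j]
    }
  }
  colnames(values) <- new_labels
  .fit_pipeline(values,
                .estimation_settings(gamma, n_points, min_ratio, floor,
                                     tol, max_iter))
}

#' Configure a full network analysis
#'
#' Exactly one input mode must be active: raw `responses`, or a
#' `correlation` matrix with its sample size `n` (in which case
#' predictability and all bootstraps are skipped with explicit notices).
#' File paths and in-memory objects are both accepted.
#'
#' @param responses Item responses: path, matrix/data frame or
#'   [item_response_matrix].
#' @param correlation Correlation matrix: path or [correlation_matrix].
#' @param n Sample size for correlation input (or rely on the sidecar
#'   metadata of the file).
#' @param partition Partition: path, [community_partition], or `NULL` for
#'   the canonical instrument partition when the labels match it.
#' @param gamma EBIC hyperparameter; default 0.5.
#' @param n_points,min_ratio Penalty-path settings.
#' @param pd_floor Eigenvalue floor for the PD repair.
#' @param bootstrap Run bootstrap diagnostics (responses mode only)?
#' @param B Bootstrap replicates; default 2000.
#' @param seed Integer seed for all bootstrap resampling.
#' @param drop_fractions Case-dropping grid; default 0.1..0.7 by 0.1.
#' @param r_threshold CS-coefficient correlation threshold; default 0.7.
#' @param alpha Difference-test significance level; default 0.05.
#' @param collapse Community to collapse for the secondary total-score
#'   network, or `NULL` to skip.
#' @param out_dir Output directory for all artifacts, or `NULL` to skip
#'   writing.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(responses = NULL, correlation = NULL, n = NULL,
                            partition = NULL, gamma = 0.5,
                            n_points = 100L, min_ratio = 0.01,
                            pd_floor = 1e-4, bootstrap = FALSE, B = 2000L,
                            seed = NULL,
                            drop_fractions = seq(0.1, 0.7, by = 0.1),
                            r_threshold = 0.7, alpha = 0.05,
                            collapse = NULL, out_dir = NULL) {
  if (is.null(responses) == is.null(correlation))
    stop("exactly one input mode must be active: `responses` or `correlation`")
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (isTRUE(bootstrap) && B < 100L)
    stop("`B` must be >= 100 when bootstraps are requested")
  structure(list(responses = responses, correlation = correlation, n = n,
                 partition = partition, gamma = gamma, n_points = n_points,
                 min_ratio = min_ratio, pd_floor = pd_floor,
                 bootstrap = isTRUE(bootstrap), B = as.integer(B),
                 seed = seed, drop_fractions = drop_fractions,
                 r_threshold = r_threshold, alpha = alpha,
                 collapse = collapse, out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis config from plain text
#'
#' `key: value` lines mirroring the arguments of [analysis_config()]
#' (comma-separated lists for vectors; `#` comments allowed). Values given
#' in `overrides` take precedence over the file.
#'
#' @param path Config file path.
#' @param ... Overrides passed on to [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_config <- function(path, ...) {
  kv <- .read_keyvalue(path)
  num <- function(x) as.numeric(strsplit(x, ",")[[1]])
  parsed <- list()
  for (key in names(kv)) {
    v <- kv[[key]]
    parsed[[key]] <- switch(key,
      responses = , correlation = , partition = , collapse = ,
      out_dir = v,
      n = , B = , seed = , n_points = as.integer(v),
      gamma = , min_ratio = , pd_floor = , r_threshold = ,
      alpha = as.numeric(v),
      drop_fractions = num(v),
      bootstrap = toupper(v) %in% c("TRUE", "YES", "1"),
      stop("unknown config key: ", key))
  }
  overrides <- list(...)
  do.call(analysis_config, modifyList(parsed, overrides))
}

.load_partition <- function(partition, labels) {
  if (is.null(partition)) {
    if (all(labels %in% instrument_labels()))
      return(default_partition())
    stop("no partition supplied and labels are not the canonical instrument items")
  }
  if (inherits(partition, "community_partition")) return(partition)
  if (is.character(partition) && length(partition) == 1L &&
      file.exists(partition))
    return(read_partition(partition))
  if (!is.null(names(partition)))
    return(community_partition(names(partition), partition))
  stop("cannot interpret `partition`")
}

#' Run the full network analysis pipeline
#'
#' Executes, in order: input loading, descriptives, Spearman correlation
#' (or ingestion of a supplied matrix), positive-definiteness repair, EBIC
#' graphical-lasso network selection, centralities and predictability, the
#' secondary collapsed-community network, and bootstrap robustness
#' diagnostics — writing every table as delimited text plus a run manifest
#' when `out_dir` is set. In correlation input mode the stages that need
#' raw responses (descriptives, predictability, aggregate network,
#' bootstraps) are skipped with explicit notices.
#'
#' Any stage failure aborts with a stage-tagged error; when an output
#' directory is set, a `FAILED` marker naming the stage is flushed there.
#'
#' @param config An [analysis_config()].
#' @return An object of class `report_bundle` with all computed
#'   components, the notices, and the run manifest.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  notices <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- input ----------------------------------------------------------
  mode <- if (!is.null(config$responses)) "responses" else "correlation"
  data <- NULL
  if (mode == "responses") {
    data <- stage("load_responses", {
      r <- config$responses
      if (is.character(r) && length(r) == 1L) read_responses(r)
      else as_item_response_matrix(r)
    })
    labels <- data$labels
  } else {
    corr_in <- stage("load_correlation", {
      cc <- config$correlation
      cc <- if (is.character(cc) && length(cc) == 1L)
        read_correlation_matrix(cc, n = config$n)
      else if (inherits(cc, "correlation_matrix")) cc
      else correlation_matrix(cc, n = if (is.null(config$n)) NA_integer_
                              else config$n)
      if (!is.null(config$n)) cc$n <- as.integer(config$n)
      if (is.na(cc$n))
        stop("correlation input mode requires a sample size `n`")
      cc
    })
    labels <- corr_in$labels
  }
  partition <- stage("load_partition",
                     .load_partition(config$partition, labels))

  # --- descriptives ---------------------------------------------------
  desc <- NULL
  if (mode == "responses") {
    desc <- stage("descriptives", descriptives(data, partition))
  } else {
    notices <- c(notices,
                 "descriptives skipped: raw responses not supplied")
  }

  # --- correlation + repair -------------------------------------------
  corr <- stage("correlation", {
    cc <- if (mode == "responses") spearman_matrix(data) else corr_in
    suppressMessages(nearest_pd_repair(cc, floor = config$pd_floor))
  })
  if (corr$repaired)
    notices <- c(notices, sprintf(
      "correlation matrix PD-repaired (eigenvalue floor %g)",
      config$pd_floor))

  # --- network --------------------------------------------------------
  network <- stage("network",
                   select_network(corr, gamma = config$gamma,
                                  n_points = config$n_points,
                                  min_ratio = config$min_ratio))

  # --- centralities ---------------------------------------------------
  centrality <- stage("centrality",
                      centrality_table(network, partition,
                                       data = if (mode == "responses") data))
  if (mode == "correlation")
    notices <- c(notices,
                 "predictability skipped: not computable from a correlation matrix alone")

  # --- secondary collapsed network ------------------------------------
  aggregate <- NULL
  if (!is.null(config$collapse)) {
    if (mode == "responses") {
      aggregate <- stage("aggregate_network",
                         aggregate_community_network(
                           data, partition, config$collapse,
                           gamma = config$gamma,
                           n_points = config$n_points,
                           min_ratio = config$min_ratio,
                           floor = config$pd_floor))
    } else {
      notices <- c(notices,
                   "aggregate (total-score) network skipped: raw responses not supplied")
    }
  }

  # --- bootstraps -----------------------------------------------------
  boot_edges <- cs <- diff_edges <- NULL
  if (config$bootstrap) {
    if (mode == "responses") {
      boot_edges <- stage("edge_bootstrap",
                          edge_ci_bootstrap(data, B = config$B,
                                            seed = config$seed,
                                            gamma = config$gamma,
                                            n_points = config$n_points,
                                            min_ratio = config$min_ratio,
                                            floor = config$pd_floor))
      diff_edges <- stage("edge_difference_test",
                          difference_test(boot_edges, alpha = config$alpha))
      cs <- stage("case_dropping",
                  case_dropping_bootstrap(
                    data,
                    statistic = c("expected_influence",
                                  "bridge_expected_influence"),
                    drop_fractions = config$drop_fractions,
                    B = config$B,
                    r_threshold = config$r_threshold,
                    seed = if (is.null(config$seed)) NULL
                           else config$seed + 1L,
                    partition = partition,
                    gamma = config$gamma,
                    n_points = config$n_points,
                    min_ratio = config$min_ratio,
                    floor = config$pd_floor))
    } else {
      notices <- c(notices,
                   "bootstraps skipped: raw responses not supplied")
    }
  }

  # --- manifest -------------------------------------------------------
  advisory <- sample_size_advisory(length(labels))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ordnet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input_mode = mode,
    nodes = length(labels),
    n = network$n,
    gamma = config$gamma,
    n_points = config$n_points,
    min_ratio = config$min_ratio,
    pd_floor = config$pd_floor,
    selected_lambda = network$penalty,
    selected_ebic = network$ebic,
    edge_count = network$edge_count,
    bootstrap = config$bootstrap,
    B = if (config$bootstrap) config$B else NA,
    seed = if (is.null(config$seed)) NA else config$seed,
    candidate_edges = advisory$candidate_edges,
    free_parameters = advisory$free_parameters,
    advised_minimum_n = advisory$minimum_n)

  bundle <- structure(list(descriptives = desc, correlation = corr,
                           network = network, centrality = centrality,
                           aggregate = aggregate,
                           boot_edges = boot_edges,
                           diff_edges = diff_edges, cs = cs,
                           partition = partition,
                           notices = notices, manifest = manifest,
                           out_dir = out_dir),
                      class = "report_bundle")
  if (!is.null(out_dir)) stage("write_outputs", .write_bundle(bundle))
  bundle
}

.write_bundle <- function(bundle) {
  out <- bundle$out_dir
  tsv <- function(df, name)
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  if (!is.null(bundle$descriptives)) {
    tsv(bundle$descriptives$items, "descriptives_items.tsv")
    tsv(bundle$descriptives$scales, "descriptives_scales.tsv")
  }
  write_correlation_matrix(bundle$correlation,
                           file.path(out, "correlation_matrix.tsv"))
  write_network_matrix(bundle$network, file.path(out, "network_weights.tsv"))
  write_edge_list(bundle$network, file.path(out, "network_edges.tsv"))
  tsv(bundle$centrality, "centrality.tsv")
  write_partition(bundle$partition, file.path(out, "partition.tsv"))
  path_df <- bundle$network$path
  tsv(path_df, "penalty_path.tsv")
  if (!is.null(bundle$aggregate)) {
    write_network_matrix(bundle$aggregate,
                         file.path(out, "aggregate_network_weights.tsv"))
    write_edge_list(bundle$aggregate,
                    file.path(out, "aggregate_network_edges.tsv"))
  }
  if (!is.null(bundle$boot_edges)) {
    be <- bundle$boot_edges
    tsv(data.frame(edge = be$labels, estimate = as.numeric(be$point),
                   lower = as.numeric(be$lower),
                   upper = as.numeric(be$upper)),
        "boot_edge_intervals.tsv")
  }
  if (!is.null(bundle$cs)) {
    for (s in names(bundle$cs)) {
      r <- bundle$cs[[s]]
      tsv(r$summary, paste0("cs_", s, ".tsv"))
    }
    cs_lines <- vapply(names(bundle$cs), function(s)
      sprintf("%s: %.2f", s, bundle$cs[[s]]$cs_coefficient), character(1))
    writeLines(c("correlation-stability coefficients", cs_lines),
               file.path(out, "cs_coefficients.txt"))
  }
  if (length(bundle$notices))
    writeLines(bundle$notices, file.path(out, "notices.txt"))
  m <- bundle$manifest
  writeLines(paste0(names(m), ": ",
                    vapply(m, function(v) paste(format(v), collapse = ","),
                           character(1))),
             file.path(out, "manifest.txt"))
  invisible(bundle)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Network analysis report bundle (", x$manifest$input_mode,
      " mode)\n", sep = "")
  print(x$network)
  if (length(x$notices)) cat("notices:\n ",
                             paste(x$notices, collapse = "\n  "), "\n")
  invisible(x)
}
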