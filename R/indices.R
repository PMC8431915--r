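#' Define an a-priori community partition
#'
#' Maps every item to exactly one community. Bridge centralities are
#' defined relative to such a partition, fixed in advance (communities are
#' never detected from the data here).
#'
#' @param items Character vector of item labels.
#' @param communities Community label per item.
#' @return Named character vector of class `community_partition`.
#' @export
community_partition <- function(items, communities) {
  items <- as.character(items)
  communities <- as.character(communities)
  if (length(items) != length(communities))
    stop("`items` and `communities` must have equal length")
  if (anyDuplicated(items))
    stop("duplicated item(s): ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  if (anyNA(items) || anyNA(communities))
    stop("missing values in partition")
  structure(setNames(communities, items), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  for (g in unique(unclass(x)))
    cat(g, ": ", paste(names(x)[x == g], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Community labels for the nodes of a network, in node order; errors on
# nodes the partition does not cover.
.node_communities <- function(labels, partition) {
  if (!inherits(partition, "community_partition"))
    partition <- community_partition(names(partition), partition)
  missing <- setdiff(labels, names(partition))
  if (length(missing))
    stop("node(s) not assigned to any community: ",
         paste(missing, collapse = ", "))
  unclass(partition)[labels]
}

#' Expected influence of each node
#'
#' One-step expected influence: the sum of the signed weights of all edges
#' attached to a node. Unlike strength centrality it does not take
#' absolute values, so it remains meaningful in networks with negative
#' edges.
#'
#' @param net A `network_model` (or a plain symmetric weight matrix with
#'   zero diagonal).
#' @param two_step If `TRUE`, adds the weight-propagated influence of each
#'   node's neighbours (two-step variant); default one-step.
#' @return Named numeric vector in node order.
#' @export
expected_influence <- function(net, two_step = FALSE) {
  w <- if (inherits(net, "network_model")) net$weights else as.matrix(net)
  ei1 <- rowSums(w)
  if (!two_step) return(ei1)
  ei1 + as.vector(w %*% ei1)
}

#' Bridge expected influence over a two-or-more community partition
#'
#' The sum of a node's signed edge weights to nodes in other communities:
#' its potential for transmitting activation across the community
#' boundary.
#'
#' @param net A `network_model` (or weight matrix).
#' @param partition A [community_partition] covering every node.
#' @return Named numeric vector in node order.
#' @export
bridge_expected_influence <- function(net, partition) {
  w <- if (inherits(net, "network_model")) net$weights else as.matrix(net)
  labels <- rownames(w) %||% paste0("V", seq_len(nrow(w)))
  comm <- .node_communities(labels, partition)
  if (length(unique(comm)) < 2L)
    stop("bridge expected influence needs at least 2 communities")
  cross <- outer(comm, comm, `!=`)
  setNames(rowSums(w * cross), labels)
}

#' Standardize values to z-scores
#'
#' `(x - mean) / sd` with the sample standard deviation. A constant input
#' returns all zeros with attribute `degenerate = TRUE`.
#'
#' @param values Numeric vector of length >= 2.
#' @return Standardized vector (mean 0, SD 1 unless degenerate).
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to standardize")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(values))
    names(out) <- names(values)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (values - mean(values)) / s
}

#' Nodewise predictability
#'
#' For every item, the share of its variance explained by all remaining
#' items — the R-squared of an ordinary least-squares regression of that
#' item on the rest, items treated as continuous. An upper bound on how
#' much of a node could be controlled through its neighbours.
#'
#' @param data An [item_response_matrix] (or matrix / data frame). Raw
#'   responses are required; predictability is not computable from a
#'   correlation matrix alone.
#' @return Named numeric vector in item order, clipped to \[0, 1\].
#' @export
predictability <- function(data) {
  data <- as_item_response_matrix(data)
  x <- data$values
  n <- nrow(x); p <- ncol(x)
  if (n <= p)
    stop("predictability needs n > p respondents; ",
         "consider a regularized nodewise estimator for n <= p")
  if (any(data$degenerate))
    stop("constant item(s): ",
         paste(data$labels[data$degenerate], collapse = ", "))
  out <- numeric(p)
  xc <- scale(x, center = TRUE, scale = FALSE)
  for (j in seq_len(p)) {
    y <- xc[, j]
    X <- xc[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), y)
    rss <- sum(fit$residuals^2)
    tss <- sum(y^2)
    out[j] <- 1 - rss / tss
  }
  names(out) <- data$labels
  pmin(pmax(out, 0), 1)
}

#' Centrality table for a network
#'
#' Per-node expected influence and bridge expected influence with z-scored
#' versions, plus nodewise predictability when raw responses are
#' available.
#'
#' @param net A `network_model`.
#' @param partition A [community_partition]; omit to skip bridge columns.
#' @param data Optional raw responses for predictability.
#' @return Data frame with one row per node, columns `node`, `community`,
#'   `expected_influence`, `ei_z`, `bridge_expected_influence`, `bei_z`,
#'   `predictability` (NA when unavailable).
#' @export
centrality_table <- function(net, partition = NULL, data = NULL) {
  ei <- expected_influence(net)
  out <- data.frame(node = net$labels,
                    community = NA_character_,
                    expected_influence = as.numeric(ei),
                    ei_z = as.numeric(zscore(ei)),
                    bridge_expected_influence = NA_real_,
                    bei_z = NA_real_,
                    predictability = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    out$community <- .node_communities(net$labels, partition)
    bei <- bridge_expected_influence(net, partition)
    out$bridge_expected_influence <- as.numeric(bei)
    out$bei_z <- as.numeric(zscore(bei))
  }
  if (!is.null(data)) {
    pr <- predictability(data)
    out$predictability <- as.numeric(pr[net$labels])
  }
  out
}
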