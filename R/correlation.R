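#' Construct an item-response matrix
#'
#' Container for forced-choice ordinal questionnaire responses: an integer
#' respondents x items matrix with unique item labels and a declared
#' category range per item. Missing entries are rejected; items observed at
#' fewer than two distinct values are flagged as degenerate (correlation
#' work will refuse them).
#'
#' @param values Integer matrix or data frame, respondents in rows.
#' @param labels Item labels; default column names.
#' @param category_range Optional list of `c(lo, hi)` per item; default the
#'   observed range.
#' @return An object of class `item_response_matrix`.
#' @export
item_response_matrix <- function(values, labels = colnames(values),
                                 category_range = NULL) {
  values <- as.matrix(values)
  if (anyNA(values))
    stop("missing responses are not supported; supply complete cases")
  if (!is.numeric(values))
    stop("responses must be numeric category codes")
  if (any(values != round(values)))
    stop("responses must be integer category codes")
  storage.mode(values) <- "integer"
  p <- ncol(values)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (length(labels) != p || anyDuplicated(labels))
    stop("`labels` must be ", p, " unique item names")
  colnames(values) <- labels
  if (is.null(category_range)) {
    category_range <- lapply(seq_len(p), function(j) range(values[, j]))
    names(category_range) <- labels
  }
  for (j in seq_len(p)) {
    r <- category_range[[j]]
    if (any(values[, j] < r[1] | values[, j] > r[2]))
      stop("item ", labels[j], ": responses outside declared category range [",
           r[1], ", ", r[2], "]")
  }
  degenerate <- vapply(seq_len(p),
                       function(j) length(unique(values[, j])) < 2L,
                       logical(1))
  names(degenerate) <- labels
  structure(list(values = values, labels = labels,
                 category_range = category_range, degenerate = degenerate),
            class = "item_response_matrix")
}

#' @export
print.item_response_matrix <- function(x, ...) {
  cat("Item responses:", nrow(x$values), "respondents x",
      ncol(x$values), "items\n")
  if (any(x$degenerate))
    cat("  degenerate (constant) items:",
        paste(x$labels[x$degenerate], collapse = ", "), "\n")
  invisible(x)
}

# Coerce matrix / data.frame / item_response_matrix inputs.
as_item_response_matrix <- function(x) {
  if (inherits(x, "item_response_matrix")) x else item_response_matrix(x)
}

#' Construct a correlation matrix object
#'
#' A symmetric unit-diagonal association matrix together with the sample
#' size it summarizes and a method tag. Symmetry is enforced by averaging
#' numerically asymmetric remnants; material asymmetry is an error.
#'
#' @param mat Square numeric matrix.
#' @param n Sample size the matrix summarizes (`NA` for model-implied).
#' @param method One of `"spearman"`, `"model_implied"`,
#'   `"user_supplied"`.
#' @param labels Variable labels; default dimnames.
#' @return An object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(mat, n = NA_integer_,
                               method = c("user_supplied", "spearman",
                                          "model_implied"),
                               labels = NULL) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  p <- nrow(mat)
  if (ncol(mat) != p) stop("correlation matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-8)
    stop("correlation matrix must be symmetric")
  mat <- (mat + t(mat)) / 2
  if (max(abs(diag(mat) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  diag(mat) <- 1
  if (max(abs(mat)) > 1 + 1e-8)
    stop("correlation entries must lie in [-1, 1]")
  mat[mat > 1] <- 1
  mat[mat < -1] <- -1
  if (is.null(labels))
    labels <- rownames(mat) %||% paste0("V", seq_len(p))
  if (length(labels) != p || anyDuplicated(labels))
    stop("`labels` must be ", p, " unique names")
  dimnames(mat) <- list(labels, labels)
  ev_min <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(matrix = mat, labels = labels,
                 n = if (is.na(n)) NA_integer_ else as.integer(n),
                 method = method, repaired = FALSE,
                 min_eigenvalue = ev_min),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("%s correlation matrix: %d variables, n = %s%s\n",
              x$method, length(x$labels),
              if (is.na(x$n)) "?" else x$n,
              if (x$repaired) " (PD-repaired)" else ""))
  cat(sprintf("  smallest eigenvalue: %.4g\n", x$min_eigenvalue))
  invisible(x)
}

#' Spearman correlation matrix of ordinal responses
#'
#' Pairwise Spearman rank correlations (average ranks for ties, then
#' Pearson on the ranks), the rank-based association matrix that feeds
#' network estimation for ordinal items.
#'
#' @param data An [item_response_matrix], matrix or data frame.
#' @return A [correlation_matrix] with method tag `"spearman"` and the
#'   sample size recorded.
#' @export
spearman_matrix <- function(data) {
  data <- as_item_response_matrix(data)
  n <- nrow(data$values)
  if (n < 3L) stop("at least 3 respondents are required")
  if (any(data$degenerate))
    stop("constant item(s): ",
         paste(data$labels[data$degenerate], collapse = ", "),
         "; Spearman correlation is undefined for them")
  s <- stats::cor(data$values, method = "spearman")
  correlation_matrix(s, n = n, method = "spearman", labels = data$labels)
}

#' Repair a non-positive-definite correlation matrix
#'
#' Clips eigenvalues at a small positive floor, reassembles the matrix and
#' rescales it to unit diagonal. Matrices already positive definite with
#' smallest eigenvalue at or above the floor pass through unchanged. A
#' repair is recorded on the result and announced via [message()].
#'
#' Rank-based correlation matrices are not guaranteed positive definite,
#' and the graphical lasso requires a PD input, so estimation is always
#' preceded by this step.
#'
#' @param corr A [correlation_matrix] (or plain symmetric matrix).
#' @param floor Eigenvalue floor; default `1e-4`.
#' @return A [correlation_matrix]; `$repaired` says whether anything
#'   changed.
#' @export
nearest_pd_repair <- function(corr, floor = 1e-4) {
  if (!inherits(corr, "correlation_matrix"))
    corr <- correlation_matrix(corr)
  if (floor <= 0) stop("`floor` must be positive")
  e <- eigen(corr$matrix, symmetric = TRUE)
  if (min(e$values) >= floor) return(corr)
  # rescaling to unit diagonal can push the smallest eigenvalue back
  # below the floor, so clip-and-rescale is iterated to convergence
  m <- .pd_clip(corr$matrix, floor)
  out <- correlation_matrix(m, n = corr$n, method = corr$method,
                            labels = corr$labels)
  out$repaired <- TRUE
  out$floor <- floor
  message(sprintf(
    "correlation matrix repaired: smallest eigenvalue %.4g raised to >= %.4g",
    min(e$values), floor))
  out
}
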