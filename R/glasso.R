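#' Graphical lasso at a single penalty
#'
#' Penalized maximum-likelihood estimate of the precision (inverse
#' covariance) matrix: the maximizer of
#' `log det K - trace(S K) - lambda * sum_{i != j} |K_ij|`, with the
#' diagonal unpenalized. Solved by block coordinate descent; convergence is
#' declared when the duality gap `trace(SK) + lambda*||K||_1,off - p` falls
#' below `tol`.
#'
#' @param corr A positive-definite [correlation_matrix] (or plain
#'   symmetric matrix).
#' @param penalty Nonnegative L1 penalty `lambda`.
#' @param tol Duality-gap tolerance; default `1e-6`.
#' @param max_iter Maximum outer sweeps; default 200.
#' @return The estimated precision matrix, with attributes `gap`,
#'   `iterations` and `covariance` (the estimated covariance `W`).
#' @export
glasso_fit <- function(corr, penalty, tol = 1e-6, max_iter = 200L) {
  s <- .corr_input(corr)
  if (penalty < 0) stop("`penalty` must be >= 0")
  ev_min <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop("input matrix is not positive definite (smallest eigenvalue ",
         signif(ev_min, 4), "); apply nearest_pd_repair() first")
  fit <- glasso_cpp(s, penalty, as.integer(max_iter), tol,
                    matrix(0, 0, 0), matrix(0, 0, 0), FALSE)
  if (!fit$converged)
    stop(sprintf(
      "graphical lasso did not converge: lambda = %.4g, duality gap %.3g after %d sweeps",
      penalty, fit$gap, fit$iterations))
  K <- fit$K
  dimnames(K) <- dimnames(s)
  attr(K, "gap") <- fit$gap
  attr(K, "iterations") <- fit$iterations
  attr(K, "covariance") <- fit$W
  K
}

.corr_input <- function(corr) {
  if (inherits(corr, "correlation_matrix")) corr$matrix else as.matrix(corr)
}

#' Penalty path for graphical lasso selection
#'
#' Log-spaced descending sequence of `n_points` penalties from
#' `lambda_max` — the largest absolute off-diagonal of the correlation
#' matrix, the smallest penalty yielding the empty graph — down to
#' `lambda_max * min_ratio`.
#'
#' @param corr Correlation matrix (object or plain matrix).
#' @param n_points Number of penalties (>= 2); default 100.
#' @param min_ratio Ratio of smallest to largest penalty, in (0, 1);
#'   default 0.01.
#' @return Numeric vector of descending penalties.
#' @export
penalty_path <- function(corr, n_points = 100L, min_ratio = 0.01) {
  s <- .corr_input(corr)
  if (n_points < 2L) stop("`n_points` must be >= 2")
  if (min_ratio <= 0 || min_ratio >= 1) stop("`min_ratio` must be in (0, 1)")
  lmax <- max(abs(s[upper.tri(s)]))
  if (lmax == 0) return(0)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_points))
}

#' Extended BIC of a penalized precision matrix
#'
#' `-2 L + E log(n) + 4 E gamma log(p)`, where
#' `L = (n/2) (log det K - trace(S K))` is the Gaussian log-likelihood and
#' `E` the number of nonzero upper-triangle off-diagonal precision entries
#' (entries with magnitude below `1e-10` count as zero). Larger `gamma`
#' favours sparser models.
#'
#' @param precision Positive-definite precision matrix `K`.
#' @param corr Correlation matrix `S` (object or plain matrix).
#' @param n Sample size.
#' @param gamma EBIC hyperparameter, >= 0.
#' @return The EBIC score (scalar; smaller is better).
#' @export
ebic_score <- function(precision, corr, n, gamma) {
  s <- .corr_input(corr)
  p <- nrow(s)
  if (!all(dim(precision) == dim(s)))
    stop("precision and correlation dimensions disagree")
  if (n < 1) stop("`n` must be >= 1")
  if (gamma < 0) stop("`gamma` must be >= 0")
  ch <- tryCatch(chol(precision), error = function(e) NULL)
  if (is.null(ch))
    stop("precision matrix is not positive definite; log-determinant undefined")
  logdet <- 2 * sum(log(diag(ch)))
  L <- (n / 2) * (logdet - sum(s * precision))
  E <- sum(abs(precision[upper.tri(precision)]) > 1e-10)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Convert a precision matrix to partial-correlation edge weights
#'
#' `w_ij = -K_ij / sqrt(K_ii K_jj)` off the diagonal, zero on it; numerical
#' asymmetry is averaged away.
#'
#' @param precision Precision matrix with strictly positive diagonal.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
precision_to_partial <- function(precision) {
  d <- diag(precision)
  if (any(d <= 0))
    stop("precision matrix has nonpositive diagonal entries")
  w <- -precision / sqrt(d %o% d)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso at every penalty on a log-spaced path, scores
#' each fit by extended BIC, and returns the minimum-EBIC model as a
#' partial-correlation network. Ties are broken toward the larger penalty
#' (the sparser model). The full path of scores is retained for
#' inspection.
#'
#' @param corr A positive-definite [correlation_matrix]; repair first (see
#'   [nearest_pd_repair()]) if needed.
#' @param n Sample size; defaults to the one recorded on `corr`.
#' @param gamma EBIC hyperparameter; default 0.5, trading a little
#'   sensitivity for specificity of edge detection.
#' @param n_points,min_ratio Path settings, see [penalty_path()].
#' @param tol,max_iter Convergence settings, see [glasso_fit()].
#' @return An object of class `network_model`: `weights` (partial
#'   correlations, zero diagonal), `precision`, `penalty`, `gamma`,
#'   `ebic`, `n`, `edge_count` and `path` (a data frame of lambda, ebic,
#'   edge_count along the path).
#' @export
select_network <- function(corr, n = NULL, gamma = 0.5, n_points = 100L,
                           min_ratio = 0.01, tol = 1e-6, max_iter = 200L) {
  if (!inherits(corr, "correlation_matrix"))
    corr <- correlation_matrix(corr)
  if (is.null(n)) n <- corr$n
  if (is.null(n) || is.na(n) || n < 1)
    stop("sample size `n` is required (attach it to the correlation matrix ",
         "or pass it explicitly)")
  s <- corr$matrix
  p <- nrow(s)
  ev_min <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0)
    stop("correlation matrix is not positive definite; ",
         "apply nearest_pd_repair() first")

  lambdas <- penalty_path(s, n_points = n_points, min_ratio = min_ratio)
  path <- data.frame(lambda = lambdas, ebic = NA_real_,
                     edge_count = NA_integer_)
  best <- NULL
  W <- matrix(0, 0, 0); B <- matrix(0, 0, 0); warm <- FALSE
  for (i in seq_along(lambdas)) {
    fit <- glasso_cpp(s, lambdas[i], as.integer(max_iter), tol, W, B, warm)
    if (!fit$converged)
      stop(sprintf(
        "graphical lasso did not converge at lambda = %.4g (gap %.3g)",
        lambdas[i], fit$gap))
    W <- fit$W; B <- fit$B; warm <- TRUE       # warm start down the path
    K <- fit$K
    K[abs(K) < 1e-10] <- 0
    score <- ebic_score(K, s, n, gamma)
    path$ebic[i] <- score
    path$edge_count[i] <- sum(abs(K[upper.tri(K)]) > 0)
    if (is.null(best) || score < best$score)   # ties keep the sparser model
      best <- list(score = score, K = K, lambda = lambdas[i])
  }
  if (is.null(best)) stop("no usable fit along the penalty path")

  K <- best$K
  dimnames(K) <- list(corr$labels, corr$labels)
  weights <- precision_to_partial(K)
  structure(list(labels = corr$labels,
                 weights = weights,
                 precision = K,
                 penalty = best$lambda,
                 gamma = gamma,
                 ebic = best$score,
                 n = as.integer(n),
                 edge_count = sum(weights[upper.tri(weights)] != 0),
                 path = path,
                 settings = list(n_points = n_points, min_ratio = min_ratio,
                                 tol = tol, max_iter = max_iter)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  p <- length(x$labels)
  cat("Regularized partial-correlation network\n")
  cat(sprintf("  nodes: %d   edges: %d of %d possible\n",
              p, x$edge_count, p * (p - 1) / 2))
  cat(sprintf("  lambda = %.4g (EBIC %.2f, gamma %.2f), n = %d\n",
              x$penalty, x$ebic, x$gamma, x$n))
  neg <- sum(x$weights[upper.tri(x$weights)] < 0)
  if (neg > 0) cat("  negative edges:", neg, "\n")
  invisible(x)
}

#' Long-format edge list of a network
#'
#' Nonzero edges sorted by absolute weight, descending.
#'
#' @param net A `network_model` (or `true_network`).
#' @return Data frame with columns `item_a`, `item_b`, `weight`.
#' @export
edge_list <- function(net) {
  w <- if (inherits(net, "true_network")) net$partial else net$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  df <- data.frame(item_a = rownames(w)[ut[, 1]],
                   item_b = colnames(w)[ut[, 2]],
                   weight = w[ut],
                   stringsAsFactors = FALSE)
  df <- df[df$weight != 0, , drop = FALSE]
  df <- df[order(-abs(df$weight)), , drop = FALSE]
  rownames(df) <- NULL
  df
}
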