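# Estimation settings shared by the main run and its bootstrap replicates.
.estimation_settings <- function(gamma = 0.5, n_points = 100L,
                                 min_ratio = 0.01, floor = 1e-4,
                                 tol = 1e-6, max_iter = 200L) {
  list(gamma = gamma, n_points = n_points, min_ratio = min_ratio,
       floor = floor, tol = tol, max_iter = max_iter)
}

# Quiet eigenvalue-clipping repair on a plain matrix: clip at the floor,
# rescale to unit diagonal, repeat until the floor actually holds (the
# rescaling perturbs the spectrum slightly).
.pd_clip <- function(s, floor) {
  for (i in 1:100) {
    e <- eigen(s, symmetric = TRUE)
    if (min(e$values) >= floor * (1 - 1e-8)) return(s)
    m <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / (d %o% d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    s <- m
  }
  stop("positive-definiteness repair did not stabilize at floor ", floor)
}

# Spearman -> PD repair -> EBIC glasso selection on a raw value matrix.
# Errors (e.g. a constant column in a resample) propagate to the caller.
.fit_pipeline <- function(values, settings) {
  if (any(apply(values, 2, function(v) length(unique(v)) < 2L)))
    stop("degenerate resample: constant item")
  s <- stats::cor(values, method = "spearman")
  s <- .pd_clip(s, settings$floor)
  corr <- correlation_matrix(s, n = nrow(values), method = "spearman",
                             labels = colnames(values))
  select_network(corr, gamma = settings$gamma,
                 n_points = settings$n_points,
                 min_ratio = settings$min_ratio,
                 tol = settings$tol, max_iter = settings$max_iter)
}

# Named upper-triangle edge-weight vector of a network.
.edge_vector <- function(net) {
  w <- net$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  setNames(w[upper.tri(w)],
           paste(rownames(w)[ut[, 1]], colnames(w)[ut[, 2]], sep = "--"))
}

.extract_statistic <- function(net, statistic, partition) {
  switch(statistic,
         edge_weight = .edge_vector(net),
         expected_influence = expected_influence(net),
         bridge_expected_influence =
           bridge_expected_influence(net, partition),
         stop("unknown statistic: ", statistic))
}

#' Nonparametric bootstrap of edge weights (and centralities)
#'
#' Resamples respondents with replacement and re-runs the full estimation
#' pipeline (Spearman correlations, positive-definiteness repair, EBIC
#' graphical lasso selection) on every replicate, using the estimation
#' settings of the main run throughout. Returns per-element quantile
#' confidence intervals. Replicates in which some item becomes constant
#' are dropped and counted; more than 5% such failures is an error.
#'
#' @param data An [item_response_matrix] (or matrix / data frame).
#' @param B Number of bootstrap replicates. Values below 100 are allowed
#'   (e.g. for smoke tests) but trigger a warning.
#' @param seed Optional integer seed; fixes the resampling exactly.
#' @param statistic `"edge_weight"` (default), `"expected_influence"` or
#'   `"bridge_expected_influence"`.
#' @param partition Required when `statistic` is
#'   `"bridge_expected_influence"`.
#' @param level Confidence level; default 0.95.
#' @param gamma,n_points,min_ratio,floor,tol,max_iter Estimation settings,
#'   reused for every replicate.
#' @return An object of class `bootstrap_result`: `statistic`, `labels`,
#'   `point` (full-sample values), `replicates` (kept replicates x
#'   elements), `lower`, `upper`, `B`, `B_failed`, `seed`, `level`,
#'   `settings`.
#' @export
edge_ci_bootstrap <- function(data, B = 2000L, seed = NULL,
                              statistic = c("edge_weight",
                                            "expected_influence",
                                            "bridge_expected_influence"),
                              partition = NULL, level = 0.95,
                              gamma = 0.5, n_points = 100L, min_ratio = 0.01,
                              floor = 1e-4, tol = 1e-6, max_iter = 200L) {
  statistic <- match.arg(statistic)
  data <- as_item_response_matrix(data)
  B <- as.integer(B)
  if (B < 2L) stop("`B` must be at least 2")
  if (B < 100L)
    warning("B = ", B, " bootstrap replicates is very small; ",
            "intervals will be unreliable")
  if (statistic == "bridge_expected_influence" && is.null(partition))
    stop("`partition` is required for bridge expected influence")
  settings <- .estimation_settings(gamma, n_points, min_ratio, floor,
                                   tol, max_iter)
  if (!is.null(seed)) set.seed(as.integer(seed))

  full <- .fit_pipeline(data$values, settings)
  point <- .extract_statistic(full, statistic, partition)
  m <- length(point)
  n <- nrow(data$values)

  reps <- matrix(NA_real_, B, m, dimnames = list(NULL, names(point)))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    net <- tryCatch(.fit_pipeline(data$values[idx, , drop = FALSE], settings),
                    error = function(e) NULL)
    if (is.null(net)) { failed <- failed + 1L; next }
    reps[b, ] <- .extract_statistic(net, statistic, partition)
  }
  if (failed > 0.05 * B)
    stop(failed, " of ", B, " bootstrap replicates were degenerate (> 5%)")
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  a <- (1 - level) / 2
  lower <- apply(reps, 2, stats::quantile, probs = a)
  upper <- apply(reps, 2, stats::quantile, probs = 1 - a)
  structure(list(statistic = statistic, labels = names(point),
                 point = point, replicates = reps,
                 lower = lower, upper = upper,
                 B = B, B_failed = failed,
                 seed = seed, level = level, settings = settings),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap of %s: B = %d (%d degenerate), %d elements\n",
              x$statistic, x$B, x$B_failed, length(x$point)))
  cat(sprintf("  %.0f%% intervals; seed = %s\n", 100 * x$level,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Lower empirical quantile as an order statistic (type-1 quantile), so the
# CS coefficient can be reproduced exactly from the stored draws.
.quantile_order_stat <- function(x, prob) {
  x <- sort(x)
  x[max(1L, ceiling(prob * length(x)))]
}

#' Case-dropping bootstrap and correlation-stability coefficient
#'
#' For each drop fraction, repeatedly re-estimates the network on random
#' subsamples (that fraction of respondents removed, sampling without
#' replacement) and correlates (Pearson) the subsample centralities with
#' the full-sample ones. The correlation-stability (CS) coefficient of a
#' statistic is the largest tested drop fraction at which the correlation
#' stays at or above `r_threshold` with 95% probability — i.e. whose
#' empirical 2.5th-percentile correlation (order statistic) is at least
#' `r_threshold` — or 0 if no fraction qualifies. Conventional reading:
#' above 0.5 is preferred, below 0.25 inadequate.
#'
#' When a subsample statistic is constant (typically an empty network) its
#' correlation with the full-sample statistic is recorded as 0: a constant
#' profile carries no ordering information.
#'
#' @param data An [item_response_matrix] (or matrix / data frame).
#' @param statistic One or both of `"expected_influence"`,
#'   `"bridge_expected_influence"`; when both, the same subsamples are
#'   shared and a named list is returned.
#' @param drop_fractions Fractions of respondents to drop, each in
#'   (0, 0.95); default 0.1 to 0.7 in steps of 0.1.
#' @param B Subsamples per fraction; values below 100 warn.
#' @param r_threshold Correlation threshold defining the CS coefficient;
#'   default 0.7.
#' @param seed Optional integer seed.
#' @param partition Required for bridge expected influence.
#' @param gamma,n_points,min_ratio,floor,tol,max_iter Estimation settings,
#'   reused for every subsample.
#' @return A `cs_result` (or named list of them): `statistic`,
#'   `drop_fractions` (those actually tested), `correlations` (B x
#'   fractions matrix of stored draws), `summary` (per-fraction table),
#'   `cs_coefficient`, `r_threshold`, `B`, `seed`, `skipped`, `settings`.
#' @export
case_dropping_bootstrap <- function(data,
                                    statistic = c("expected_influence",
                                                  "bridge_expected_influence"),
                                    drop_fractions = seq(0.1, 0.7, by = 0.1),
                                    B = 2000L, r_threshold = 0.7,
                                    seed = NULL, partition = NULL,
                                    gamma = 0.5, n_points = 100L,
                                    min_ratio = 0.01, floor = 1e-4,
                                    tol = 1e-6, max_iter = 200L) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  data <- as_item_response_matrix(data)
  B <- as.integer(B)
  if (B < 2L) stop("`B` must be at least 2")
  if (B < 100L)
    warning("B = ", B, " subsamples per fraction is very small; ",
            "the CS coefficient will be unreliable")
  if (any(drop_fractions <= 0 | drop_fractions >= 0.95))
    stop("`drop_fractions` must lie in (0, 0.95)")
  if ("bridge_expected_influence" %in% statistic && is.null(partition))
    stop("`partition` is required for bridge expected influence")
  settings <- .estimation_settings(gamma, n_points, min_ratio, floor,
                                   tol, max_iter)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- nrow(data$values)
  p <- ncol(data$values)
  full <- .fit_pipeline(data$values, settings)
  full_stat <- lapply(statistic, .extract_statistic, net = full,
                      partition = partition)
  names(full_stat) <- statistic

  drop_fractions <- sort(drop_fractions)
  keep_m <- round(n * (1 - drop_fractions))
  usable <- keep_m >= p + 1L
  skipped <- drop_fractions[!usable]
  if (length(skipped))
    warning("drop fraction(s) ", paste(skipped, collapse = ", "),
            " skipped: subsample smaller than p + 1")
  fracs <- drop_fractions[usable]
  keep_m <- keep_m[usable]
  if (!length(fracs)) stop("no usable drop fractions")

  cors <- lapply(statistic, function(s)
    matrix(NA_real_, B, length(fracs),
           dimnames = list(NULL, paste0("drop_", fracs))))
  names(cors) <- statistic

  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  for (fi in seq_along(fracs)) {
    for (b in seq_len(B)) {
      idx <- sample.int(n, keep_m[fi], replace = FALSE)
      net <- tryCatch(
        .fit_pipeline(data$values[idx, , drop = FALSE], settings),
        error = function(e) NULL)
      if (is.null(net)) next
      for (s in statistic)
        cors[[s]][b, fi] <- safe_cor(
          .extract_statistic(net, s, partition), full_stat[[s]])
    }
  }

  build <- function(s) {
    cm <- cors[[s]]
    q025 <- apply(cm, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      .quantile_order_stat(v, 0.025)
    })
    qualifies <- !is.na(q025) & q025 >= r_threshold
    cs <- if (any(qualifies)) max(fracs[qualifies]) else 0
    summary <- data.frame(drop_fraction = fracs,
                          n_kept = keep_m,
                          mean_cor = apply(cm, 2, mean, na.rm = TRUE),
                          q025 = q025,
                          median = apply(cm, 2, stats::median, na.rm = TRUE),
                          failures = apply(cm, 2, function(v) sum(is.na(v))))
    rownames(summary) <- NULL
    structure(list(statistic = s, drop_fractions = fracs,
                   correlations = cm, summary = summary,
                   cs_coefficient = cs, r_threshold = r_threshold,
                   B = B, seed = seed, skipped = skipped,
                   settings = settings),
              class = "cs_result")
  }
  out <- lapply(statistic, build)
  names(out) <- statistic
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("Case-dropping bootstrap of %s (B = %d per fraction)\n",
              x$statistic, x$B))
  cat(sprintf("  CS coefficient: %.2f (threshold r >= %.2f with 95%% probability)\n",
              x$cs_coefficient, x$r_threshold))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Bootstrapped difference test
#'
#' For every pair of bootstrapped elements (edges or node centralities),
#' forms the bootstrap distribution of their difference; the pair differs
#' significantly when the central `1 - alpha` quantile interval of that
#' distribution excludes zero. No multiplicity correction is applied by
#' default (the convention for these descriptive network diagnostics);
#' `adjust = "bonferroni"` divides `alpha` by the number of pairs.
#'
#' @param boot A [edge_ci_bootstrap()] result with at least 2 elements.
#' @param alpha Significance level; default 0.05.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return An object of class `difference_test`: symmetric logical matrix
#'   `significant` (diagonal `FALSE`), matrices `lower` and `upper` of the
#'   difference-interval bounds (row minus column), and the settings.
#' @export
difference_test <- function(boot, alpha = 0.05,
                            adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(boot, "bootstrap_result"))
  reps <- boot$replicates
  m <- ncol(reps)
  if (m < 2L) stop("difference tests need at least 2 elements")
  n_pairs <- m * (m - 1) / 2
  a <- if (adjust == "bonferroni") alpha / n_pairs else alpha
  if (nrow(reps) * a / 2 < 1)
    stop("B = ", nrow(reps), " replicates is too small for alpha = ", a,
         " difference tests")
  sig <- matrix(FALSE, m, m, dimnames = list(boot$labels, boot$labels))
  lower <- upper <- matrix(0, m, m, dimnames = dimnames(sig))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d <- reps[, i] - reps[, j]
      q <- stats::quantile(d, probs = c(a / 2, 1 - a / 2), names = FALSE)
      lower[i, j] <- q[1]; upper[i, j] <- q[2]
      lower[j, i] <- -q[2]; upper[j, i] <- -q[1]
      sig[i, j] <- sig[j, i] <- q[1] > 0 || q[2] < 0
    }
  }
  structure(list(statistic = boot$statistic, labels = boot$labels,
                 significant = sig, lower = lower, upper = upper,
                 alpha = alpha, adjust = adjust),
            class = "difference_test")
}

#' @export
print.difference_test <- function(x, ...) {
  m <- length(x$labels)
  cat(sprintf(
    "Bootstrapped difference test of %s: %d of %d pairs significant (alpha = %g, %s correction)\n",
    x$statistic, sum(x$significant[upper.tri(x$significant)]),
    m * (m - 1) / 2, x$alpha,
    if (x$adjust == "none") "no" else x$adjust))
  invisible(x)
}
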