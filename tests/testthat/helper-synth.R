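# Shared generators for the test suite. All randomness is seeded by the
# caller through synthetic_spec(seed = ...).

# Paper-shaped study conditions: 12 + 7 ordinal items, n = 624, sparse
# two-community truth.
paper_shaped_spec <- function(n = 624, seed = 42, ...) {
  synthetic_spec(n = n, seed = seed, ...)
}

# Tiny bivariate network with a single planted edge.
bivariate_spec <- function(w, n = 1000, seed = 1) {
  synthetic_spec(n = n, community_sizes = c(1L, 1L),
                 category_counts = c(5L, 5L), category_start = c(1L, 1L),
                 density = 1, weight_range = c(abs(w), abs(w)),
                 negative_fraction = if (w < 0) 1 else 0, seed = seed)
}

# Estimate a network from raw values with the default pipeline settings.
fit_from_values <- function(values, n = nrow(values)) {
  co <- suppressMessages(nearest_pd_repair(spearman_matrix(values)))
  select_network(co, n = n)
}

# Recovery scores of an estimated weight matrix against a true partial
# matrix: sensitivity, specificity, false-positive rate, sign agreement
# among true edges.
recovery_scores <- function(est, truth) {
  ut <- upper.tri(truth)
  te <- truth[ut] != 0
  ee <- est[ut] != 0
  list(sensitivity = mean(ee[te]),
       specificity = mean(!ee[!te]),
       fpr = mean(ee[!te]),
       sign_agreement = mean(sign(est[ut])[te] == sign(truth[ut])[te]))
}
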