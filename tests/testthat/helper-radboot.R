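# Shared fixtures: a small, fast cohort and a light engine for unit tests.
# Acceptance tests use study-scale settings and state their own scaling.

tiny_config <- function(...) {
  cohort_config(n_patients = 30, n_radiomic = 20, n_signal = 4, n_noise = 6,
                n_mediator = 2, rho_range = c(0.5, 0.9), ...)
}

tiny_cohort <- function(seed = 42, ...) generate_cohort(tiny_config(...), seed = seed)

light_engine <- function(n_trees = 60, min_leaf = 3, tune = FALSE, ...) {
  engine_config(n_trees = n_trees, min_leaf = min_leaf, tune = tune, ...)
}

# Independent AUC oracle: brute-force pairwise comparison count
# (ties count one half), kept deliberately separate from roc_auc().
auc_pairwise_oracle <- function(prob, labels) {
  pos <- prob[labels == 1]
  neg <- prob[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Independent chi-squared oracle: explicit expected counts and summation.
chisq_oracle <- function(tab) {
  n <- sum(tab)
  e <- rowSums(tab) %o% colSums(tab) / n
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}
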