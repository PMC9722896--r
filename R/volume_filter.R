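#' Pearson chi-squared test of independence
#'
#' The plain Pearson statistic `sum((O - E)^2 / E)` on a contingency table,
#' without continuity correction, with `(r - 1)(c - 1)` degrees of freedom.
#' Implemented directly (not via [stats::chisq.test()]) so the test suite can
#' verify it against that independent oracle.
#'
#' @param tab matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_squared_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop_radboot("counts must be finite and non-negative", "radboot_domain")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0) || n == 0)
    stop_radboot("degenerate table: zero marginal", "radboot_degenerate")
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Dependence of a categorical feature on lesion volume
#'
#' Two-sided Wilcoxon rank-sum test for binary features, Kruskal-Wallis for
#' features with more than two categories (volumes compared across
#' categories). Empty categories are dropped; if fewer than two remain the
#' test is skipped with a warning and `NA` returned.
#'
#' @param values categorical feature (character/factor).
#' @param volumes positive lesion volumes (cc).
#' @return Two-sided p-value (or `NA` when skipped).
#' @export
test_categorical_volume_dependence <- function(values, volumes) {
  values <- as.character(values)
  keep <- !is.na(values) & !is.na(volumes)
  values <- values[keep]; volumes <- volumes[keep]
  tab <- table(values)
  cats <- names(tab)[tab >= 1]
  if (length(cats) < length(tab))
    warning("dropping empty categories")
  if (length(cats) < 2) {
    warning("fewer than two categories: test skipped")
    return(NA_real_)
  }
  sel <- values %in% cats
  if (length(cats) == 2) {
    g <- values[sel] == cats[1]
    suppressWarnings(wilcox.test(volumes[sel][g], volumes[sel][!g]))$p.value
  } else {
    kruskal.test(volumes[sel], factor(values[sel]))$p.value
  }
}

#' Correlation of a continuous feature with volume and diameter
#'
#' Pearson correlations of the feature with lesion volume and with its cubic
#' root (a diameter analogue), each with a two-sided p-value.
#'
#' @param x continuous feature values.
#' @param volumes positive lesion volumes (cc).
#' @return List `r_vol`, `p_vol`, `r_diam`, `p_diam`.
#' @export
test_continuous_volume_correlation <- function(x, volumes) {
  keep <- is.finite(x) & is.finite(volumes)
  x <- x[keep]; volumes <- volumes[keep]
  if (length(x) < 3)
    stop_radboot("need at least 3 observations", "radboot_degenerate")
  if (sd(x) == 0 || sd(volumes) == 0)
    stop_radboot("correlation undefined for constant input",
                 "radboot_degenerate")
  tv <- cor.test(x, volumes)
  td <- cor.test(x, volumes^(1 / 3))
  list(r_vol = unname(tv$estimate), p_vol = tv$p.value,
       r_diam = unname(td$estimate), p_diam = td$p.value)
}

#' Select features for volume decorrelation
#'
#' Applies the removal rule at a correlation threshold `t`: categorical
#' clinical features are removed when their volume-dependence p-value (rank
#' sum / Kruskal-Wallis) is below the Bonferroni-corrected `alpha`;
#' continuous features (radiomic columns, age, GTV volume) are removed when
#' either volume or cubic-root-volume correlation is significant at `alpha`
#' and `max(|r_vol|, |r_diam|)` exceeds `t`; GTV volume itself is always
#' removed at any `t < 1`. At `t = 1` (baseline) nothing is removed.
#'
#' @param cohort an `srs_cohort`.
#' @param threshold correlation coefficient threshold in `[0, 1]`.
#' @param alpha significance level, default `0.05 / 118` (Bonferroni over the
#'   119 features excluding GTV volume itself).
#' @return List with `removed` (character vector) and `decisions` (one row
#'   per feature: class, test, p-values, correlations, removal verdict).
#' @export
select_features_for_removal <- function(cohort, threshold,
                                        alpha = 0.05 / 118) {
  stopifnot(threshold >= 0, threshold <= 1)
  vols <- cohort$gtv_volume
  rcols <- attr(cohort, "radiomic_cols") %||%
    grep("^f[0-9]{3}$", names(cohort), value = TRUE)
  cont <- c("age", rcols)
  cats <- setdiff(clinical_feature_names(), c("age", "gtv_volume"))

  rows <- list()
  for (f in cats) {
    p <- suppressWarnings(test_categorical_volume_dependence(cohort[[f]], vols))
    rows[[f]] <- data.frame(
      feature = f, class = "categorical",
      test = if (length(unique(cohort[[f]])) == 2) "rank_sum" else "kruskal_wallis",
      p_vol = p, p_diam = NA_real_, r_vol = NA_real_, r_diam = NA_real_,
      removed = isTRUE(p < alpha) && threshold < 1,
      stringsAsFactors = FALSE)
  }
  for (f in cont) {
    ct <- test_continuous_volume_correlation(cohort[[f]], vols)
    signif_cor <- (ct$p_vol < alpha) || (ct$p_diam < alpha)
    big <- max(abs(ct$r_vol), abs(ct$r_diam)) > threshold
    rows[[f]] <- data.frame(
      feature = f, class = "continuous", test = "pearson",
      p_vol = ct$p_vol, p_diam = ct$p_diam,
      r_vol = ct$r_vol, r_diam = ct$r_diam,
      removed = signif_cor && big && threshold < 1,
      stringsAsFactors = FALSE)
  }
  # GTV volume is the confounder itself
  rows[["gtv_volume"]] <- data.frame(
    feature = "gtv_volume", class = "continuous", test = "identity",
    p_vol = 0, p_diam = 0, r_vol = 1, r_diam = NA_real_,
    removed = threshold < 1, stringsAsFactors = FALSE)

  decisions <- do.call(rbind, rows)
  decisions$threshold <- threshold
  rownames(decisions) <- NULL
  list(removed = decisions$feature[decisions$removed], decisions = decisions)
}

#' Volume-decorrelation threshold sweep
#'
#' Reruns the full bootstrapped experiment at each correlation threshold
#' (default `{1, 0.85, 0.70, 0.55, 0.40, 0.25, 0.10, 0}`, 1 = baseline with
#' no removal) and reports the error-metric suite overall and per volume
#' group (< / > `volume_cut` cc). All thresholds share the same bootstrap
#' partitions so differences are attributable to the feature removal alone.
#'
#' @inheritParams run_experiment
#' @param thresholds vector of correlation thresholds.
#' @param alpha Bonferroni-corrected significance level for the filter.
#' @param volume_cut volume group boundary in cc, default 7.5.
#' @return An object of class `srs_sweep`: list with `metrics` (long data
#'   frame: threshold, group, metric, estimate, ci_low, ci_high), `removals`
#'   (named list of removed feature sets), `thresholds`.
#' @export
threshold_sweep <- function(cohort,
                            thresholds = c(1, 0.85, 0.70, 0.55, 0.40, 0.25,
                                           0.10, 0),
                            feature_set = "both", n_reps = 250, seed = 1,
                            engine = engine_config(), alpha = 0.05 / 118,
                            volume_cut = 7.5) {
  removals <- list()
  metrics <- list()
  for (th in thresholds) {
    sel <- select_features_for_removal(cohort, th, alpha = alpha)
    removals[[as.character(th)]] <- sel$removed
    exp <- run_experiment(cohort, feature_set = feature_set, n_reps = n_reps,
                          removed = sel$removed, seed = seed,
                          engine = engine, partition_seed = seed)
    sm <- stratified_metrics(exp, cohort, by = "volume",
                             volume_cut = volume_cut)
    overall <- error_metrics(exp)
    long <- rbind(
      data.frame(group = "all", as.data.frame(overall),
                 stringsAsFactors = FALSE),
      sm)
    long <- data.frame(threshold = th, long, stringsAsFactors = FALSE)
    metrics[[as.character(th)]] <- long
  }
  structure(list(metrics = do.call(rbind, metrics), removals = removals,
                 thresholds = thresholds),
            class = "srs_sweep")
}

#' Primary-site decorrelation filter
#'
#' The primary-site analogue of the volume filter: continuous features are
#' tested for site dependence by Kruskal-Wallis, categorical clinical
#' features by chi-squared against site, at a Bonferroni-corrected alpha;
#' significant features are removed along with primary site itself. Site
#' categories below `min_count` lesions are pooled into `"other"`.
#'
#' @param cohort an `srs_cohort`.
#' @param alpha significance level, default `0.05 / 118`.
#' @param min_count minimum lesions per site category before pooling.
#' @return List with `removed` and `decisions`.
#' @export
site_dependence_filter <- function(cohort, alpha = 0.05 / 118,
                                   min_count = 5) {
  site <- as.character(cohort$site)
  tab <- table(site)
  small <- names(tab)[tab < min_count]
  if (length(small)) {
    message("pooling sparse site categories into 'other': ",
            paste(small, collapse = ", "))
    site[site %in% small] <- "other"
  }
  if (length(unique(site)) < 2)
    stop_radboot("need at least two site categories", "radboot_degenerate")
  site <- factor(site)
  rcols <- attr(cohort, "radiomic_cols") %||%
    grep("^f[0-9]{3}$", names(cohort), value = TRUE)
  cont <- c("age", "gtv_volume", rcols)
  cats <- setdiff(clinical_feature_names(), c("age", "gtv_volume", "site"))

  rows <- list()
  for (f in cats) {
    p <- if (length(unique(cohort[[f]])) < 2) NA_real_
         else chi_squared_test(table(cohort[[f]], site))$p_value
    rows[[f]] <- data.frame(feature = f, class = "categorical",
                            test = "chi_squared", p_value = p,
                            removed = isTRUE(p < alpha),
                            stringsAsFactors = FALSE)
  }
  for (f in cont) {
    p <- if (sd(cohort[[f]]) == 0) NA_real_
         else kruskal.test(cohort[[f]], site)$p.value
    rows[[f]] <- data.frame(feature = f, class = "continuous",
                            test = "kruskal_wallis", p_value = p,
                            removed = isTRUE(p < alpha),
                            stringsAsFactors = FALSE)
  }
  rows[["site"]] <- data.frame(feature = "site", class = "categorical",
                               test = "identity", p_value = 0, removed = TRUE,
                               stringsAsFactors = FALSE)
  decisions <- do.call(rbind, rows)
  rownames(decisions) <- NULL
  list(removed = decisions$feature[decisions$removed], decisions = decisions)
}

#' Univariate association of each clinical feature with progression
#'
#' Chi-squared tests for categorical features, two-sided Wilcoxon rank-sum
#' tests for the continuous features (age, GTV volume), each against the
#' binary progression label; the scanner model is included as an additional
#' categorical row. Constant features are skipped with a warning.
#'
#' @param cohort an `srs_cohort`.
#' @return Data frame `feature`, `test`, `p_value`.
#' @export
univariate_association_tests <- function(cohort) {
  y <- as.integer(cohort$label)
  if (length(unique(y)) < 2)
    stop_radboot("both outcome classes required", "radboot_degenerate")
  feats <- c(clinical_feature_names(),
             if (!is.null(cohort$scanner)) "scanner")
  rows <- lapply(feats, function(f) {
    v <- cohort[[f]]
    if (length(unique(v)) < 2) {
      warning("constant feature skipped: ", f)
      return(data.frame(feature = f, test = "skipped", p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (is.numeric(v)) {
      p <- suppressWarnings(wilcox.test(v[y == 1], v[y == 0]))$p.value
      data.frame(feature = f, test = "rank_sum", p_value = p,
                 stringsAsFactors = FALSE)
    } else {
      p <- chi_squared_test(table(v, y))$p_value
      data.frame(feature = f, test = "chi_squared", p_value = p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
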