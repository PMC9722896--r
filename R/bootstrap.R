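#' Encode cohort features as a numeric model matrix
#'
#' Categorical clinical features are integer-coded with fixed level orders so
#' that encodings agree across bootstrap partitions; age, GTV volume, and the
#' radiomic columns pass through as numeric.
#'
#' @param cohort an `srs_cohort` (or compatible data frame).
#' @param features character vector of feature column names.
#' @return Numeric matrix with one row per lesion.
#' @export
encode_features <- function(cohort, features) {
  levels_map <- list(
    sex = c("female", "male"),
    primary_active = c("yes", "no"),
    site = c("lung", "breast", "renal", "colorectal", "skin", "other"),
    histology = c("adenocarcinoma", "nsclc", "melanoma", "squamous", "other"),
    extracranial = c("yes", "no"),
    systemic_therapy = c("radical", "palliative", "none"),
    steroid_response = c("fully_resolved", "improvement", "limited", "none",
                         "unknown"),
    ecog = c("0", "1", "2", "3"),
    location = c("supratentorial", "infratentorial"),
    prescription = c("15Gy_1fx", "18Gy_1fx", "21Gy_1fx", "24Gy_3fx"),
    scanner = c("vision", "avanto", "expert", "sonata", "signa")
  )
  cols <- lapply(features, function(f) {
    v <- cohort[[f]]
    if (is.null(v)) stop_radboot(paste("unknown feature:", f), "radboot_config")
    if (is.numeric(v)) return(as.numeric(v))
    lv <- levels_map[[f]] %||% sort(unique(as.character(v)))
    lv <- c(lv, setdiff(unique(as.character(v)), lv))
    as.numeric(factor(as.character(v), levels = lv))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- features
  m
}

#' Bootstrap engine configuration
#'
#' Hyper-parameters for the per-repetition forest fit. With `tune = TRUE`
#' the grid `mtry in {sqrt(p), p/3}` x `min_leaf` is searched and the
#' combination with the best out-of-bag AUC on the training data is used,
#' so tuning never touches the test partition.
#'
#' @param n_trees trees per forest.
#' @param min_leaf candidate minimum leaf sizes.
#' @param tune search the grid (`TRUE`) or use `sqrt(p)` / `min_leaf[1]`.
#' @param corr_cutoff inter-feature correlation filter cutoff (|Pearson r|).
#' @return An object of class `srs_engine_config`.
#' @export
engine_config <- function(n_trees = 500, min_leaf = c(1, 3, 5), tune = TRUE,
                          corr_cutoff = 0.95) {
  stopifnot(n_trees >= 1, corr_cutoff > 0, corr_cutoff <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf),
                 tune = isTRUE(tune), corr_cutoff = corr_cutoff),
            class = "srs_engine_config")
}

#' Patient-level bootstrap partition
#'
#' Draws patients with replacement (training multiset of size
#' `n = length(unique(patient_ids))`); patients never drawn form the test
#' set, so all of a patient's lesions travel together and no patient appears
#' in both partitions. If every patient is drawn (empty test set), the draw
#' is redone on the next substream and the attempt count recorded.
#'
#' @param patient_ids character vector of patient ids (one per patient, or
#'   per lesion - duplicates are collapsed).
#' @param seed integer seed.
#' @return List with `train` (multiset of patient ids), `test` (vector of
#'   patient ids), and `attempts`.
#' @export
draw_patient_bootstrap <- function(patient_ids, seed = 1) {
  ids <- unique(as.character(patient_ids))
  if (length(ids) < 2)
    stop_radboot("need at least two patients", "radboot_config")
  for (attempt in 1:1000) {
    s <- if (attempt == 1) seed else derive_seed(seed, 7919, attempt)
    train <- with_seed(s, sample(ids, length(ids), replace = TRUE))
    test <- setdiff(ids, train)
    if (length(test) > 0)
      return(list(train = train, test = test, attempts = attempt))
  }
  stop_radboot("could not draw a non-empty test set", "radboot_internal")
}

#' Greedy inter-feature correlation filter
#'
#' Removes features so that no retained pair has `|Pearson r| > cutoff` on
#' the training data. Features are visited in order of decreasing univariate
#' training AUC (when labels are supplied); a visited feature is kept unless
#' it correlates above the cutoff with an already-kept feature. Constant
#' features are removed with a warning.
#'
#' @param x numeric training feature matrix.
#' @param cutoff absolute correlation cutoff, default 0.95.
#' @param y optional 0/1 training labels defining the greedy order.
#' @return Named logical vector: `TRUE` = removed.
#' @export
filter_interfeature_correlation <- function(x, cutoff = 0.95, y = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(p >= 1)
  nm <- colnames(x) %||% paste0("V", seq_len(p))
  sds <- apply(x, 2, sd)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant))
    warning("removing constant feature(s): ", paste(nm[constant], collapse = ", "))
  ord <- seq_len(p)
  if (!is.null(y) && length(unique(y)) == 2) {
    disc <- vapply(seq_len(p), function(j) {
      if (constant[j]) return(0)
      a <- roc_auc(x[, j], y)
      max(a, 1 - a)
    }, numeric(1))
    ord <- order(disc, decreasing = TRUE)
  }
  cm <- suppressWarnings(abs(cor(x)))
  removed <- constant
  kept <- integer(0)
  for (j in ord) {
    if (removed[j]) next
    if (length(kept) && any(cm[j, kept] > cutoff, na.rm = TRUE)) {
      removed[j] <- TRUE
    } else {
      kept <- c(kept, j)
    }
  }
  names(removed) <- nm
  removed
}

#' Fit one bootstrap repetition
#'
#' Applies the inter-feature correlation filter on the training data, tunes
#' the forest on training out-of-bag AUC (see [engine_config()]), fits the
#' random decision forest, and records test, out-of-bag, and resubstitution
#' probabilities plus raw importances.
#'
#' @param train,test `srs_cohort` subsets (training rows may repeat patients).
#' @param features active feature names (after any volume-filter removal).
#' @param engine an [engine_config()].
#' @param seed integer seed for this repetition.
#' @return List with `test_prob`, `oob_prob`, `resub_prob` (named by lesion
#'   id), `importance` (raw, named; `NA` for filter-removed features),
#'   `filter_removed` (logical), and the chosen `mtry` / `min_leaf`.
#' @export
fit_and_predict <- function(train, test, features, engine = engine_config(),
                            seed = 1) {
  y_tr <- as.integer(train$label)
  if (length(unique(y_tr)) < 2L)
    stop_radboot("training data contains a single outcome class",
                 "radboot_single_class")
  x_tr <- encode_features(train, features)
  x_te <- encode_features(test, features)
  removed <- suppressWarnings(
    filter_interfeature_correlation(x_tr, cutoff = engine$corr_cutoff, y = y_tr))
  active <- features[!removed]
  if (length(active) == 0)
    stop_radboot("all features removed by the inter-feature filter",
                 "radboot_degenerate")
  x_tr_a <- x_tr[, active, drop = FALSE]
  x_te_a <- x_te[, active, drop = FALSE]
  p <- length(active)

  if (engine$tune) {
    grid <- expand.grid(mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3)))),
                        min_leaf = engine$min_leaf)
  } else {
    grid <- data.frame(mtry = max(1L, floor(sqrt(p))),
                       min_leaf = engine$min_leaf[1])
  }
  fits <- lapply(seq_len(nrow(grid)), function(g) {
    rd_forest(x_tr_a, y_tr, x_te_a, n_trees = engine$n_trees,
              mtry = grid$mtry[g], min_leaf = grid$min_leaf[g],
              seed = derive_seed(seed, 31, g))
  })
  oob_auc <- vapply(fits, function(f) {
    ok <- !is.na(f$oob_prob)
    if (length(unique(y_tr[ok])) < 2L) return(NA_real_)
    roc_auc(f$oob_prob[ok], y_tr[ok])
  }, numeric(1))
  best <- which.max(oob_auc)  # first maximum on ties
  fit <- fits[[best]]

  imp <- rep(NA_real_, length(features))
  names(imp) <- features
  imp[active] <- fit$importance

  list(
    test_prob = stats::setNames(fit$test_prob, test$bm_id),
    oob_prob = stats::setNames(fit$oob_prob, train$bm_id),
    resub_prob = stats::setNames(fit$resub_prob, train$bm_id),
    importance = imp,
    filter_removed = removed,
    mtry = grid$mtry[best], min_leaf = grid$min_leaf[best],
    oob_auc = oob_auc[best]
  )
}

#' Run a bootstrapped evaluation experiment
#'
#' The core experiment: `n_reps` patient-level bootstrap repetitions, each
#' with training-data-only inter-feature filtering, hyper-parameter tuning by
#' out-of-bag AUC, forest fitting, and recording of test / out-of-bag /
#' resubstitution probabilities and raw importances. Repetitions whose
#' training draw yields a single outcome class (or an empty test set) are
#' redrawn on the next substream.
#'
#' @param cohort an `srs_cohort`.
#' @param feature_set `"both"`, `"clinical"`, or `"radiomic"`.
#' @param n_reps number of bootstrap repetitions (250 in the full design).
#' @param removed feature names removed up front (e.g. by
#'   [select_features_for_removal()]); applied before feature-set selection.
#' @param volume_threshold optional volume-decorrelation threshold; when set,
#'   the filter runs automatically (once on the full cohort by default,
#'   matching the fixed published removal counts, or per training set with
#'   `per_repetition_filter = TRUE` for the leakage-free variant).
#' @param filter_alpha significance level for the automatic volume filter.
#' @param per_repetition_filter recompute the volume filter on each
#'   repetition's training lesions instead of once on the full cohort.
#' @param seed master seed for this experiment.
#' @param engine an [engine_config()].
#' @param partition_seed optional seed for the bootstrap partitions only, so
#'   different feature-set arms can share identical partitions.
#' @return An object of class `srs_experiment`: list with `probs` (long data
#'   frame: `rep`, `bm_id`, `partition` in test/oob/apparent, `probability`,
#'   `label`), `importance` (reps x features raw matrix), `filter_mask`
#'   (reps x features logical), `features`, `feature_set`, `n_reps`, `seed`.
#' @export
run_experiment <- function(cohort, feature_set = c("both", "clinical",
                                                   "radiomic"),
                           n_reps = 250, removed = character(),
                           volume_threshold = NULL,
                           filter_alpha = 0.05 / 118,
                           per_repetition_filter = FALSE,
                           seed = 1, engine = engine_config(),
                           partition_seed = NULL) {
  feature_set <- match.arg(feature_set)
  if (!is.null(volume_threshold) && !per_repetition_filter) {
    sel <- select_features_for_removal(cohort, volume_threshold,
                                       alpha = filter_alpha)
    removed <- union(removed, sel$removed)
  }
  rcols <- attr(cohort, "radiomic_cols") %||%
    grep("^f[0-9]{3}$", names(cohort), value = TRUE)
  ccols <- attr(cohort, "clinical_cols") %||% clinical_feature_names()
  pool <- switch(feature_set,
                 clinical = ccols,
                 radiomic = rcols,
                 both = c(ccols, rcols))
  features <- setdiff(pool, removed)
  if (length(features) == 0)
    stop_radboot("no features left after removal", "radboot_config")
  labels <- stats::setNames(as.integer(cohort$label), cohort$bm_id)
  pseed <- partition_seed %||% seed

  probs_list <- vector("list", n_reps)
  imp <- matrix(NA_real_, n_reps, length(features),
                dimnames = list(NULL, features))
  mask <- matrix(FALSE, n_reps, length(features),
                 dimnames = list(NULL, features))
  chosen <- data.frame(rep = seq_len(n_reps), mtry = NA_integer_,
                       min_leaf = NA_integer_, attempts = NA_integer_)

  for (r in seq_len(n_reps)) {
    fit <- NULL
    for (attempt in 1:100) {
      part <- draw_patient_bootstrap(cohort$patient_id,
                                     seed = derive_seed(pseed, r, attempt))
      train <- cohort[unlist(lapply(part$train,
                                    function(p) which(cohort$patient_id == p))), ]
      test <- cohort[cohort$patient_id %in% part$test, ]
      if (length(unique(train$label)) < 2L) next
      feats_r <- features
      if (!is.null(volume_threshold) && per_repetition_filter) {
        rem_r <- select_features_for_removal(train, volume_threshold,
                                             alpha = filter_alpha)$removed
        feats_r <- setdiff(features, rem_r)
      }
      fit <- fit_and_predict(train, test, feats_r, engine = engine,
                             seed = derive_seed(seed, r, 1009, attempt))
      break
    }
    if (is.null(fit))
      stop_radboot(sprintf("repetition %d: no two-class training draw found", r),
                   "radboot_internal")
    probs_list[[r]] <- data.frame(
      rep = r,
      bm_id = c(names(fit$test_prob), names(fit$oob_prob),
                names(fit$resub_prob)),
      partition = rep(c("test", "oob", "apparent"),
                      c(length(fit$test_prob), length(fit$oob_prob),
                        length(fit$resub_prob))),
      probability = c(fit$test_prob, fit$oob_prob, fit$resub_prob),
      stringsAsFactors = FALSE
    )
    imp[r, names(fit$importance)] <- fit$importance
    mask[r, names(fit$filter_removed)] <- fit$filter_removed
    chosen$mtry[r] <- fit$mtry
    chosen$min_leaf[r] <- fit$min_leaf
    chosen$attempts[r] <- attempt
  }
  probs <- do.call(rbind, probs_list)
  probs$label <- labels[probs$bm_id]
  rownames(probs) <- NULL

  structure(list(
    probs = probs, importance = imp, filter_mask = mask,
    features = features, feature_set = feature_set,
    n_reps = as.integer(n_reps), seed = seed, engine = engine,
    removed = removed, tuning = chosen,
    cohort_fingerprint = sprintf("n=%d;pos=%d;vol=%.4f", nrow(cohort),
                                 sum(cohort$label),
                                 sum(cohort$gtv_volume))
  ), class = "srs_experiment")
}

#' @export
print.srs_experiment <- function(x, ...) {
  cat(sprintf("srs_experiment: %d repetitions, feature set '%s' (%d features)\n",
              x$n_reps, x$feature_set, length(x$features)))
  invisible(x)
}

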