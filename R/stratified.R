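#' Stratified re-aggregation of error metrics
#'
#' Partitions the pooled test and out-of-bag probabilities of a finished
#' experiment by stratum (primary site, volume group at the 7.5 cc cut, or
#' scanner model) and recomputes the full error-metric suite per group - no
#' refitting, mirroring how small strata are handled when per-stratum models
#' are infeasible. By default the out-of-bag operating point is recomputed
#' from each stratum's own pooled OOB probabilities; `threshold_mode =
#' "global"` instead transfers the overall threshold to every stratum.
#'
#' @param experiment an `srs_experiment`.
#' @param cohort the cohort the experiment was run on (provides the strata).
#' @param by `"site"`, `"volume"`, or `"scanner"`; ignored when `groups` is
#'   given.
#' @param groups optional named vector mapping `bm_id` to group label.
#' @param volume_cut volume group boundary in cc, default 7.5.
#' @param threshold_mode `"per_stratum"` (default) or `"global"`.
#' @param level CI coverage.
#' @return Long data frame: `group`, `metric`, `estimate`, `ci_low`,
#'   `ci_high`. Groups whose pooled predictions contain a single class get
#'   `NA` metrics and a message.
#' @export
stratified_metrics <- function(experiment, cohort,
                               by = c("site", "volume", "scanner"),
                               groups = NULL, volume_cut = 7.5,
                               threshold_mode = c("per_stratum", "global"),
                               level = 0.95) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(groups)) {
    by <- match.arg(by)
    groups <- switch(by,
      site = stats::setNames(as.character(cohort$site), cohort$bm_id),
      volume = stats::setNames(
        ifelse(cohort$gtv_volume < volume_cut, "small", "large"),
        cohort$bm_id),
      scanner = stats::setNames(as.character(cohort$scanner), cohort$bm_id))
  }
  probs <- experiment$probs
  probs$group <- groups[probs$bm_id]
  global_thr <- if (threshold_mode == "global")
    attr(error_metrics(experiment, level = level), "threshold") else NULL

  out <- lapply(sort(unique(stats::na.omit(probs$group))), function(g) {
    sub <- probs[!is.na(probs$group) & probs$group == g,
                 c("rep", "bm_id", "partition", "probability", "label")]
    em <- tryCatch(
      error_metrics(sub, threshold = global_thr, level = level),
      radboot_error = function(e) {
        message("stratum '", g, "': ", conditionMessage(e))
        data.frame(metric = c("auc", "auc_632plus", "apparent_auc", "mcr",
                              "fnr", "fpr"),
                   estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   stringsAsFactors = FALSE)
      })
    data.frame(group = g, as.data.frame(em), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scanner-pairing subset experiment
#'
#' Subsets the cohort to lesions imaged on two scanner models and reruns the
#' full bootstrapped experiment on that subset (patients carry all their
#' lesions with them, so the subset is patient-complete when a patient's
#' scans share a scanner). High accuracy for a pairing suggests the two
#' scanners share a data domain; low accuracy the opposite.
#'
#' @param cohort an `srs_cohort`.
#' @param pair character vector of two scanner model names.
#' @inheritParams run_experiment
#' @return List with `metrics` (an `srs_error_metrics`), `experiment`,
#'   `pair`, and `n_bm`.
#' @export
run_scanner_pair_experiment <- function(cohort, pair, feature_set = "both",
                                        n_reps = 250, removed = character(),
                                        seed = 1, engine = engine_config()) {
  stopifnot(length(pair) == 2)
  sub <- cohort[cohort$scanner %in% pair, ]
  for (a in c("radiomic_cols", "signal_cols", "clinical_cols", "config"))
    attr(sub, a) <- attr(cohort, a)
  class(sub) <- class(cohort)
  if (nrow(sub) < 4 || length(unique(sub$label)) < 2 ||
      length(unique(sub$patient_id)) < 2)
    stop_radboot(sprintf("scanner pair %s/%s: insufficient data (%d lesions)",
                         pair[1], pair[2], nrow(sub)),
                 "radboot_insufficient_data")
  exp <- run_experiment(sub, feature_set = feature_set, n_reps = n_reps,
                        removed = removed, seed = seed, engine = engine)
  list(metrics = error_metrics(exp), experiment = exp, pair = pair,
       n_bm = nrow(sub))
}
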