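#' Study configuration
#'
#' A single configuration object orchestrating the experiment suite:
#' feature-set comparison arms (run on shared bootstrap partitions so that
#' only the available features differ), optional stratified analyses,
#' optional volume-decorrelation threshold sweep, and optional scanner-pair
#' experiments.
#'
#' @param cohort an `srs_cohort`, or a [cohort_config()] to generate one.
#' @param experiments feature-set arms to run (subset of clinical /
#'   radiomic / both).
#' @param n_reps bootstrap repetitions per experiment.
#' @param engine an [engine_config()].
#' @param stratify_by strata to report for the `"both"` arm (subset of
#'   site / volume / scanner).
#' @param sweep_thresholds optional thresholds for [threshold_sweep()].
#' @param scanner_pairs optional list of scanner-model pairs.
#' @param out_dir optional output directory for delimited-text reports.
#' @param seed master seed; all randomness derives from it.
#' @return An object of class `srs_study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         experiments = c("clinical", "radiomic", "both"),
                         n_reps = 250, engine = engine_config(),
                         stratify_by = c("site", "volume"),
                         sweep_thresholds = NULL, scanner_pairs = NULL,
                         out_dir = NULL, seed = 1) {
  if (length(experiments) == 0)
    stop_radboot("experiment list is empty", "radboot_config")
  experiments <- match.arg(experiments, c("clinical", "radiomic", "both"),
                           several.ok = TRUE)
  structure(list(cohort = cohort, experiments = experiments, n_reps = n_reps,
                 engine = engine, stratify_by = stratify_by,
                 sweep_thresholds = sweep_thresholds,
                 scanner_pairs = scanner_pairs, out_dir = out_dir,
                 seed = seed),
            class = "srs_study_config")
}

#' Run the full experiment suite
#'
#' Executes the configured arms in order: per-feature-set experiments on
#' shared bootstrap partitions, error metrics and importance aggregation,
#' stratified re-aggregation, the volume threshold sweep, and scanner-pair
#' experiments. When `out_dir` is set, metric tables, importance reports,
#' probability dumps, and a run log (with every derived seed) are written as
#' delimited text.
#'
#' @param config an [study_config()].
#' @return List with `cohort`, `experiments` (per arm), `metrics` (long data
#'   frame across arms), `importance`, `stratified`, `sweep`,
#'   `scanner_pairs`, `seed`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "srs_study_config"))
  cohort <- if (inherits(config$cohort, "srs_cohort_config"))
    generate_cohort(config$cohort, seed = derive_seed(config$seed, 1))
  else config$cohort

  partition_seed <- derive_seed(config$seed, 2)
  log <- c(sprintf("master_seed=%d", config$seed),
           sprintf("partition_seed=%d", partition_seed))

  experiments <- list(); metrics <- list()
  for (i in seq_along(config$experiments)) {
    fs <- config$experiments[i]
    exp <- run_experiment(cohort, feature_set = fs, n_reps = config$n_reps,
                          seed = derive_seed(config$seed, 3, i),
                          engine = config$engine,
                          partition_seed = partition_seed)
    experiments[[fs]] <- exp
    metrics[[fs]] <- data.frame(feature_set = fs,
                                as.data.frame(error_metrics(exp)),
                                stringsAsFactors = FALSE)
    log <- c(log, sprintf("experiment=%s seed=%d", fs,
                          derive_seed(config$seed, 3, i)))
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  main <- experiments[["both"]] %||% experiments[[length(experiments)]]
  importance <- aggregate_importance(main)
  stratified <- lapply(stats::setNames(config$stratify_by, config$stratify_by),
                       function(b) stratified_metrics(main, cohort, by = b))

  sweep <- NULL
  if (!is.null(config$sweep_thresholds))
    sweep <- threshold_sweep(cohort, thresholds = config$sweep_thresholds,
                             n_reps = config$n_reps,
                             seed = derive_seed(config$seed, 4),
                             engine = config$engine)

  pairs <- NULL
  if (!is.null(config$scanner_pairs))
    pairs <- lapply(config$scanner_pairs, function(p)
      run_scanner_pair_experiment(cohort, p, n_reps = config$n_reps,
                                  seed = derive_seed(config$seed, 5),
                                  engine = config$engine))

  out <- list(cohort = cohort, experiments = experiments, metrics = metrics,
              importance = importance, stratified = stratified, sweep = sweep,
              scanner_pairs = pairs, seed = config$seed, log = log)
  if (!is.null(config$out_dir)) write_study_outputs(out, config$out_dir)
  out
}

write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(study$importance),
            file.path(out_dir, "importance.csv"), row.names = FALSE)
  for (nm in names(study$stratified))
    write.csv(study$stratified[[nm]],
              file.path(out_dir, sprintf("stratified_%s.csv", nm)),
              row.names = FALSE)
  if (!is.null(study$sweep))
    write.csv(study$sweep$metrics, file.path(out_dir, "sweep.csv"),
              row.names = FALSE)
  for (nm in names(study$experiments))
    write_probability_table(study$experiments[[nm]],
                            file.path(out_dir,
                                      sprintf("probabilities_%s.csv", nm)))
  writeLines(study$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Serialize / load the long probability table
#'
#' One row per lesion per repetition per partition, columns `rep`, `bm_id`,
#' `partition` (test / oob / apparent), `probability`, `label` - the shape of
#' the published data share, so externally supplied predictions can be
#' re-analysed with [replicate_error_metrics()].
#'
#' @param experiment an `srs_experiment` (or its `probs` data frame).
#' @param path CSV path.
#' @export
write_probability_table <- function(experiment, path) {
  probs <- if (inherits(experiment, "srs_experiment")) experiment$probs
           else experiment
  write.csv(probs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probability_table
#' @export
read_probability_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_probability_table(tab)
  tab
}

validate_probability_table <- function(tab) {
  need <- c("rep", "bm_id", "partition", "probability", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_radboot(paste("probability table missing columns:",
                       paste(miss, collapse = ", ")), "radboot_parse")
  bad <- which(!(tab$partition %in% c("test", "oob", "apparent")))
  if (length(bad))
    stop_radboot(sprintf("row %d: unknown partition '%s'", bad[1],
                         tab$partition[bad[1]]), "radboot_parse")
  bad <- which(!is.na(tab$probability) &
                 (tab$probability < 0 | tab$probability > 1))
  if (length(bad))
    stop_radboot(sprintf("row %d: probability outside [0, 1]", bad[1]),
                 "radboot_parse")
  bad <- which(!(tab$label %in% c(0, 1)))
  if (length(bad))
    stop_radboot(sprintf("row %d: label must be 0 or 1", bad[1]),
                 "radboot_parse")
  invisible(tab)
}

#' Recompute error metrics from an external probability table
#'
#' Replicates the error-metric post-processing from a serialized probability
#' table (e.g. the published data share) without refitting any model:
#' overall metrics, and optionally per-stratum metrics for a supplied
#' `bm_id -> group` mapping.
#'
#' @param table a data frame in the probability-table schema, or a CSV path.
#' @param strata optional named vector mapping `bm_id` to stratum label.
#' @param level CI coverage.
#' @return List with `overall` (an `srs_error_metrics`) and `stratified`
#'   (long data frame, or `NULL`).
#' @export
replicate_error_metrics <- function(table, strata = NULL, level = 0.95) {
  if (is.character(table)) table <- read_probability_table(table)
  validate_probability_table(table)
  if (!any(table$partition == "oob"))
    stop_radboot("table has no 'oob' rows: operating point cannot be selected",
                 "radboot_missing_partition")
  overall <- error_metrics(table, level = level)
  stratified <- NULL
  if (!is.null(strata)) {
    fake <- structure(list(probs = table), class = "srs_experiment")
    stratified <- stratified_metrics(fake, cohort = NULL, groups = strata,
                                     level = level)
  }
  list(overall = overall, stratified = stratified)
}
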