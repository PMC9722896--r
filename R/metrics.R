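#' Full error-metric suite for a bootstrapped experiment
#'
#' Computes the evaluation summary from pooled predicted probabilities:
#' pooled test AUC with a percentile CI over per-repetition AUCs, the
#' apparent (resubstitution) AUC, the .632+ corrected AUC, and - via the
#' out-of-bag operating point - MCR, FNR, and FPR with percentile CIs.
#' The operating threshold is found on the ROC curve of the pooled
#' out-of-bag probabilities (upper-left optimum) and transferred to the
#' pooled test predictions, so threshold selection never touches the test
#' partition.
#'
#' @param x an `srs_experiment`, or a long probability data frame with
#'   columns `rep`, `bm_id`, `partition` (test/oob/apparent), `probability`,
#'   `label`.
#' @param threshold optional fixed decision threshold; default is the
#'   out-of-bag upper-left optimum computed from `x`.
#' @param level CI coverage, default 0.95.
#' @return An object of class `srs_error_metrics`: data frame with columns
#'   `metric` (`auc`, `auc_632plus`, `apparent_auc`, `mcr`, `fnr`, `fpr`),
#'   `estimate`, `ci_low`, `ci_high`; attributes `threshold`,
#'   `operating_point`, `test_curve`, `oob_curve`, `n`.
#' @export
error_metrics <- function(x, threshold = NULL, level = 0.95) {
  probs <- if (inherits(x, "srs_experiment")) x$probs else x
  need <- c("rep", "bm_id", "partition", "probability", "label")
  miss <- setdiff(need, names(probs))
  if (length(miss))
    stop_radboot(paste("probability table missing columns:",
                       paste(miss, collapse = ", ")), "radboot_parse")
  te <- probs[probs$partition == "test", ]
  ap <- probs[probs$partition == "apparent", ]
  ob <- probs[probs$partition == "oob" & !is.na(probs$probability), ]
  if (nrow(te) == 0)
    stop_radboot("no test-partition rows", "radboot_parse")

  test_curve <- pooled_roc(te$probability, te$label)
  auc <- attr(test_curve, "auc")
  rep_auc <- vapply(split(te, te$rep), function(d) {
    if (length(unique(d$label)) < 2L) return(NA_real_)
    roc_auc(d$probability, d$label)
  }, numeric(1))
  auc_ci <- if (sum(is.finite(rep_auc)) >= 2) percentile_ci(rep_auc, level)
            else c(NA_real_, NA_real_)

  apparent <- if (nrow(ap)) roc_auc(ap$probability, ap$label) else NA_real_
  corrected <- if (is.finite(apparent)) auc_632plus(apparent, auc) else NA_real_

  oob_curve <- NULL
  op <- NULL
  if (is.null(threshold)) {
    if (nrow(ob) == 0)
      stop_radboot("no out-of-bag rows: cannot select an operating point",
                   "radboot_missing_partition")
    oob_curve <- pooled_roc(ob$probability, ob$label)
    op <- optimal_upper_left(oob_curve)
    threshold <- op$threshold
  }
  rates <- transfer_operating_point(threshold, te$probability, te$label)
  rep_rates <- lapply(split(te, te$rep), function(d) {
    if (length(unique(d$label)) < 2L) return(c(NA_real_, NA_real_, NA_real_))
    r <- transfer_operating_point(threshold, d$probability, d$label)
    c(r$mcr, r$fnr, r$fpr)
  })
  rr <- do.call(rbind, rep_rates)
  ci <- function(v) if (sum(is.finite(v)) >= 2) percentile_ci(v, level)
        else c(NA_real_, NA_real_)

  out <- data.frame(
    metric = c("auc", "auc_632plus", "apparent_auc", "mcr", "fnr", "fpr"),
    estimate = c(auc, corrected, apparent, rates$mcr, rates$fnr, rates$fpr),
    ci_low = c(auc_ci[1], NA, NA, ci(rr[, 1])[1], ci(rr[, 2])[1],
               ci(rr[, 3])[1]),
    ci_high = c(auc_ci[2], NA, NA, ci(rr[, 1])[2], ci(rr[, 2])[2],
                ci(rr[, 3])[2]),
    stringsAsFactors = FALSE
  )
  structure(out, threshold = threshold, operating_point = op,
            test_curve = test_curve, oob_curve = oob_curve,
            counts = rates[c("tp", "fp", "tn", "fn")],
            n = length(unique(te$bm_id)),
            class = c("srs_error_metrics", "data.frame"))
}

#' @export
print.srs_error_metrics <- function(x, ...) {
  cat(sprintf("Error metrics (n = %d lesions, threshold = %.3f):\n",
              attr(x, "n"), attr(x, "threshold")))
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE)
  invisible(x)
}

metric_value <- function(em, name) em$estimate[em$metric == name]
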