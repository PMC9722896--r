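#' Aggregate per-repetition forest importances
#'
#' Per repetition, raw mean-decrease-in-impurity importances are min-max
#' normalised to `[0, 1]`; features removed by that repetition's
#' inter-feature correlation filter are scored 0 (features removed by the
#' volume filter never enter the experiment and are absent from the report
#' entirely). The per-repetition scores are then averaged and the averages
#' min-max renormalised to `[0, 1]`.
#'
#' @param experiment an `srs_experiment`.
#' @return An object of class `srs_importance`: data frame `feature`,
#'   `score`, sorted by decreasing score, with the per-repetition normalised
#'   matrix in attribute `per_rep`.
#' @export
aggregate_importance <- function(experiment) {
  stopifnot(inherits(experiment, "srs_experiment"))
  imp <- experiment$importance
  mask <- experiment$filter_mask
  norm <- t(apply(imp, 1, function(v) {
    fitted <- !is.na(v)
    out <- numeric(length(v))
    if (any(fitted)) {
      x <- v[fitted]
      rng <- max(x) - min(x)
      out[fitted] <- if (rng > 0) (x - min(x)) / rng else 0
    }
    out
  }))
  norm[mask] <- 0
  all_zero <- rowSums(norm) == 0
  if (any(all_zero))
    message(sum(all_zero), " repetition(s) had all-zero importance scores")
  avg <- colMeans(norm)
  rng <- max(avg) - min(avg)
  score <- if (rng > 0) (avg - min(avg)) / rng else avg
  out <- data.frame(feature = colnames(imp), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  structure(out, per_rep = norm, class = c("srs_importance", "data.frame"))
}

#' Highly important features
#'
#' Features whose aggregated importance score is strictly above the cutoff.
#'
#' @param report an `srs_importance` report.
#' @param cutoff score cutoff in `[0, 1]`, default 0.75 (strict inequality:
#'   a score of exactly 0.75 is not highly important).
#' @return Character vector of feature names.
#' @export
highly_important <- function(report, cutoff = 0.75) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  report$feature[report$score > cutoff]
}
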