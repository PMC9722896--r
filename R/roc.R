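#' Pooled ROC curve from predicted probabilities
#'
#' Builds the standard threshold-sweep ROC over probability/label pairs pooled
#' across bootstrap repetitions. A case is called positive when its predicted
#' probability is greater than or equal to the threshold, so every observed
#' probability (plus `Inf`) appears as a threshold and the curve runs from
#' (0,0) to (1,1).
#'
#' @param probabilities numeric vector of predicted class-1 probabilities
#'   (any real scores are accepted).
#' @param labels 0/1 outcome vector.
#' @return An object of class `srs_roc`: data frame with columns `threshold`,
#'   `fpr`, `tpr`, plus attributes `auc`, `n_pos`, `n_neg`.
#' @export
pooled_roc <- function(probabilities, labels) {
  ok <- is.finite(probabilities) & !is.na(labels)
  probabilities <- probabilities[ok]
  labels <- as.integer(labels[ok])
  stopifnot(all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_radboot("ROC undefined: pooled pairs contain a single class",
                 "radboot_single_class")
  o <- order(probabilities, decreasing = TRUE)
  p_s <- probabilities[o]
  l_s <- labels[o]
  # collapse tied thresholds: curve points only where the score changes
  last_of_tie <- c(p_s[-length(p_s)] != p_s[-1], TRUE)
  tp <- cumsum(l_s)[last_of_tie]
  fp <- cumsum(1L - l_s)[last_of_tie]
  curve <- data.frame(
    threshold = c(Inf, p_s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(curve,
            auc = roc_auc(probabilities, labels),
            n_pos = n_pos, n_neg = n_neg,
            class = c("srs_roc", "data.frame"))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the Mann-Whitney U statistic divided by `n1 * n0`, with
#' tied probabilities handled by midpoint ranking (a tie counts 1/2).
#'
#' @inheritParams pooled_roc
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probabilities) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_radboot("AUC undefined: input contains a single class",
                 "radboot_single_class")
  r <- rank(probabilities)  # midpoint ranks for ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' .632+ bootstrap correction for AUC
#'
#' Applies the .632+ estimator in error space `e = 1 - AUC` with the
#' no-information error rate fixed at `gamma = 0.5` (a random ranking).
#' The bootstrap (out-of-sample) error is first clamped to at most `gamma`;
#' the relative overfitting rate `R = (e1 - e_app) / (gamma - e_app)` is
#' clamped to `[0, 1]` (with `R = 0` when the apparent error already reaches
#' the no-information rate); the weight is `w = 0.632 / (1 - 0.368 * R)` and
#' the corrected error is `(1 - w) * e_app + w * e1`.
#'
#' @param apparent_auc resubstitution (apparent) AUC in `[0, 1]`.
#' @param bootstrap_auc out-of-sample bootstrap AUC in `[0, 1]`.
#' @return The corrected AUC. Always lies between `bootstrap_auc` (after
#'   clamping at 0.5) and `apparent_auc` when apparent >= bootstrap.
#' @examples
#' auc_632plus(0.95, 0.70)  # 0.7514
#' @export
auc_632plus <- function(apparent_auc, bootstrap_auc) {
  stopifnot(apparent_auc >= 0, apparent_auc <= 1,
            bootstrap_auc >= 0, bootstrap_auc <= 1)
  gamma <- 0.5
  e_app <- 1 - apparent_auc
  e1 <- min(1 - bootstrap_auc, gamma)
  if (e_app >= gamma) {
    r <- 0
  } else {
    r <- (e1 - e_app) / (gamma - e_app)
    r <- min(max(r, 0), 1)
  }
  w <- 0.632 / (1 - 0.368 * r)
  1 - ((1 - w) * e_app + w * e1)
}

#' Optimal upper-left operating point of a ROC curve
#'
#' Returns the curve point minimising Euclidean distance to the perfect
#' classifier corner (FPR, TPR) = (0, 1). Exact ties are broken in favour of
#' the lower FPR.
#'
#' @param curve an `srs_roc` object (or data frame with `threshold`, `fpr`,
#'   `tpr`).
#' @return A one-row data frame `threshold`, `fpr`, `tpr`.
#' @export
optimal_upper_left <- function(curve) {
  stopifnot(all(c("threshold", "fpr", "tpr") %in% names(curve)))
  d2 <- curve$fpr^2 + (1 - curve$tpr)^2
  cand <- which(d2 <= min(d2) + 1e-12)
  best <- cand[which.min(curve$fpr[cand])]
  out <- as.data.frame(curve)[best, c("threshold", "fpr", "tpr")]
  rownames(out) <- NULL
  out
}

#' Transfer an operating point to pooled predictions
#'
#' Classifies `probability >= threshold` as positive and reports the
#' misclassification rate, false negative rate, and false positive rate.
#'
#' @param threshold decision threshold (typically from the out-of-bag curve).
#' @inheritParams pooled_roc
#' @return List with `mcr`, `fnr`, `fpr` and the confusion counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
transfer_operating_point <- function(threshold, probabilities, labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  if (length(unique(labels)) < 2L)
    stop_radboot("error rates undefined: stratum contains a single class",
                 "radboot_single_class")
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(mcr = (fn + fp) / length(labels),
       fnr = fn / (fn + tp),
       fpr = fp / (fp + tn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Empirical percentile confidence interval
#'
#' The 2.5th-97.5th (for `level = 0.95`) percentile interval of a vector of
#' per-repetition statistics, using the default (type 7) quantile rule.
#'
#' @param values numeric vector (one entry per bootstrap repetition).
#' @param level coverage level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 2L, level > 0, level < 1)
  a <- (1 - level) / 2
  unname(quantile(values, probs = c(a, 1 - a)))
}

#' Vertically averaged ROC curve with percentile bands
#'
#' Interpolates each repetition's ROC curve onto a common FPR grid and
#' averages TPR vertically; used for the banded curve display, while pooled
#' pairs drive the point estimates.
#'
#' @inheritParams pooled_roc
#' @param rep repetition index per pair.
#' @param fpr_grid FPR grid, default `seq(0, 1, by = 0.01)`.
#' @param level band coverage level.
#' @return Data frame `fpr`, `tpr_mean`, `tpr_low`, `tpr_high`.
#' @export
vertical_average_roc <- function(probabilities, labels, rep,
                                 fpr_grid = seq(0, 1, by = 0.01),
                                 level = 0.95) {
  reps <- unique(rep)
  tpr_mat <- vapply(reps, function(r) {
    sel <- rep == r
    if (length(unique(labels[sel])) < 2L) return(rep(NA_real_, length(fpr_grid)))
    cv <- pooled_roc(probabilities[sel], labels[sel])
    # step-function interpolation: best TPR achievable at FPR <= grid value
    vapply(fpr_grid, function(f) max(cv$tpr[cv$fpr <= f + 1e-12]), numeric(1))
  }, numeric(length(fpr_grid)))
  tpr_mat <- tpr_mat[, colSums(is.na(tpr_mat)) == 0, drop = FALSE]
  a <- (1 - level) / 2
  data.frame(
    fpr = fpr_grid,
    tpr_mean = rowMeans(tpr_mat),
    tpr_low = apply(tpr_mat, 1, quantile, probs = a),
    tpr_high = apply(tpr_mat, 1, quantile, probs = 1 - a)
  )
}
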