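#' Fit a random decision forest and score train/test partitions
#'
#' A compact bagged-CART classifier (Gini splits, `mtry` random candidate
#' features per node, minimum leaf size) that records everything the
#' bootstrapped evaluation needs in one pass: class-1 probabilities for the
#' test rows, out-of-bag (OOB) probabilities for every training row — each
#' training row scored only by trees whose internal bootstrap excluded it —
#' resubstitution (apparent) probabilities over all trees, and mean-decrease-
#' in-impurity feature importances.
#'
#' Determinism: the forest uses its own internal RNG stream keyed by `seed`,
#' so results are byte-identical across runs and platforms and do not touch
#' R's global RNG state.
#'
#' @param x_train numeric matrix of training features (rows = lesions).
#' @param y_train binary 0/1 outcome vector.
#' @param x_test numeric matrix of test features (same columns as `x_train`);
#'   may have zero rows.
#' @param n_trees number of trees.
#' @param mtry candidate features per split; default `floor(sqrt(p))`.
#' @param min_leaf minimum samples in a leaf.
#' @param seed integer seed for the forest's internal RNG.
#' @param keep_inbag if `TRUE`, also return the per-tree in-bag count matrix
#'   and per-tree training predictions (used to audit OOB honesty).
#' @return An object of class `rd_forest`: list with `test_prob`, `oob_prob`
#'   (`NA` for rows in-bag in every tree), `resub_prob`, `importance` (named),
#'   `oob_count`, and optionally `inbag` / `tree_train_pred`.
#' @examples
#' x <- matrix(rnorm(60), 30, 2)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' f <- rd_forest(x, y, x, n_trees = 50, seed = 1)
#' range(f$test_prob)
#' @export
rd_forest <- function(x_train, y_train, x_test = NULL, n_trees = 500,
                      mtry = NULL, min_leaf = 1, seed = 1,
                      keep_inbag = FALSE) {
  x_train <- as.matrix(x_train)
  storage.mode(x_train) <- "double"
  y_train <- as.integer(y_train)
  stopifnot(length(y_train) == nrow(x_train), all(y_train %in% 0:1))
  if (length(unique(y_train)) < 2L)
    stop_radboot("training data contains a single outcome class",
                 "radboot_single_class")
  if (is.null(x_test)) x_test <- x_train[0, , drop = FALSE]
  x_test <- as.matrix(x_test)
  storage.mode(x_test) <- "double"
  stopifnot(ncol(x_test) == ncol(x_train))
  p <- ncol(x_train)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- max(1L, min(as.integer(mtry), p))
  fit <- .rf_fit_cpp(x_train, y_train, x_test,
                     as.integer(n_trees), mtry, as.integer(min_leaf),
                     as.double(seed), isTRUE(keep_inbag))
  names(fit$importance) <- colnames(x_train)
  fit$mtry <- mtry
  fit$min_leaf <- as.integer(min_leaf)
  fit$n_trees <- as.integer(n_trees)
  class(fit) <- "rd_forest"
  fit
}

#' @export
print.rd_forest <- function(x, ...) {
  cat(sprintf("rd_forest: %d trees, mtry=%d, min_leaf=%d, %d features\n",
              x$n_trees, x$mtry, x$min_leaf, length(x$importance)))
  invisible(x)
}
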