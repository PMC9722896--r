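test_that("pooled ROC handles perfect, anti-perfect, and degenerate input", {
  curve <- pooled_roc(c(0.9, 0.1), c(1, 0))
  expect_equal(attr(curve, "auc"), 1)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_equal(attr(pooled_roc(c(0.9, 0.1), c(0, 1)), "auc"), 0)
  expect_identical(curve$fpr[1], 0); expect_identical(curve$tpr[1], 0)
  expect_identical(curve$fpr[nrow(curve)], 1)
  expect_identical(curve$tpr[nrow(curve)], 1)
  expect_error(pooled_roc(c(0.2, 0.4), c(1, 1)), class = "radboot_single_class")
})

test_that("AUC equals the pairwise Mann-Whitney oracle, ties included", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    prob <- round(runif(n), sample(c(1, 2, 16), 1))  # force some ties
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_auc(prob, lab), auc_pairwise_oracle(prob, lab),
                 tolerance = 1e-12)
    # curve monotonicity
    cv <- pooled_roc(prob, lab)
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
  }
})

test_that(".632+ correction reproduces its limits and the worked value", {
  expect_equal(auc_632plus(0.8, 0.8), 0.8, tolerance = 1e-12)   # no overfit
  expect_equal(auc_632plus(1.0, 0.5), 0.5, tolerance = 1e-12)   # total overfit
  # independent direct substitution: e_app=.05, e1=.30, gamma=.5
  r_direct <- (0.30 - 0.05) / (0.50 - 0.05)
  w_direct <- 0.632 / (1 - 0.368 * r_direct)
  expected <- 1 - ((1 - w_direct) * 0.05 + w_direct * 0.30)
  expect_equal(auc_632plus(0.95, 0.70), expected, tolerance = 1e-12)
  expect_equal(expected, 0.7514, tolerance = 5e-5)
})

test_that(".632+ lies between bootstrap and apparent AUC", {
  set.seed(12)
  for (i in 1:2000) {
    app <- runif(1, 0.5, 1)
    boot <- runif(1, 0, app)
    corr <- auc_632plus(app, boot)
    expect_gte(corr + 1e-12, max(boot, 0.5) - 1e-12)
    expect_lte(corr - 1e-12, app)
  }
  # apparent error above no-information rate: defined via R = 0
  expect_true(is.finite(auc_632plus(0.3, 0.2)))
})

test_that("the upper-left operating point matches brute-force search", {
  cv <- data.frame(threshold = c(Inf, 0.9, 0.7, 0.5, 0.2),
                   fpr = c(0, 0.1, 0.2, 0.5, 1),
                   tpr = c(0, 0.4, 0.8, 0.9, 1))
  op <- optimal_upper_left(cv)
  d <- sqrt(cv$fpr^2 + (1 - cv$tpr)^2)
  expect_equal(op$threshold, cv$threshold[which.min(d)])
  # a curve containing the perfect corner returns it
  cv2 <- rbind(cv, data.frame(threshold = 0.6, fpr = 0, tpr = 1))
  expect_equal(optimal_upper_left(cv2)$fpr, 0)
  expect_equal(optimal_upper_left(cv2)$tpr, 1)
  # exact ties break to the lower FPR
  tie <- data.frame(threshold = c(0.8, 0.4), fpr = c(0.2, 0.6),
                    tpr = c(0.4, 0.8))  # equal distances
  expect_equal(optimal_upper_left(tie)$fpr, 0.2)
})

test_that("operating-point transfer matches a confusion-matrix oracle", {
  r <- transfer_operating_point(0.5, c(0.9, 0.1), c(1, 0))
  expect_equal(c(r$mcr, r$fnr, r$fpr), c(0, 0, 0))
  r <- transfer_operating_point(1.1, c(0.9, 0.1), c(1, 0))
  expect_equal(c(r$fnr, r$fpr), c(1, 0))
  set.seed(13)
  for (i in 1:50) {
    prob <- runif(30); lab <- rbinom(30, 1, 0.4)
    if (length(unique(lab)) < 2) next
    th <- runif(1)
    r <- transfer_operating_point(th, prob, lab)
    pred <- prob >= th
    expect_identical(r$fn, sum(!pred & lab == 1))
    expect_identical(r$fp, sum(pred & lab == 0))
    expect_equal(r$mcr, mean(pred != lab), tolerance = 1e-12)
    # MCR decomposes exactly by prevalence
    prev <- mean(lab)
    expect_equal(r$mcr, prev * r$fnr + (1 - prev) * r$fpr, tolerance = 1e-12)
  }
  expect_error(transfer_operating_point(0.5, c(0.2, 0.8), c(1, 1)),
               class = "radboot_single_class")
})

test_that("percentile CIs follow the order-statistic rule", {
  expect_equal(percentile_ci(rep(3, 10)), c(3, 3))
  expect_equal(percentile_ci(1:100), c(3.475, 97.525), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    v <- rnorm(sample(10:50, 1))
    ci <- percentile_ci(v)
    expect_lte(ci[1], median(v)); expect_gte(ci[2], median(v))
  }
})

test_that("vertical-average band contains the pooled curve for homogeneous reps", {
  set.seed(15)
  prob <- rep(runif(40), 5)
  lab <- rep(rbinom(40, 1, 0.3), 5)
  rep_id <- rep(1:5, each = 40)
  band <- vertical_average_roc(prob, lab, rep_id)
  pooled <- pooled_roc(prob, lab)
  pooled_tpr <- vapply(band$fpr, function(f)
    max(pooled$tpr[pooled$fpr <= f + 1e-12]), numeric(1))
  expect_true(all(pooled_tpr >= band$tpr_low - 1e-12 &
                    pooled_tpr <= band$tpr_high + 1e-12))
})
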