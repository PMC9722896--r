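test_that("patient bootstrap partitions are disjoint with the right sizes", {
  ids <- sprintf("P%02d", 1:25)
  fracs <- vapply(1:300, function(s) {
    part <- draw_patient_bootstrap(ids, seed = s)
    expect_length(part$train, 25)
    expect_length(intersect(part$train, part$test), 0)
    expect_setequal(union(part$train, part$test), ids)
    length(part$test) / 25
  }, numeric(1))
  # mean held-out fraction ~ (1 - 1/25)^25
  expect_lt(abs(mean(fracs) - (1 - 1 / 25)^25), 0.02)
  expect_error(draw_patient_bootstrap("P1"), class = "radboot_config")
})

test_that("the inter-feature filter removes exactly one of a duplicate pair", {
  set.seed(31)
  x <- cbind(a = rnorm(50), b = rnorm(50))
  x <- cbind(x, a2 = x[, "a"])
  rem <- filter_interfeature_correlation(x, cutoff = 0.95)
  expect_identical(sum(rem[c("a", "a2")]), 1L)
  expect_false(rem["b"])
  # independent features survive
  z <- matrix(rnorm(500 * 6), 500, 6)
  expect_false(any(filter_interfeature_correlation(z, 0.95)))
  expect_warning(filter_interfeature_correlation(cbind(z, const = 1), 0.95),
                 "constant")
})

test_that("greedy filtering matches an independent rule-by-rule oracle", {
  set.seed(32)
  # five features with a known correlation structure
  base <- rnorm(300)
  x <- cbind(f1 = base,
             f2 = 0.99 * base + sqrt(1 - 0.99^2) * rnorm(300),
             f3 = rnorm(300),
             f4 = -0.98 * base + sqrt(1 - 0.98^2) * rnorm(300),
             f5 = rnorm(300))
  y <- rbinom(300, 1, plogis(base))
  rem <- filter_interfeature_correlation(x, cutoff = 0.95, y = y)
  # oracle: replay the greedy rule with independently computed quantities
  disc <- apply(x, 2, function(v) {
    a <- auc_pairwise_oracle(v, y); max(a, 1 - a)
  })
  ord <- order(disc, decreasing = TRUE)
  kept <- integer(0); rem_oracle <- logical(5)
  for (j in ord) {
    high <- any(vapply(kept, function(k) abs(cor(x[, j], x[, k])) > 0.95,
                       logical(1)))
    if (high) rem_oracle[j] <- TRUE else kept <- c(kept, j)
  }
  expect_identical(unname(rem), rem_oracle)
  # post-condition: no retained pair above the cutoff
  keep <- which(!rem)
  cm <- abs(cor(x[, keep]))
  expect_true(all(cm[upper.tri(cm)] <= 0.95))
})

test_that("fit_and_predict honours its contracts on toy data", {
  set.seed(33)
  n <- 60
  co <- data.frame(patient_id = sprintf("P%02d", 1:n),
                   bm_id = sprintf("B%02d", 1:n),
                   g1 = rnorm(n), g2 = rnorm(n))
  co$label <- as.integer(co$g1 > 0)
  tr <- co[1:40, ]; te <- co[41:60, ]
  fit <- fit_and_predict(tr, te, c("g1", "g2"), engine = light_engine(),
                         seed = 2)
  expect_equal(roc_auc(fit$test_prob, te$label), 1)
  expect_named(fit$test_prob, te$bm_id)
  fit2 <- fit_and_predict(tr, te, c("g1", "g2"), engine = light_engine(),
                          seed = 2)
  expect_identical(fit, fit2)
  tr1 <- tr; tr1$label <- 1L
  expect_error(fit_and_predict(tr1, te, c("g1", "g2")),
               class = "radboot_single_class")
})

test_that("experiments respect feature sets, repetition counts, and seeds", {
  co <- tiny_cohort()
  ex <- run_experiment(co, "clinical", n_reps = 4, seed = 3,
                       engine = light_engine())
  expect_true(all(ex$features %in% clinical_feature_names()))
  expect_identical(ex$n_reps, 4L)
  expect_identical(sort(unique(ex$probs$rep)), 1:4)
  expect_setequal(unique(ex$probs$partition), c("test", "oob", "apparent"))
  ex2 <- run_experiment(co, "clinical", n_reps = 4, seed = 3,
                        engine = light_engine())
  expect_identical(ex$probs, ex2$probs)
  rad <- run_experiment(co, "radiomic", n_reps = 2, seed = 3,
                        engine = light_engine())
  expect_true(all(grepl("^f[0-9]{3}$", rad$features)))
})

test_that("no patient ever appears in both partitions of a repetition", {
  co <- tiny_cohort()
  pat <- stats::setNames(co$patient_id, co$bm_id)
  ex <- run_experiment(co, "both", n_reps = 6, seed = 4,
                       engine = light_engine())
  for (r in unique(ex$probs$rep)) {
    d <- ex$probs[ex$probs$rep == r, ]
    test_pat <- unique(pat[d$bm_id[d$partition == "test"]])
    train_pat <- unique(pat[d$bm_id[d$partition == "oob"]])
    expect_length(intersect(test_pat, train_pat), 0)
    # every training lesion has an OOB record (possibly NA) and a resub one
    expect_setequal(unique(d$bm_id[d$partition == "oob"]),
                    unique(d$bm_id[d$partition == "apparent"]))
  }
  expect_true(all(ex$probs$probability >= 0 & ex$probs$probability <= 1,
                  na.rm = TRUE))
})

test_that("planted signal beats permuted labels across repetitions", {
  co <- tiny_cohort(seed = 5)
  ex <- run_experiment(co, "both", n_reps = 8, seed = 6,
                       engine = light_engine(n_trees = 150))
  perm <- co
  set.seed(99)
  perm$label <- sample(co$label)  # permuted outcome
  exp_perm <- run_experiment(perm, "both", n_reps = 8, seed = 6,
                             engine = light_engine(n_trees = 150))
  te <- ex$probs[ex$probs$partition == "test", ]
  tp <- exp_perm$probs[exp_perm$probs$partition == "test", ]
  expect_gt(roc_auc(te$probability, te$label),
            roc_auc(tp$probability, tp$label))
})

test_that("the automatic volume filter supports full and per-rep modes", {
  co <- tiny_cohort(seed = 7)
  full <- run_experiment(co, "both", n_reps = 2, seed = 8,
                         engine = light_engine(), volume_threshold = 0.25)
  expect_false("gtv_volume" %in% full$features)
  manual <- run_experiment(co, "both", n_reps = 2, seed = 8,
                           engine = light_engine(),
                           removed = select_features_for_removal(co, 0.25)$removed)
  expect_identical(full$probs, manual$probs)
  per_rep <- run_experiment(co, "both", n_reps = 2, seed = 8,
                            engine = light_engine(), volume_threshold = 0.25,
                            per_repetition_filter = TRUE)
  # gtv volume is the confounder: filtered out of every repetition's fit
  expect_true(all(is.na(per_rep$importance[, "gtv_volume"])))
})
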