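test_that("chi-squared matches the direct-sum oracle and known tables", {
  # progression vs primary-cancer-active, reconstructed from the study counts
  r <- chi_squared_test(rbind(c(5, 50), c(22, 46)))
  expect_equal(round(r$p_value, 3), 0.002)
  r0 <- chi_squared_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  set.seed(41)
  for (i in 1:50) {
    tab <- matrix(rpois(6, 12) + 1, 2, 3)
    mine <- chi_squared_test(tab)
    oracle <- chisq_oracle(tab)
    expect_equal(mine$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
    # and agrees with the stats:: implementation without correction
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
  expect_error(chi_squared_test(rbind(c(0, 0), c(1, 2))),
               class = "radboot_degenerate")
})

test_that("categorical volume dependence uses rank tests appropriately", {
  set.seed(42)
  vols <- c(runif(20, 0.1, 1), runif(20, 10, 30))
  split_feat <- rep(c("lo", "hi"), each = 20)  # perfect separation
  expect_lt(test_categorical_volume_dependence(split_feat, vols), 1e-6)
  # an independent feature yields roughly uniform p-values
  ps <- vapply(1:200, function(i) {
    test_categorical_volume_dependence(sample(c("a", "b"), 40, TRUE),
                                       rlnorm(40))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_warning(p <- test_categorical_volume_dependence(rep("a", 10),
                                                         rlnorm(10)),
                 "skipped")
  expect_true(is.na(p))
})

test_that("continuous volume correlation reports both scales", {
  set.seed(43)
  vols <- rlnorm(60, 1, 1)
  r <- test_continuous_volume_correlation(vols, vols)
  expect_equal(r$r_vol, 1, tolerance = 1e-12)
  r <- test_continuous_volume_correlation(vols^(1 / 3), vols)
  expect_equal(r$r_diam, 1, tolerance = 1e-12)
  expect_lt(r$r_vol, 1)
  # planted correlation recovered; p matches a direct-formula oracle
  n <- 50
  x <- 0.7 * scale(log(vols))[1:n] + sqrt(1 - 0.49) * rnorm(n)
  r <- test_continuous_volume_correlation(x, vols[1:n]^3)  # vs log-ish scale
  r2 <- test_continuous_volume_correlation(x, vols[1:n])
  expect_lt(abs(r2$r_vol - 0.7), 0.25)
  rr <- cor(x, vols[1:n])
  tt <- rr * sqrt((n - 2) / (1 - rr^2))
  expect_equal(r2$p_vol, 2 * pt(-abs(tt), n - 2), tolerance = 1e-10)
  expect_error(test_continuous_volume_correlation(rep(1, 10), rlnorm(10)),
               class = "radboot_degenerate")
})

test_that("removal selection follows the stated rule exactly", {
  co <- tiny_cohort(seed = 44)
  # baseline: threshold 1 removes nothing
  expect_length(select_features_for_removal(co, 1)$removed, 0)

  sel <- select_features_for_removal(co, 0.25)
  expect_true("gtv_volume" %in% sel$removed)
  dec <- sel$decisions
  alpha <- 0.05 / 118
  # rule-by-rule oracle on the decision table
  for (i in seq_len(nrow(dec))) {
    d <- dec[i, ]
    if (d$feature == "gtv_volume") next
    if (d$class == "continuous") {
      should <- (min(d$p_vol, d$p_diam) < alpha) &&
        max(abs(d$r_vol), abs(d$r_diam)) > 0.25
      expect_identical(d$removed, should, label = d$feature)
    } else {
      expect_identical(d$removed, isTRUE(d$p_vol < alpha), label = d$feature)
    }
  }
  # no clinical feature is volume-dependent by construction except the
  # dose prescription, whose dependence needs study-scale power to detect
  other_cats <- intersect(sel$removed,
                          c("sex", "primary_active", "site", "histology",
                            "extracranial", "systemic_therapy",
                            "steroid_response", "ecog", "location"))
  expect_length(other_cats, 0)
  study <- generate_cohort(cohort_config(), seed = 44)
  sel_study <- select_features_for_removal(study, 0.25)
  expect_true("prescription" %in% sel_study$removed)
  expect_false("sex" %in% sel_study$removed)

  # threshold 0 removes every significantly correlated continuous feature
  sel0 <- select_features_for_removal(co, 0)
  cont0 <- dec[dec$class == "continuous" & dec$feature != "gtv_volume", ]
  signif0 <- cont0$feature[pmin(cont0$p_vol, cont0$p_diam) < alpha]
  expect_true(all(signif0 %in% sel0$removed))
})

test_that("removal sets are nested and the post-filter guarantee holds", {
  co <- tiny_cohort(seed = 45)
  alpha <- 0.05 / 118
  ths <- c(1, 0.85, 0.55, 0.25, 0.1, 0)
  sets <- lapply(ths, function(t) select_features_for_removal(co, t, alpha))
  for (i in seq_along(ths)[-1]) {
    expect_true(all(sets[[i - 1]]$removed %in% sets[[i]]$removed),
                label = sprintf("nested at %.2f", ths[i]))
  }
  for (i in seq_along(ths)) {
    dec <- sets[[i]]$decisions
    kept <- dec[!dec$removed & dec$class == "continuous" &
                  dec$test != "identity", ]
    ok <- pmin(kept$p_vol, kept$p_diam) >= alpha |
      pmax(abs(kept$r_vol), abs(kept$r_diam)) <= ths[i]
    expect_true(all(ok), label = sprintf("guarantee at %.2f", ths[i]))
  }
})

test_that("site-dependence filter removes site surrogates only", {
  co <- tiny_cohort(seed = 46)
  co$histology <- as.character(co$site)  # a perfect site surrogate
  co$f010 <- 5                           # constant across sites: retained
  res <- suppressMessages(site_dependence_filter(co))
  expect_true("site" %in% res$removed)
  expect_true("histology" %in% res$removed)
  expect_false("f010" %in% res$removed)
})

test_that("univariate association tests match the study-table mechanics", {
  co <- tiny_cohort(seed = 47)
  tab <- univariate_association_tests(co)
  expect_true(all(c("age", "gtv_volume") %in%
                    tab$feature[tab$test == "rank_sum"]))
  expect_true("site" %in% tab$feature[tab$test == "chi_squared"])
  co2 <- co
  co2$sex <- "female"
  expect_warning(tab2 <- univariate_association_tests(co2), "constant")
  expect_true(is.na(tab2$p_value[tab2$feature == "sex"]))
})

test_that("the threshold sweep shares partitions and nests removals", {
  co <- tiny_cohort(seed = 48)
  sw <- suppressMessages(
    threshold_sweep(co, thresholds = c(1, 0.25), n_reps = 3, seed = 2,
                    engine = light_engine()))
  expect_true(all(sw$removals[["1"]] %in% sw$removals[["0.25"]]))
  expect_length(sw$removals[["1"]], 0)
  expect_setequal(unique(sw$metrics$group), c("all", "small", "large"))
  expect_setequal(unique(sw$metrics$threshold), c(1, 0.25))
  # baseline arm of the sweep equals a direct run on the same seeds
  direct <- run_experiment(co, "both", n_reps = 3, seed = 2,
                           engine = light_engine(), partition_seed = 2)
  em <- error_metrics(direct)
  base_all <- sw$metrics[sw$metrics$threshold == 1 &
                           sw$metrics$group == "all", ]
  expect_equal(base_all$estimate, em$estimate, tolerance = 1e-12)
})
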