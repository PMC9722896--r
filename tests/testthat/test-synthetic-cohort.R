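test_that("progression scoring applies the inclusive 25% diameter-product rule", {
  expect_identical(score_progression(c(2, 2, 2), c(2, 2, 2)), 0L)
  expect_identical(score_progression(c(1, 1, 1), c(1.25, 1, 1)), 1L)  # boundary
  expect_identical(score_progression(c(1, 1, 1), c(1.1, 1.1, 1.0)), 0L)  # 1.21
  m_pre <- rbind(c(10, 10, 10), c(4, 5, 6))
  m_post <- rbind(c(10, 10, 12.5), c(4, 5, 6))
  expect_identical(score_progression(m_pre, m_post), c(1L, 0L))
  expect_error(score_progression(c(0, 1, 1), c(1, 1, 1)),
               class = "radboot_domain")
})

test_that("cohorts are byte-identical given config and seed", {
  a <- tiny_cohort(seed = 9)
  b <- tiny_cohort(seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, tiny_cohort(seed = 10)))
})

test_that("lesions stay grouped under their patient", {
  co <- tiny_cohort()
  expect_true(all(table(co$bm_id) == 1))
  # every lesion maps to exactly one patient; patient attributes constant
  for (f in c("sex", "site", "scanner")) {
    per_pat <- tapply(co[[f]], co$patient_id, function(v) length(unique(v)))
    expect_true(all(per_pat == 1))
  }
  sh <- co[sample(nrow(co)), ]
  expect_identical(sort(paste(sh$patient_id, sh$bm_id)),
                   sort(paste(co$patient_id, co$bm_id)))
})

test_that("cohort structure matches the study sample over seeds", {
  counts <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(), seed = s)
    c(nrow(co), mean(co$label))
  }, numeric(2))
  expect_gt(mean(counts[1, ]), 116)   # ~123 lesions from 99 patients
  expect_lt(mean(counts[1, ]), 130)
  expect_gt(mean(counts[2, ]), 0.17)  # ~22% progression prevalence
  expect_lt(mean(counts[2, ]), 0.27)
  co <- generate_cohort(cohort_config(), seed = 1)
  expect_true(all(co$gtv_volume >= 0.02 & co$gtv_volume <= 30.23))
  expect_true(all(co$label %in% 0:1))
})

test_that("categorical marginals are recovered within 2 points at n = 5000", {
  co <- generate_cohort(cohort_config(n_patients = 5000), seed = 3)
  fr <- default_clinical_freqs()
  for (f in c("sex", "site", "ecog")) {
    emp <- table(co[[f]]) / nrow(co)
    expect_true(all(abs(emp[names(fr[[f]])] - fr[[f]]) < 0.02), label = f)
  }
})

test_that("volume-correlation targets are recovered at n = 5000", {
  # all proxies at rho 0.6; no scanner shift so targets are exact
  cfg <- cohort_config(n_patients = 5000, rho_range = c(0.6, 0.6),
                       scanner_shift = c(vision = 0, avanto = 0, expert = 0,
                                         sonata = 0, signa = 0))
  co <- generate_cohort(cfg, seed = 4)
  zv <- scale(log(co$gtv_volume))
  proxy_cols <- sprintf("f%03d", (cfg$n_signal + cfg$n_noise +
                                    cfg$n_mediator + 1):cfg$n_radiomic)
  r <- vapply(proxy_cols, function(f) cor(co[[f]], zv), numeric(1))
  expect_true(all(abs(r - 0.6) < 0.03))
  # zero-coupling noise feature: empirical correlation ~ 0
  noise_col <- sprintf("f%03d", cfg$n_signal + 1)
  expect_lt(abs(cor(co[[noise_col]], zv)), 0.05)
  # mediator targets
  med_r <- vapply(attr(co, "mediator_cols"),
                  function(f) cor(co[[f]], zv), numeric(1))
  expect_true(all(abs(med_r - cfg$mediator_rho) < 0.05))
})

test_that("intercept-only outcome model hits the target prevalence", {
  co <- generate_cohort(cohort_config(n_patients = 4000), seed = 5)
  om <- outcome_model(intercept = qlogis(0.22), beta_volume = 0,
                      mediator_weights = numeric(0),
                      signal_weights = rep(0, 8),
                      site_attenuation = c(lung = 0))
  lab <- assign_outcomes(co, om, seed = 6)
  expect_lt(abs(mean(lab) - 0.22), 0.02)
})

test_that("a positive volume coefficient raises the large-lesion rate", {
  co <- generate_cohort(cohort_config(n_patients = 4000), seed = 7)
  om <- outcome_model(beta_volume = 1, mediator_weights = numeric(0),
                      signal_weights = rep(0, 8))
  lab <- assign_outcomes(co, om, seed = 8)
  big <- co$gtv_volume > 7.5
  expect_gt(mean(lab[big]), mean(lab[!big]) + 0.05)
})

test_that("zero site attenuation makes the signal uninformative within site", {
  co <- generate_cohort(cohort_config(n_patients = 4000), seed = 9)
  om <- outcome_model()  # breast attenuation is 0
  lab <- assign_outcomes(co, om, seed = 10)
  sig <- as.matrix(co[, attr(co, "signal_cols")])
  score <- as.numeric(sig %*% om$signal_weights)
  breast <- co$site == "breast"
  expect_lt(abs(roc_auc(score[breast], lab[breast]) - 0.5), 0.05)
  expect_gt(roc_auc(score[co$site == "colorectal"],
                    lab[co$site == "colorectal"]), 0.75)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(bm_count_probs = c(0.5, 0.5, 0.5)),
               class = "radboot_config")
  bad <- default_clinical_freqs()
  bad$sex <- c(female = 0.7, male = 0.7)
  expect_error(cohort_config(clinical_freqs = bad), class = "radboot_config")
})

test_that("cohorts round-trip through delimited text", {
  co <- tiny_cohort()
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$gtv_volume, co$gtv_volume, tolerance = 1e-12)
  expect_identical(back$label, co$label)
  expect_identical(attr(back, "radiomic_cols"), attr(co, "radiomic_cols"))
  expect_error(read_cohort({
    p <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), p, row.names = FALSE)
    p
  }), class = "radboot_parse")
})
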