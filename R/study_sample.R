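#' Clinical feature distribution of the motivating study sample
#'
#' Per-category lesion counts and progression counts of the 123-metastasis
#' SRS cohort this framework emulates, reconstructed from the published
#' per-category frequencies and progression percentages. These counts drive
#' the generator defaults and let the univariate association tests be
#' recomputed without the patient-level data.
#'
#' @return Data frame with columns `feature`, `category`, `n_bm`,
#'   `n_progressed`.
#' @export
study_table1 <- function() {
  rows <- list(
    c("sex", "female", 66, 14), c("sex", "male", 57, 13),
    c("primary_active", "yes", 55, 5), c("primary_active", "no", 68, 22),
    c("site", "lung", 70, 9), c("site", "breast", 14, 5),
    c("site", "renal", 15, 2), c("site", "colorectal", 10, 4),
    c("site", "skin", 9, 6), c("site", "other", 5, 1),
    c("histology", "adenocarcinoma", 65, 13), c("histology", "nsclc", 36, 4),
    c("histology", "melanoma", 9, 6), c("histology", "squamous", 8, 4),
    c("histology", "other", 5, 0),
    c("extracranial", "yes", 50, 10), c("extracranial", "no", 73, 17),
    c("systemic_therapy", "radical", 10, 2),
    c("systemic_therapy", "palliative", 60, 19),
    c("systemic_therapy", "none", 53, 6),
    c("steroid_response", "fully_resolved", 31, 5),
    c("steroid_response", "improvement", 4, 2),
    c("steroid_response", "limited", 56, 14),
    c("steroid_response", "none", 11, 1),
    c("steroid_response", "unknown", 21, 5),
    c("ecog", "0", 39, 7), c("ecog", "1", 73, 16),
    c("ecog", "2", 9, 3), c("ecog", "3", 2, 1),
    c("volume_group", "small", 94, 16), c("volume_group", "large", 29, 11),
    c("location", "supratentorial", 96, 22),
    c("location", "infratentorial", 27, 5),
    c("prescription", "15Gy_1fx", 5, 0), c("prescription", "18Gy_1fx", 36, 11),
    c("prescription", "21Gy_1fx", 72, 10), c("prescription", "24Gy_3fx", 10, 6)
  )
  out <- data.frame(
    feature = vapply(rows, `[`, "", 1),
    category = vapply(rows, `[`, "", 2),
    n_bm = as.integer(vapply(rows, `[`, "", 3)),
    n_progressed = as.integer(vapply(rows, `[`, "", 4)),
    stringsAsFactors = FALSE
  )
  out
}

#' Scanner-model distribution of the motivating study sample
#'
#' Model-level lesion and progression counts (acquisition configurations
#' pooled within a scanner model). Note: the published per-configuration
#' counts sum to 121 lesions although the sample has 123; progression counts
#' sum to the full 27. The counts are reproduced as printed.
#'
#' @return Data frame `scanner`, `n_bm`, `n_progressed`.
#' @export
study_table2 <- function() {
  data.frame(
    scanner = c("vision", "avanto", "expert", "sonata", "signa"),
    n_bm = c(39L, 45L, 29L, 7L, 1L),
    n_progressed = c(11L, 5L, 9L, 2L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Univariate chi-squared tests on the study-sample counts
#'
#' Recomputes, from the reconstructed per-category counts, the chi-squared
#' p-values of each categorical clinical feature against progression, plus
#' the scanner-model tests (all five models, and the three majority models
#' Vision/Avanto/Expert).
#'
#' @return Data frame `feature`, `p_value`.
#' @export
study_univariate_pvalues <- function() {
  t1 <- study_table1()
  feats <- setdiff(unique(t1$feature), "volume_group")
  ps <- vapply(feats, function(f) {
    d <- t1[t1$feature == f, ]
    chi_squared_test(cbind(d$n_progressed, d$n_bm - d$n_progressed))$p_value
  }, numeric(1))
  t2 <- study_table2()
  p_sc5 <- chi_squared_test(cbind(t2$n_progressed,
                                  t2$n_bm - t2$n_progressed))$p_value
  t2m <- t2[t2$scanner %in% c("vision", "avanto", "expert"), ]
  p_sc3 <- chi_squared_test(cbind(t2m$n_progressed,
                                  t2m$n_bm - t2m$n_progressed))$p_value
  data.frame(feature = c(feats, "scanner_all", "scanner_major"),
             p_value = unname(c(ps, p_sc5, p_sc3)),
             stringsAsFactors = FALSE)
}

#' Overall progression prevalence of the study sample
#'
#' @return Prevalence in percent, computed from the reconstructed counts.
#' @export
study_prevalence <- function() {
  t1 <- study_table1()
  d <- t1[t1$feature == "sex", ]  # any single partition of the 123 lesions
  100 * sum(d$n_progressed) / sum(d$n_bm)
}
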