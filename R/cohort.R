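#' Clinical category frequencies of the motivating study sample
#'
#' Per-lesion marginal frequencies of the 123-metastasis SRS cohort that this
#' framework emulates, used as the generator's default categorical targets.
#'
#' @return Named list of named probability vectors (each sums to 1).
#' @export
default_clinical_freqs <- function() {
  f <- function(x) x / sum(x)
  list(
    sex = f(c(female = 66, male = 57)),
    primary_active = f(c(yes = 55, no = 68)),
    site = f(c(lung = 70, breast = 14, renal = 15,
               colorectal = 10, skin = 9, other = 5)),
    histology = f(c(adenocarcinoma = 65, nsclc = 36, melanoma = 9,
                    squamous = 8, other = 5)),
    extracranial = f(c(yes = 50, no = 73)),
    systemic_therapy = f(c(radical = 10, palliative = 60, none = 53)),
    steroid_response = f(c(fully_resolved = 31, improvement = 4,
                           limited = 56, none = 11, unknown = 21)),
    ecog = f(c(`0` = 39, `1` = 73, `2` = 9, `3` = 2)),
    location = f(c(supratentorial = 96, infratentorial = 27))
  )
}

#' Outcome model for synthetic progression labels
#'
#' Logistic model for per-lesion progression: the linear predictor is
#' `intercept + beta_volume * z(log volume) + attenuation[site] * sum(w_j s_j)`
#' where `s_j` are the designated volume-independent signal features. When
#' `intercept` is `NULL` it is solved per cohort so the expected prevalence
#' over the realised linear predictors equals `prevalence`.
#'
#' The volume dependence of progression is modelled as largely *mediated*:
#' a small direct term on standardised log-volume plus designated
#' volume-correlated mediator features (hypoxia/vascularisation-like
#' markers that both track lesion size and drive progression). A model
#' trained on all features exploits the mediators (and volume proxies),
#' coupling its predictions to volume; once the decorrelation filter
#' removes them, the volume-independent signal still carries the outcome.
#' Defaults encode the study sample: 22.0% prevalence, and mediator/direct
#' coefficients calibrated so the marginal progression split matches the
#' observed 17.0% (< 7.5 cc) vs 37.9% (> 7.5 cc). Signal weights decline
#' over 8 features (radiomic importance concentrated in a few dominant
#' features); per-site attenuation orders the sites as in the per-site
#' accuracy table (colorectal/skin most predictable, breast at chance).
#'
#' @param intercept logit-scale intercept, or `NULL` to solve for `prevalence`.
#' @param prevalence target marginal progression probability.
#' @param beta_volume direct coefficient on standardised log-volume.
#' @param mediator_weights coefficients of the volume-correlated mediator
#'   features.
#' @param signal_weights coefficients of the volume-independent signal
#'   features.
#' @param site_attenuation named multiplier on the volume-independent signal
#'   term per primary site.
#' @return An object of class `srs_outcome_model`.
#' @export
outcome_model <- function(intercept = NULL,
                          prevalence = 0.22,
                          beta_volume = 0.1,
                          mediator_weights = rep(0.58, 4),
                          signal_weights = 2.0 * 0.65^(0:7),
                          site_attenuation = c(lung = 0.8, breast = 0,
                                               renal = 1, colorectal = 1.4,
                                               skin = 1.2, other = 1)) {
  stopifnot(prevalence > 0, prevalence < 1)
  structure(list(intercept = intercept, prevalence = prevalence,
                 beta_volume = beta_volume,
                 mediator_weights = mediator_weights,
                 signal_weights = signal_weights,
                 site_attenuation = site_attenuation),
            class = "srs_outcome_model")
}

#' Synthetic cohort configuration
#'
#' Parameterises the generator that emulates the study sample: 99 patients
#' with 1-3 brain metastases each (about 123 lesions), 12 clinical features
#' with the published category frequencies, 107 continuous radiomic-like
#' features, log-normal lesion volumes with median 3.07 cc clamped to
#' `[0.02, 30.23]` cc, five scanner models with the published assignment
#' frequencies, and ~74% of radiomic features volume-correlated.
#'
#' Radiomic feature layout: the first `n_signal` columns are independent
#' standard-normal volume-independent signal features (they drive the
#' outcome); the next `n_noise` are pure noise; the next `n_mediator` are
#' volume-correlated mediators `mediator_rho * z(log volume) +
#' sqrt(1 - mediator_rho^2) * noise` that also enter the outcome; the rest
#' are plain volume proxies `rho * z(log volume) + sqrt(1 - rho^2) * noise`
#' with correlation targets spread over `rho_range`. Each scanner model adds
#' a per-feature offset with standard deviation `scanner_shift[model]` and
#' scales feature noise by `scanner_scale[model]`.
#'
#' @param n_patients number of patients.
#' @param bm_count_probs probabilities of 1, 2, or 3 lesions per patient.
#' @param clinical_freqs categorical targets, see [default_clinical_freqs()].
#' @param volume_meanlog,volume_sdlog log-normal volume parameters (cc).
#' @param volume_range clamp applied to drawn volumes (cc).
#' @param n_radiomic,n_signal,n_noise,n_mediator radiomic column counts; the
#'   remaining `n_radiomic - n_signal - n_noise - n_mediator` columns are
#'   plain volume proxies.
#' @param mediator_rho volume-correlation target of the mediator features.
#' @param rho_range range of per-proxy volume-correlation targets; targets are
#'   an evenly spaced deterministic sequence over this range.
#' @param age_mean,age_sd,age_range age model (years).
#' @param scanner_probs per-lesion scanner-model assignment probabilities
#'   (applied per patient).
#' @param scanner_shift,scanner_scale per-model additive offset SD and
#'   multiplicative noise scale for the domain-shift mechanism.
#' @param outcome an [outcome_model()]; its signal/mediator weight vectors
#'   are truncated or zero-padded to `n_signal` / `n_mediator`.
#' @param censor_prob probability a truly progressing lesion is lost to
#'   follow-up and scored as non-progression (off by default).
#' @param dose_rule_violation probability a small lesion does not receive the
#'   most aggressive prescription (21 Gy in 1 fraction below 7.5 cc).
#' @param seed generator seed.
#' @return An object of class `srs_cohort_config`.
#' @export
cohort_config <- function(n_patients = 99,
                          bm_count_probs = c(0.79, 0.18, 0.03),
                          clinical_freqs = default_clinical_freqs(),
                          volume_meanlog = log(3.07),
                          volume_sdlog = 1.3,
                          volume_range = c(0.02, 30.23),
                          n_radiomic = 107,
                          n_signal = 8,
                          n_noise = 16,
                          n_mediator = 4,
                          mediator_rho = 0.55,
                          rho_range = c(0.35, 0.9),
                          age_mean = 59, age_sd = 10,
                          age_range = c(38.4, 86.0),
                          scanner_probs = c(vision = 39, avanto = 45,
                                            expert = 29, sonata = 7,
                                            signa = 1) / 121,
                          scanner_shift = c(vision = 0, avanto = 0.15,
                                            expert = 0.05, sonata = 0.1,
                                            signa = 0.1),
                          scanner_scale = c(vision = 1, avanto = 1,
                                            expert = 1, sonata = 1,
                                            signa = 1),
                          outcome = outcome_model(),
                          censor_prob = 0,
                          dose_rule_violation = 0.05,
                          seed = 1) {
  stopifnot(n_patients >= 2, length(bm_count_probs) == 3,
            n_signal + n_noise + n_mediator < n_radiomic,
            mediator_rho >= -1, mediator_rho <= 1,
            all(rho_range >= -1), all(rho_range <= 1))
  if (abs(sum(bm_count_probs) - 1) > 1e-8)
    stop_radboot("bm_count_probs must sum to 1", "radboot_config")
  for (nm in names(clinical_freqs)) {
    fr <- clinical_freqs[[nm]]
    if (abs(sum(fr) - 1) > 1e-8 || any(fr < 0))
      stop_radboot(sprintf("frequencies for '%s' must be non-negative and sum to 1", nm),
                   "radboot_config")
  }
  if (abs(sum(scanner_probs) - 1) > 1e-8)
    stop_radboot("scanner_probs must sum to 1", "radboot_config")
  n_proxy <- n_radiomic - n_signal - n_noise - n_mediator
  structure(list(
    n_patients = n_patients, bm_count_probs = bm_count_probs,
    clinical_freqs = clinical_freqs,
    volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
    volume_range = volume_range,
    n_radiomic = n_radiomic, n_signal = n_signal, n_noise = n_noise,
    n_mediator = n_mediator, mediator_rho = mediator_rho,
    n_proxy = n_proxy,
    proxy_rho = seq(rho_range[1], rho_range[2], length.out = n_proxy),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    scanner_probs = scanner_probs, scanner_shift = scanner_shift,
    scanner_scale = scanner_scale,
    outcome = outcome, censor_prob = censor_prob,
    dose_rule_violation = dose_rule_violation, seed = seed
  ), class = "srs_cohort_config")
}

#' Names of the 12 clinical feature columns
#' @return Character vector.
#' @export
clinical_feature_names <- function() {
  c("sex", "age", "primary_active", "site", "histology", "extracranial",
    "systemic_therapy", "steroid_response", "ecog", "gtv_volume",
    "location", "prescription")
}

radiomic_feature_names <- function(n = 107) sprintf("f%03d", seq_len(n))

#' Generate a synthetic SRS cohort
#'
#' Draws a cohort of brain metastases with the statistical structure the
#' downstream analysis assumes: patient-grouped lesions, categorical clinical
#' features at the configured frequencies, clamped log-normal volumes, the
#' prescription dose rule (most aggressive below 7.5 cc), scanner assignment
#' with per-model covariate shift, radiomic columns with controlled volume
#' correlations, and logistic progression labels via [assign_outcomes()].
#' Identical config and seed give a byte-identical cohort.
#'
#' @param config an [cohort_config()] object.
#' @param seed optional override of `config$seed`.
#' @return A data frame of class `srs_cohort`, one row per lesion: columns
#'   `patient_id`, `bm_id`, the 12 clinical features, `scanner`,
#'   `f001`...`f107`, `label`; attributes `radiomic_cols`, `signal_cols`,
#'   `clinical_cols`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "srs_cohort_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    np <- config$n_patients
    n_bm <- sample(1:3, np, replace = TRUE, prob = config$bm_count_probs)
    n <- sum(n_bm)
    patient <- rep(sprintf("P%03d", seq_len(np)), times = n_bm)
    bm_id <- sprintf("B%03d", seq_len(n))

    draw_cat <- function(fr, m) {
      names(fr)[sample.int(length(fr), m, replace = TRUE, prob = fr)]
    }
    fr <- config$clinical_freqs
    # patient-level attributes, replicated over the patient's lesions
    pat_rep <- function(x) rep(x, times = n_bm)
    sex <- pat_rep(draw_cat(fr$sex, np))
    age <- pat_rep(pmin(pmax(rnorm(np, config$age_mean, config$age_sd),
                             config$age_range[1]), config$age_range[2]))
    primary_active <- pat_rep(draw_cat(fr$primary_active, np))
    site <- pat_rep(draw_cat(fr$site, np))
    histology <- pat_rep(draw_cat(fr$histology, np))
    extracranial <- pat_rep(draw_cat(fr$extracranial, np))
    systemic_therapy <- pat_rep(draw_cat(fr$systemic_therapy, np))
    steroid_response <- pat_rep(draw_cat(fr$steroid_response, np))
    ecog <- pat_rep(draw_cat(fr$ecog, np))
    scanner <- pat_rep(draw_cat(config$scanner_probs, np))

    # per-lesion attributes
    location <- draw_cat(fr$location, n)
    volume <- pmin(pmax(rlnorm(n, config$volume_meanlog, config$volume_sdlog),
                        config$volume_range[1]), config$volume_range[2])

    # prescription: most aggressive (21 Gy / 1 fx) below 7.5 cc, with a small
    # violation rate; larger lesions get a less aggressive prescription
    small <- volume < 7.5
    presc <- character(n)
    viol <- runif(n) < config$dose_rule_violation
    presc[small & !viol] <- "21Gy_1fx"
    presc[small & viol] <- "18Gy_1fx"
    presc[!small] <- c("15Gy_1fx", "18Gy_1fx", "24Gy_3fx")[
      sample.int(3, sum(!small), replace = TRUE, prob = c(0.15, 0.5, 0.35))]

    zv <- as.numeric(scale(log(volume)))
    ns <- config$n_signal; nn <- config$n_noise
    nm <- config$n_mediator; npx <- config$n_proxy
    signal <- matrix(rnorm(n * ns), n, ns)
    noise <- matrix(rnorm(n * nn), n, nn)
    mediator <- sqrt(1 - config$mediator_rho^2) * matrix(rnorm(n * nm), n, nm) +
      outer(zv, rep(config$mediator_rho, nm))
    eps <- matrix(rnorm(n * npx), n, npx)
    proxy <- sweep(eps, 2, sqrt(1 - config$proxy_rho^2), `*`) +
      outer(zv, config$proxy_rho)
    radiomic <- cbind(signal, noise, mediator, proxy)
    colnames(radiomic) <- radiomic_feature_names(config$n_radiomic)

    # scanner domain shift: per-model, per-feature additive offset + scale
    models <- names(config$scanner_probs)
    offsets <- matrix(rnorm(length(models) * config$n_radiomic), length(models),
                      dimnames = list(models, NULL))
    offsets <- offsets * config$scanner_shift[models]
    radiomic <- radiomic * config$scanner_scale[scanner] + offsets[scanner, ]

    cohort <- data.frame(
      patient_id = patient, bm_id = bm_id,
      sex = sex, age = age, primary_active = primary_active, site = site,
      histology = histology, extracranial = extracranial,
      systemic_therapy = systemic_therapy, steroid_response = steroid_response,
      ecog = ecog, gtv_volume = volume, location = location,
      prescription = presc, scanner = scanner,
      stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, as.data.frame(radiomic))

    attr(cohort, "radiomic_cols") <- colnames(radiomic)
    attr(cohort, "signal_cols") <- colnames(radiomic)[seq_len(ns)]
    attr(cohort, "mediator_cols") <- colnames(radiomic)[ns + nn + seq_len(nm)]
    attr(cohort, "clinical_cols") <- clinical_feature_names()
    attr(cohort, "config") <- config
    class(cohort) <- c("srs_cohort", "data.frame")

    # labels drawn from the latent (pre-scanner-shift) signal: the scanner is
    # a measurement artefact, not biology
    # outcome weights follow the configured column counts (truncate / pad 0)
    fit_w <- function(w, k) if (length(w) >= k) w[seq_len(k)]
                            else c(w, rep(0, k - length(w)))
    om <- config$outcome
    om$signal_weights <- fit_w(om$signal_weights, ns)
    om$mediator_weights <- fit_w(om$mediator_weights, nm)
    cohort$label <- assign_outcomes(cohort, om,
                                    seed = derive_seed(seed, 104729),
                                    signal = signal, mediators = mediator)
    if (config$censor_prob > 0) {
      cens <- runif(n) < config$censor_prob
      cohort$label[cens] <- 0L
    }
    cohort
  })
}

#' Assign progression labels from an outcome model
#'
#' Computes the logistic linear predictor for each lesion (see
#' [outcome_model()]) and draws independent Bernoulli labels. When the model
#' intercept is `NULL` it is solved (deterministically, by root finding) so
#' that the mean progression probability over the realised linear predictors
#' equals the model's target prevalence.
#'
#' @param records an `srs_cohort` data frame (needs `gtv_volume`, `site`).
#' @param model an [outcome_model()].
#' @param seed seed for the label draws.
#' @param signal optional matrix of signal-feature values; defaults to the
#'   cohort's designated signal columns.
#' @param mediators optional matrix of mediator-feature values; defaults to
#'   the cohort's designated mediator columns (zero contribution if absent).
#' @return Integer 0/1 label vector.
#' @export
assign_outcomes <- function(records, model = outcome_model(), seed = 1,
                            signal = NULL, mediators = NULL) {
  stopifnot(inherits(model, "srs_outcome_model"))
  n <- nrow(records)
  zv <- as.numeric(scale(log(records$gtv_volume)))
  if (is.null(signal)) {
    sc <- attr(records, "signal_cols")
    if (is.null(sc)) sc <- radiomic_feature_names(length(model$signal_weights))
    signal <- as.matrix(records[, sc, drop = FALSE])
  }
  w <- model$signal_weights
  stopifnot(ncol(signal) == length(w))
  wm <- model$mediator_weights %||% numeric(0)
  med_term <- 0
  if (length(wm)) {
    if (is.null(mediators)) {
      mc <- attr(records, "mediator_cols")
      mediators <- if (is.null(mc)) NULL
                   else as.matrix(records[, mc, drop = FALSE])
    }
    if (!is.null(mediators)) {
      stopifnot(ncol(mediators) == length(wm))
      med_term <- as.numeric(mediators %*% wm)
    }
  }
  att <- model$site_attenuation[records$site]
  att[is.na(att)] <- 1
  eta0 <- model$beta_volume * zv + med_term +
    as.numeric(att) * as.numeric(signal %*% w)
  b0 <- model$intercept
  if (is.null(b0)) {
    b0 <- uniroot(function(b) mean(plogis(b + eta0)) - model$prevalence,
                  interval = c(-20, 20), tol = 1e-10)$root
  }
  p <- plogis(b0 + eta0)
  with_seed(seed, as.integer(runif(n) < p))
}

#' Score progression from perpendicular diameter triples
#'
#' A lesion is scored as progressing when the product of its three
#' perpendicular maximum diameters (superior-inferior, mediolateral,
#' posterior-anterior) increases by at least 25% post-treatment; the 25%
#' boundary is inclusive.
#'
#' @param pre,post numeric length-3 vectors or 3-column matrices of positive
#'   diameters (mm).
#' @return Integer 0/1 vector.
#' @examples
#' score_progression(c(1, 1, 1), c(1.25, 1, 1))  # 1 (exactly +25%)
#' score_progression(c(1, 1, 1), c(1.1, 1.1, 1)) # 0 (+21%)
#' @export
score_progression <- function(pre, post) {
  pre <- rbind(pre); post <- rbind(post)
  stopifnot(ncol(pre) == 3, ncol(post) == 3, nrow(pre) == nrow(post))
  if (any(pre <= 0) || any(post <= 0))
    stop_radboot("diameters must be positive", "radboot_domain")
  ratio <- apply(post, 1, prod) / apply(pre, 1, prod)
  as.integer(ratio >= 1.25)
}

#' Write / read a cohort as delimited text
#'
#' One row per lesion; columns `patient_id`, `bm_id`, the 12 clinical
#' features, `scanner`, `f001`..., `label`. `write_cohort` also writes a
#' `<path>.json` sidecar (feature column lists) when jsonlite is available.
#'
#' @param cohort an `srs_cohort`.
#' @param path CSV file path.
#' @return `read_cohort` returns an `srs_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(radiomic_cols = attr(cohort, "radiomic_cols"),
                 signal_cols = attr(cohort, "signal_cols"),
                 clinical_cols = attr(cohort, "clinical_cols"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "bm_id", "label", clinical_feature_names())
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop_radboot(paste("cohort file missing columns:",
                       paste(miss, collapse = ", ")), "radboot_parse")
  rcols <- grep("^f[0-9]{3}$", names(cohort), value = TRUE)
  attr(cohort, "radiomic_cols") <- rcols
  attr(cohort, "clinical_cols") <- clinical_feature_names()
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path) && requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(cohort, "signal_cols") <- meta$signal_cols
  }
  class(cohort) <- c("srs_cohort", "data.frame")
  cohort
}
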