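small_cohort <- function(n = 250, seed = 101) {
  generate_cohort(generator_config(n_patients = n, seed = seed))
}

small_config <- function(...) {
  harness_config(model_modes = c("baseline", "trajectory"),
                 repetitions = 2, outer_folds = 10, lambda_grid = 1,
                 bootstrap_B = 100,
                 variables = c("gcs_total", "lactate", "heart_rate"),
                 seed = 7, ...)
}

test_that("repeated nested CV produces R x K fold AUCs per mode", {
  coh <- small_cohort()
  r <- nested_cv(coh$stays, coh$observations, coh$notes, small_config())
  for (m in names(r$modes)) {
    expect_length(r$modes[[m]]$fold_auc, 20)  # R=2, K=10
    expect_true(all(r$modes[[m]]$fold_auc >= 0 &
                      r$modes[[m]]$fold_auc <= 1))
    expect_equal(r$modes[[m]]$auc, mean(r$modes[[m]]$fold_auc))
    ci <- r$modes[[m]]$auc_ci
    expect_lte(ci[1], r$modes[[m]]$auc)
    expect_gte(ci[2], r$modes[[m]]$auc)
  }
  # deterministic for a fixed seed
  r2 <- nested_cv(coh$stays, coh$observations, coh$notes, small_config())
  expect_equal(r$modes$baseline$fold_auc, r2$modes$baseline$fold_auc)
})

test_that("cross-site validation fills every off-diagonal cell", {
  coh <- small_cohort(n = 500, seed = 103)
  cfg <- harness_config(model_modes = c("baseline", "trajectory_nlp"),
                        lambda_grid = 10, vocab_k = 50,
                        variables = c("gcs_total", "lactate", "heart_rate"),
                        seed = 3)
  xs <- cross_site(coh$stays, coh$observations, coh$notes, cfg)
  expect_equal(dim(xs$auc), c(3, 3, 2))
  for (m in 1:2) {
    a <- xs$auc[, , m]
    expect_true(all(is.na(diag(a))))
    expect_equal(sum(!is.na(a)), 6)  # ordered pairs of 3 sites
    expect_true(all(a[!is.na(a)] >= 0 & a[!is.na(a)] <= 1))
  }
})

test_that("two statistically identical sites transfer without AUC loss", {
  # force a single generative distribution across two site labels
  se <- default_site_effects()
  se$sites <- se$sites[1:2, ]
  se$sites$weight <- c(0.5, 0.5)
  se$sites$prevalence_scale <- c(1, 1)
  se$sites$missing_scale <- c(1, 1)
  se$sites$age_shift <- c(0, 0)
  se$term_scale <- NULL
  coh <- generate_cohort(generator_config(2000, site_effects = se, seed = 107))
  cfg <- harness_config(model_modes = "trajectory", lambda_grid = 10,
                        repetitions = 1, outer_folds = 5, bootstrap_B = 100,
                        variables = c("gcs_total", "gcs_verbal", "sbp",
                                      "lactate"),
                        seed = 11)
  xs <- cross_site(coh$stays, coh$observations, coh$notes, cfg)
  within <- nested_cv(coh$stays, coh$observations, coh$notes, cfg)
  transfer <- mean(xs$auc[, , 1], na.rm = TRUE)
  expect_lt(abs(transfer - within$modes$trajectory$auc), 0.05)
})

test_that("out-of-vocabulary test notes contribute nothing to predictions", {
  coh <- small_cohort(n = 300, seed = 109)
  cfg <- harness_config(model_modes = "trajectory_nlp", lambda_grid = 10,
                        vocab_k = 50,
                        variables = c("gcs_total", "lactate", "heart_rate"),
                        seed = 5)
  fit <- fit_mortality_model(coh$stays, coh$observations, coh$notes,
                             "trajectory_nlp", cfg)
  new_stays <- coh$stays[1:20, ]
  new_obs <- coh$observations[coh$observations$patient_id %in%
                                new_stays$patient_id, ]
  oov_notes <- data.frame(patient_id = new_stays$patient_id, t = 1,
                          text = "zzzunseen qqqterm xxxnothing",
                          stringsAsFactors = FALSE)
  no_notes <- oov_notes[0, ]
  p_oov <- predict(fit, new_stays, new_obs, oov_notes)
  p_none <- predict(fit, new_stays, new_obs, no_notes)
  expect_equal(p_oov, p_none, tolerance = 1e-12)
})

test_that("the alive-at-24h sensitivity analysis restricts the cohort correctly", {
  coh <- small_cohort(n = 2500, seed = 111)
  st <- coh$stays
  early <- sum(st$died_in_hospital & st$death_time_hours < 24)
  deaths <- sum(st$died_in_hospital)
  # about 85.3% of deaths remain after dropping early decedents
  se <- sqrt(0.147 * (1 - 0.147) / deaths)
  expect_lt(abs(early / deaths - 0.147), 3 * se)
  cfg <- small_config()
  r_all <- nested_cv(st, coh$observations, coh$notes, cfg)
  r_restr <- sensitivity_alive_24h(st, coh$observations, coh$notes, cfg)
  expect_equal(r_restr$n, nrow(st) - early)
  expect_lt(r_restr$prevalence, r_all$prevalence)

  # with no early deaths the restricted analysis is the full analysis
  st2 <- st
  st2$death_time_hours[st2$died_in_hospital] <- 48
  r1 <- nested_cv(st2, coh$observations, coh$notes, cfg)
  r2 <- sensitivity_alive_24h(st2, coh$observations, coh$notes, cfg)
  expect_equal(r1$modes$baseline$fold_auc, r2$modes$baseline$fold_auc)
})

test_that("construct validity flags outcome-linked measures and not constants", {
  coh <- small_cohort(n = 1500, seed = 113)
  fm <- build_feature_matrix(coh$stays, coh$observations,
                             variables = c("gcs_total", "temperature"),
                             mode = "trajectory")
  cv <- construct_validity(fm)
  row <- cv[cv$measure == "gcs_total.slope", ]
  expect_gt(row$mean_survivor, row$mean_nonsurvivor)
  expect_lt(row$t_p_value, 0.001)
  # constant feature: equal means, Wilcoxon p = 1
  fm$x[, "temperature.sd"] <- 1
  cv2 <- construct_validity(fm)
  row2 <- cv2[cv2$measure == "temperature.sd", ]
  expect_equal(row2$mean_survivor, row2$mean_nonsurvivor)
  expect_equal(row2$wilcoxon_p_value, 1)
})
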