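short_config <- pbpk_config(duration_h = 12, output_interval_h = 0.25)

test_that("a noise-free single-subject study equals the model curve", {
  spec <- study_spec("clean", dose_mg = 50, n_subjects = 1,
                     female_fraction = 0, weight_mean = 68, weight_sd = 0,
                     residual_cv = 0, cv_organs = 0,
                     sampling_times_h = c(0.5, 1, 2, 4, 8, 12), seed = 1)
  study <- generate_observed_study(spec, ref_drug, short_config)
  dense <- study$simulated |> dplyr::filter(subject_id == 1)
  expected <- stats::approx(dense$time_h, dense$conc_ng_ml,
                            xout = spec$sampling_times_h)$y
  expect_equal(study$profiles$conc_ng_ml, expected)
  expect_equal(nrow(study$profiles), 6)
})

test_that("residual noise reproduces the requested CV at each sampling time", {
  spec <- study_spec("noisy", dose_mg = 50, n_subjects = 200,
                     weight_mean = 68, weight_sd = 0, residual_cv = 0.2,
                     cv_organs = 0, sampling_times_h = c(1, 2, 6, 12), seed = 5)
  study <- generate_observed_study(spec, ref_drug, short_config)
  cvs <- study$profiles |>
    dplyr::group_by(time_h) |>
    dplyr::summarise(cv = stats::sd(conc_ng_ml) / mean(conc_ng_ml))
  expect_true(all(cvs$cv > 0.15 & cvs$cv < 0.25))
})

test_that("study generation is deterministic given the seed", {
  spec <- study_spec("det", n_subjects = 3, weight_sd = 4, seed = 9,
                     sampling_times_h = c(1, 4, 12))
  s1 <- generate_observed_study(spec, ref_drug, short_config)
  s2 <- generate_observed_study(spec, ref_drug, short_config)
  expect_equal(s1$profiles, s2$profiles)
})

test_that("study specs built from the packaged table mirror its demographics", {
  spec1 <- study_spec_from_table(1, dose_mg = 50, route = "oral")
  expect_equal(spec1$n_subjects, 11)
  expect_equal(spec1$dose_mg, 50)
  expect_equal(spec1$weight_mean, 68.1)
  expect_equal(spec1$weight_sd, 7.1)
  spec5 <- study_spec_from_table(5, subgroup = "severe")
  expect_equal(spec5$n_subjects, 96)
  expect_equal(spec5$population, "severe")
  expect_error(study_spec_from_table(1, dose_mg = 75), "not administered")
})

test_that("packaged reference tables load with the printed key values", {
  tabs <- load_reference_tables()
  expect_equal(
    tabs$drug_inputs$input_value[tabs$drug_inputs$parameter == "km_umol_l"],
    "190")
  oral_healthy <- dplyr::filter(tabs$pk_ratios, route == "oral",
                                population == "healthy")
  expect_equal(nrow(oral_healthy), 14)
  study5 <- dplyr::filter(tabs$studies, study_id == 5)
  expect_true(all(study5$n_subjects == 96))
  expect_true(all(study5$population == "ckd"))
  expect_equal(nrow(tabs$afe), 6)
})

test_that("self-consistent synthetic studies recover ratios centred on 1", {
  spec <- study_spec("recovery", dose_mg = 50, n_subjects = 30,
                     weight_mean = 68, weight_sd = 6, residual_cv = 0.15,
                     cv_organs = 0.15, seed = 17,
                     sampling_times_h = c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12))
  study <- generate_observed_study(spec, ref_drug, short_config)
  obs <- nca_population(study$profiles)
  pred <- compute_nca(structure(list(data = study$mean_profile, dose_mg = 50),
                                class = "pbpk_profile"))
  r_auc <- pred$auc_last_ng_h_ml / obs$auc_last_ng_h_ml
  se <- stats::sd(r_auc) / sqrt(length(r_auc))
  expect_lt(abs(mean(r_auc) - 1), 3 * se + 0.05)
  expect_lt(mean(!two_fold_pass(r_auc)), 0.1)
})

test_that("an injected 2x clearance error shifts clearance ratios to ~0.5 and trips the flag", {
  fast <- drug_parameters(metabolic_scaling = 2 * ref_drug$metabolic_scaling,
                          renal_clearance_l_h_kg = 2 * ref_drug$renal_clearance_l_h_kg)
  spec <- study_spec("biased", dose_mg = 50, n_subjects = 30,
                     weight_mean = 68, weight_sd = 6, residual_cv = 0.15,
                     cv_organs = 0.15, seed = 17,
                     sampling_times_h = c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12))
  study <- generate_observed_study(spec, fast, short_config)
  obs <- nca_population(study$profiles)
  # evaluating model: the unbiased drug, via its own clean mean profile
  clean <- generate_observed_study(
    study_spec("eval", dose_mg = 50, n_subjects = 30, weight_mean = 68,
               weight_sd = 6, residual_cv = 0, cv_organs = 0.15, seed = 17,
               sampling_times_h = c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12)),
    ref_drug, short_config)
  pred <- compute_nca(structure(list(data = clean$mean_profile, dose_mg = 50),
                                class = "pbpk_profile"))
  r_cl <- pred$cl_over_f_l_h / obs$cl_over_f_l_h
  expect_equal(mean(r_cl), 0.5, tolerance = 0.15)
  # the shift parks the cohort at the two-fold boundary: an appreciable
  # share of subjects trips the flag, unlike the self-consistent study
  expect_gt(mean(!two_fold_pass(r_cl)), 0.05)
  se <- stats::sd(r_cl) / sqrt(length(r_cl))
  expect_lt(mean(r_cl) + 3 * se, 0.7)
})
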