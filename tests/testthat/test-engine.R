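test_that("a zero dose yields an all-zero profile and ledger", {
  prof <- pbpk_simulate(ref_phys, ref_drug, dose_regimen("oral", 0), fast_config)
  expect_true(all(prof$data$conc_ng_ml == 0))
  expect_true(all(abs(prof$ledger$balance_error) < 1e-12))
  expect_true(all(prof$ledger$in_body == 0))
})

test_that("with linear renal elimination only, AUC matches the closed form to 0.1%", {
  # analytic limit: a single linear clearance CL drawn from the arterial
  # pool gives CL * AUC_art = dose exactly; integrating the lung and
  # arterial balances then yields AUC_ven = AUC_art * (CO + CL) / CO, so the
  # venous-sampled AUC has the closed form dose * (CO + CL) / (CO * CL)
  # independent of every organ volume and partition coefficient.
  drug <- drug_parameters(metabolic_scaling = 0)
  config <- pbpk_config(duration_h = 96, output_interval_h = 0.1)
  prof <- pbpk_simulate(ref_phys, drug, dose_regimen("iv_infusion", 25), config)
  cl <- renal_clearance(drug, ref_phys)
  co <- ref_phys$cardiac_output
  nca <- compute_nca(prof)
  expect_equal(nca$auc_inf_ng_h_ml, 25e6 / 1000 * (co + cl) / (co * cl),
               tolerance = 1e-3)
  expect_equal(nca$cl_over_f_l_h, cl * co / (co + cl), tolerance = 1e-3)
})

test_that("the calibrated model reproduces the intravenous clearance", {
  prof <- pbpk_simulate(ref_phys, ref_drug, dose_regimen("iv_infusion", 25))
  expect_equal(compute_nca(prof)$cl_over_f_l_h, 52.1, tolerance = 0.005)
})

test_that("mass balance closes within 0.1% of the administered dose at all times", {
  for (reg in list(dose_regimen("oral", 50), dose_regimen("iv_infusion", 25),
                   dose_regimen("oral", 50, formulation = "solution"))) {
    prof <- pbpk_simulate(ref_phys, ref_drug, reg)
    rel <- abs(prof$ledger$balance_error) / prof$dose_mg
    expect_lt(max(rel), 1e-3)
  }
})

test_that("exposure is dose-proportional from 25 to 200 mg within 2%", {
  doses <- c(25, 50, 100, 200)
  nca <- purrr::map_dfr(doses, function(d) {
    compute_nca(pbpk_simulate(ref_phys, ref_drug, dose_regimen("oral", d)))
  })
  auc_per_dose <- nca$auc_inf_ng_h_ml / doses
  cmax_per_dose <- nca$cmax_ng_ml / doses
  expect_lt(diff(range(auc_per_dose)) / mean(auc_per_dose), 0.02)
  expect_lt(diff(range(cmax_per_dose)) / mean(cmax_per_dose), 0.02)
})

test_that("halving solver tolerances changes Cmax and AUC by far less than 0.1%", {
  base <- pbpk_simulate(ref_phys, ref_drug, dose_regimen("oral", 50))
  tight <- pbpk_simulate(ref_phys, ref_drug, dose_regimen("oral", 50),
                         pbpk_config(rtol = 0.5e-8, atol = 0.5e-6))
  n1 <- compute_nca(base); n2 <- compute_nca(tight)
  expect_equal(n1$cmax_ng_ml, n2$cmax_ng_ml, tolerance = 1e-3)
  expect_equal(n1$auc_inf_ng_h_ml, n2$auc_inf_ng_h_ml, tolerance = 1e-3)
})

test_that("oral absorption peaks within 1-2 h in the healthy reference", {
  prof <- pbpk_simulate(ref_phys, ref_drug, dose_regimen("oral", 50))
  tmax <- compute_nca(prof)$tmax_h
  expect_gte(tmax, 1)
  expect_lte(tmax, 2)
})

test_that("a Weibull shape above 1 delays early release", {
  steep <- drug_parameters(weibull_shape = 2)
  p1 <- pbpk_simulate(ref_phys, ref_drug, dose_regimen("oral", 50), fast_config)
  p2 <- pbpk_simulate(ref_phys, steep, dose_regimen("oral", 50), fast_config)
  early <- p1$data$time_h <= 0.5
  expect_true(all(p2$data$conc_ng_ml[early] <= p1$data$conc_ng_ml[early]))
})

test_that("a single-subject population reproduces the single-subject simulation", {
  pop <- sample_population(1, 0, c(30, 30), 68, 0, cv_organs = 0, seed = 1)
  set_prof <- pbpk_simulate_population(pop, ref_drug, dose_regimen("oral", 50),
                                       fast_config)
  single <- pbpk_simulate(pop$phys[[1]], ref_drug, dose_regimen("oral", 50),
                          fast_config)
  expect_equal(set_prof$conc_ng_ml, single$data$conc_ng_ml)
  expect_equal(mean_profile(set_prof)$data$conc_ng_ml, single$data$conc_ng_ml)
})

test_that("15% organ variability propagates to a plausible Cmax spread", {
  pop <- sample_population(60, 0.5, c(18, 45), 70, 8, cv_organs = 0.15, seed = 21)
  sims <- pbpk_simulate_population(pop, ref_drug, dose_regimen("oral", 50),
                                   fast_config)
  cmax <- sims |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(cmax = max(conc_ng_ml))
  cv <- stats::sd(cmax$cmax) / mean(cmax$cmax)
  expect_gt(cv, 0.08)
  expect_lt(cv, 0.30)
})

test_that("moderate CKD raises population mean exposure at an equal dose", {
  healthy <- sample_population(10, 0.5, c(18, 45), 63, 5, stage = "healthy",
                               seed = 31)
  moderate <- sample_population(10, 0.5, c(18, 45), 63, 5, stage = "moderate",
                                seed = 31)
  auc_mean <- function(pop) {
    sims <- pbpk_simulate_population(pop, ref_drug, dose_regimen("oral", 50))
    mean(nca_population(sims)$auc_inf_ng_h_ml)
  }
  expect_gt(auc_mean(moderate), auc_mean(healthy))
})
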