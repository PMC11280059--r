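test_that("reference individual carries healthy system parameters and conserves flow", {
  phys <- build_reference_individual(70, "M", 30)
  expect_equal(phys$hematocrit, 0.47)
  expect_gt(phys$egfr_ml_min, 60)
  expect_equal(phys$gastric_emptying_min, 15)
  expect_equal(phys$intestinal_transit_h, 2.1)
  expect_equal(phys$protein_scaling, 1.0)
  systemic <- sum(phys$organs$flow_l_h[phys$organs$organ != "lung"])
  expect_equal(systemic, phys$cardiac_output, tolerance = 1e-9)
  expect_true(all(phys$organs$volume_l > 0))
})

test_that("organ volumes and flows scale linearly with body weight", {
  full <- build_reference_individual(70, "M", 30)
  half <- build_reference_individual(35, "M", 30)
  expect_equal(half$organs$volume_l, full$organs$volume_l / 2)
  expect_equal(half$organs$flow_l_h, full$organs$flow_l_h / 2)
  expect_equal(half$cardiac_output, full$cardiac_output / 2)
})

test_that("out-of-range inputs raise errors naming the field", {
  expect_error(build_reference_individual(20, "M", 30), "body_weight")
  expect_error(build_reference_individual(70, "M", 99), "age")
})

test_that("CKD stages overwrite the pathophysiological parameters", {
  phys <- build_reference_individual(70, "M", 30)
  mod <- apply_ckd(phys, "moderate")
  expect_equal(mod$egfr_ml_min, 48)
  expect_equal(mod$gastric_emptying_min, 20.63)
  expect_equal(mod$hematocrit, 0.42)
  expect_equal(mod$protein_scaling, 0.93)
  sev <- apply_ckd(phys, "severe")
  expect_equal(sev$hematocrit, 0.37)
  expect_equal(sev$intestinal_transit_h, 4.12)
  expect_equal(sev$egfr_ml_min, 29)
  # unbound fraction rises with reduced binding protein
  expect_gt(sev$fu_effective, phys$fu_effective)
  expect_equal(sev$fu_effective, adjust_fu(0.907, 0.83))
})

test_that("applying the healthy stage is the identity and stages are idempotent", {
  phys <- build_reference_individual(70, "M", 30)
  expect_equal(apply_ckd(phys, "healthy"), phys)
  sev1 <- apply_ckd(phys, "severe")
  expect_equal(apply_ckd(sev1, "severe"), sev1)
})

test_that("population sampling is deterministic given the seed and varies across seeds", {
  p1 <- sample_population(20, 0.48, c(18, 45), 58.6, 5.6, seed = 11)
  p2 <- sample_population(20, 0.48, c(18, 45), 58.6, 5.6, seed = 11)
  p3 <- sample_population(20, 0.48, c(18, 45), 58.6, 5.6, seed = 12)
  expect_equal(p1$body_weight, p2$body_weight)
  expect_equal(p1$phys[[7]]$organs, p2$phys[[7]]$organs)
  expect_false(identical(p1$body_weight, p3$body_weight))
})

test_that("sampled weights and sex match the requested demographics", {
  pop <- sample_population(1000, 0.48, c(18, 45), 58.6, 5.6, seed = 3)
  expect_equal(nrow(pop), 1000)
  # truncation at [30, 150] is ~4 SD away, so the sample mean tracks 58.6
  expect_lt(abs(mean(pop$body_weight) - 58.6), 3 * 5.6 / sqrt(1000))
  big <- sample_population(5000, 0.48, c(18, 45), 58.6, 0, seed = 4)
  se <- sqrt(0.48 * 0.52 / 5000)
  expect_lt(abs(mean(big$sex == "F") - 0.48), 2 * se)
})

test_that("degenerate sampling returns the exact reference individual", {
  pop <- sample_population(1, 0, c(30, 30), 70, 0, cv_organs = 0, seed = 1)
  ref <- build_reference_individual(70, "M", 30)
  expect_equal(pop$phys[[1]]$organs, ref$organs)
  expect_equal(pop$body_weight, 70)
})

test_that("flow conservation survives inter-individual variability", {
  pop <- sample_population(50, 0.5, c(18, 45), 70, 10, cv_organs = 0.15, seed = 5)
  for (ph in pop$phys) {
    systemic <- sum(ph$organs$flow_l_h[ph$organs$organ != "lung"])
    expect_equal(systemic, ph$cardiac_output, tolerance = 1e-9)
  }
  # variability is actually present
  vols <- purrr::map_dbl(pop$phys, ~ .x$organs$volume_l[.x$organs$organ == "liver"] /
                           .x$body_weight)
  expect_gt(stats::sd(vols) / mean(vols), 0.05)
})

test_that("population export drops the nested physiology objects", {
  pop <- sample_population(3, 0.5, c(18, 45), 70, 5, seed = 1)
  tab <- population_table(pop)
  expect_false("phys" %in% names(tab))
  expect_equal(nrow(tab), 3)
})
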