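test_that("fraction-unbound adjustment follows the binding-site dilution formula", {
  expect_equal(adjust_fu(0.907, 1.0), 0.907)
  # direct evaluation: 1 / (1 + 0.83 * (1/0.907 - 1))
  expect_equal(adjust_fu(0.907, 0.83), 0.9215700, tolerance = 1e-6)
  expect_equal(adjust_fu(0.4, 0), 1.0)
  expect_error(adjust_fu(0, 1), "fu_plasma")
})

test_that("adjust_fu is strictly decreasing in scaling and maps into (0, 1]", {
  scalings <- c(0.1, 0.5, 0.83, 0.93, 1, 1.5, 3)
  vals <- adjust_fu(0.907, scalings)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("Poulin-Theil coefficients reproduce an independent evaluation to 6 decimals", {
  # frozen from an independent numpy evaluation of the same composition table
  oracle <- c(lung = 0.951605, heart = 1.264104, brain = 3.005906,
              muscle = 1.573778, adipose = 1.946488, skin = 1.728210,
              bone = 2.872053, liver = 2.120258, kidney = 1.587879,
              gut = 2.455546, spleen = 1.610794, pancreas = 2.031375,
              rest = 1.573778)
  kp <- partition_coefficients(drug_parameters())
  expect_equal(kp[names(oracle)], oracle, tolerance = 5e-7)
})

test_that("a plasma-like tissue with no protein binding partitions 1:1", {
  comp <- tissue_composition()
  plasma_like <- comp[comp$organ == "plasma", ]
  comp[comp$organ != "adipose", c("f_water", "f_neutral_lipid", "f_phospholipid")] <-
    plasma_like[rep(1, sum(comp$organ != "adipose")),
                c("f_water", "f_neutral_lipid", "f_phospholipid")]
  kp <- partition_coefficients(drug_parameters(), comp = comp, fu = 1)
  expect_equal(unname(kp["muscle"]), 1, tolerance = 1e-12)
  expect_equal(unname(kp["liver"]), 1, tolerance = 1e-12)
})

test_that("lipid partitioning is monotone: fattier tissues and higher logP give larger Kp", {
  kp <- partition_coefficients(drug_parameters())
  expect_gt(kp[["adipose"]], kp[["muscle"]])
  kp_hi <- partition_coefficients(drug_parameters(logp = 1.55 + log10(2)))
  lipid_rich <- c("adipose", "brain", "liver", "muscle", "bone")
  expect_true(all(kp_hi[lipid_rich] > kp[lipid_rich]))
})

test_that("missing organ composition raises a configuration error", {
  comp <- tissue_composition()
  expect_error(
    partition_coefficients(drug_parameters(), comp = comp[comp$organ != "liver", ]),
    "liver"
  )
})

test_that("renal clearance reproduces 13 L/h for a healthy adult and scales with eGFR", {
  drug <- drug_parameters()
  healthy <- build_reference_individual(72.2, "M", 30)
  expect_equal(renal_clearance(drug, healthy), 13, tolerance = 0.001)
  sev <- apply_ckd(healthy, "severe")
  expect_equal(renal_clearance(drug, sev),
               renal_clearance(drug, healthy) * 29 / 110, tolerance = 1e-12)
  # linear and homogeneous in eGFR
  h2 <- healthy
  h2$egfr_ml_min <- 2 * healthy$egfr_ml_min
  expect_equal(renal_clearance(drug, h2), 2 * renal_clearance(drug, healthy))
})

test_that("Michaelis-Menten rate has the right limits", {
  drug <- drug_parameters()
  v <- 0.31
  expect_equal(metabolic_rate(0, drug, v), 0)
  vmax_umol_h <- drug$vmax_nmol_l_s * 1e-3 * 3600
  expect_equal(metabolic_rate(drug$km_umol_l, drug, v),
               0.5 * drug$metabolic_scaling * vmax_umol_h * v)
  # linear regime within 1% of the first-order approximation at C = 1 uM
  lin <- drug$metabolic_scaling * vmax_umol_h / drug$km_umol_l * v * 1
  expect_equal(metabolic_rate(1, drug, v), lin, tolerance = 0.01)
  expect_error(metabolic_rate(-1, drug, v), "non-negative")
})

test_that("drug parameters round-trip through YAML with Table-style values intact", {
  drug <- drug_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_drug_parameters(drug, path)
  back <- read_drug_parameters(path)
  expect_equal(back$km_umol_l, 190)
  expect_equal(back$logp, 1.55)
  expect_equal(back$logp_literature, 1.12)
  expect_equal(back$molecular_weight, 303.4)
  expect_equal(unclass(back)[order(names(back))],
               unclass(drug)[order(names(drug))])
})
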