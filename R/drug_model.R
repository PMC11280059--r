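# Vildagliptin drug-specific constants and derived quantities.

#' Vildagliptin drug parameters
#'
#' Returns the full vildagliptin parameter set used by the model:
#' physicochemical constants (molecular weight 303.4 g/mol, optimized logP
#' 1.55 with the literature value 1.12 retained as metadata, base pKa 9.7,
#' water solubility 60 mg/mL at pH 7), distribution (fraction unbound 0.907,
#' albumin binding), absorption (specific intestinal permeability 5e-4 cm/s,
#' Weibull dissolution with 50% dissolved at 50 min), metabolism
#' (Michaelis-Menten hydrolysis, Km 190 umol/L, Vmax 23.31 nmol/L/s, with a
#' dimensionless enzyme-abundance scaling calibrated once against the model's
#' intravenous clearance), and excretion (renal clearance 13 L/h for a
#' healthy adult, 0.18 L/h/kg). Any field can be overridden.
#'
#' @param ... Named overrides of default fields.
#' @return An object of class `drug_parameters` (a named list).
#' @examples
#' drug <- drug_parameters()
#' drug$km_umol_l
#' @export
drug_parameters <- function(...) {
  defaults <- list(
    name = "vildagliptin",
    molecular_weight = 303.4,          # g/mol
    logp = 1.55,                       # optimized lipophilicity used by the model
    logp_literature = 1.12,            # literature value retained as metadata
    pka_base = 9.7,
    water_solubility_mg_ml = 60,       # at pH 7
    fu_plasma = 0.907,
    binding_protein = "albumin",
    intestinal_permeability_cm_s = 5e-4,
    weibull_t50_min = 50,
    weibull_shape = 1,                 # exponential dissolution by default
    km_umol_l = 190,
    vmax_nmol_l_s = 23.31,
    renal_clearance_l_h = 13,          # healthy adult
    renal_clearance_l_h_kg = 0.18,
    metabolic_scaling = 399.9676,      # enzyme abundance; one-time calibration
                                       # against the predicted IV clearance
                                       # (see calibrate_metabolic_scaling)
    blood_plasma_ratio = 1,            # 1 - hct*(1 - Kery:p) with Kery:p = 1
    egfr_reference_ml_min = REFERENCE_EGFR_ML_MIN
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown drug parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  stopifnot(defaults$fu_plasma > 0, defaults$fu_plasma <= 1)
  structure(defaults, class = "drug_parameters")
}

#' Disease-adjusted fraction unbound
#'
#' Scales the plasma fraction unbound for a change in binding-protein
#' (albumin) concentration. With binding proportional to protein
#' concentration, `fu' = 1 / (1 + scaling * (1/fu - 1))`: a scaling below 1
#' (hypoalbuminemia, as in CKD) raises the unbound fraction.
#'
#' @param fu_plasma Baseline fraction unbound in (0, 1].
#' @param protein_scaling Relative binding-protein concentration (> 0 allowed
#'   to approach 0, where fu tends to 1).
#' @return Adjusted fraction unbound.
#' @examples
#' adjust_fu(0.907, 0.83)
#' @export
adjust_fu <- function(fu_plasma, protein_scaling) {
  if (any(fu_plasma <= 0) || any(fu_plasma > 1)) {
    stop("`fu_plasma` must lie in (0, 1]", call. = FALSE)
  }
  if (any(protein_scaling < 0)) {
    stop("`protein_scaling` must be non-negative", call. = FALSE)
  }
  1 / (1 + protein_scaling * (1 / fu_plasma - 1))
}

# Fractional tissue composition (wet-weight fractions of water, neutral
# lipid and phospholipid) for the model organs and plasma, from the standard
# published human composition table used with the Poulin-Theil partitioning
# method. The carcass "rest" compartment reuses muscle composition.
#' Tissue composition table
#'
#' Fractional water, neutral-lipid and phospholipid content per organ (plus
#' plasma) used to compute Poulin-Theil tissue:plasma partition coefficients.
#'
#' @return A tibble with columns `organ`, `f_water`, `f_neutral_lipid`,
#'   `f_phospholipid`.
#' @export
tissue_composition <- function() {
  tibble::tribble(
    ~organ,     ~f_water, ~f_neutral_lipid, ~f_phospholipid,
    "lung",     0.811,    0.0030,           0.0090,
    "heart",    0.758,    0.0115,           0.0166,
    "brain",    0.770,    0.0510,           0.0565,
    "muscle",   0.760,    0.0238,           0.0072,
    "adipose",  0.180,    0.7900,           0.0020,
    "skin",     0.718,    0.0284,           0.0111,
    "bone",     0.439,    0.0740,           0.0011,
    "liver",    0.751,    0.0348,           0.0252,
    "kidney",   0.783,    0.0207,           0.0162,
    "gut",      0.718,    0.0487,           0.0163,
    "spleen",   0.788,    0.0201,           0.0198,
    "pancreas", 0.641,    0.0403,           0.0093,
    "rest",     0.760,    0.0238,           0.0072,
    "plasma",   0.960,    0.00147,          0.00083
  )
}

#' Poulin-Theil tissue:plasma partition coefficients
#'
#' Computes the steady-state tissue:plasma partition coefficient for every
#' organ from tissue composition: the drug partitions into neutral lipid
#' (weighted by the octanol:water coefficient `10^logP`; the vegetable
#' oil:water coefficient `10^(1.115 logP - 1.35)` for adipose), into
#' phospholipid (treated as 30% lipid-like, 70% water-like), and into tissue
#' water, relative to the same terms in plasma, corrected by the unbound
#' fraction ratio. Non-adipose tissues assume interstitial binding proteins
#' at half their plasma concentration; adipose assumes no protein binding.
#'
#' @param drug A `drug_parameters` object.
#' @param comp Tissue-composition tibble (defaults to the embedded table).
#' @param fu Plasma fraction unbound (defaults to the drug's healthy value).
#' @return A named numeric vector of Kt:p, one entry per non-plasma organ.
#' @examples
#' kp <- partition_coefficients(drug_parameters())
#' kp["adipose"] > kp["muscle"]
#' @export
partition_coefficients <- function(drug, comp = tissue_composition(),
                                   fu = drug$fu_plasma) {
  needed <- reference_organ_table()$organ
  missing <- setdiff(c(needed, "plasma"), comp$organ)
  if (length(missing) > 0) {
    stop("tissue composition missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p_ow <- 10^drug$logp
  p_vow <- 10^(1.115 * drug$logp - 1.35)
  plasma <- comp[comp$organ == "plasma", ]
  lipid_term <- function(row, p) {
    p * (row$f_neutral_lipid + 0.3 * row$f_phospholipid) +
      (row$f_water + 0.7 * row$f_phospholipid)
  }
  fu_t_nonadipose <- 1 / (1 + 0.5 * (1 / fu - 1))
  kp <- vapply(needed, function(org) {
    row <- comp[comp$organ == org, ]
    if (org == "adipose") {
      lipid_term(row, p_vow) / lipid_term(plasma, p_vow) * fu / 1
    } else {
      lipid_term(row, p_ow) / lipid_term(plasma, p_ow) * fu / fu_t_nonadipose
    }
  }, numeric(1))
  stopifnot(all(kp > 0))
  kp
}

#' Renal plasma clearance scaled by body size and kidney function
#'
#' `CL_R = CL_per_kg * body_weight * (eGFR / eGFR_reference)`. For a healthy
#' 72.2 kg adult this reproduces the drug's 13 L/h; in CKD it declines in
#' proportion to the glomerular filtration rate.
#'
#' @param drug A `drug_parameters` object.
#' @param phys A `physiology` object with positive `egfr_ml_min`.
#' @return Renal plasma clearance in L/h.
#' @examples
#' renal_clearance(drug_parameters(), build_reference_individual(72.2, "M", 30))
#' @export
renal_clearance <- function(drug, phys) {
  stopifnot(phys$egfr_ml_min > 0)
  drug$renal_clearance_l_h_kg * phys$body_weight *
    (phys$egfr_ml_min / drug$egfr_reference_ml_min)
}

#' Michaelis-Menten metabolic rate
#'
#' Saturable hydrolysis rate at a given unbound concentration:
#' `rate = scaling * Vmax * C / (Km + C) * volume`, returned in umol/h. At
#' concentrations well below Km (190 umol/L; clinical vildagliptin exposures
#' are ~100-fold lower) the rate is linear in concentration with intrinsic
#' clearance `scaling * Vmax / Km * volume`.
#'
#' @param conc_unbound_umol_l Unbound concentration, umol/L (>= 0).
#' @param drug A `drug_parameters` object.
#' @param volume_l Volume of the metabolizing compartment, L.
#' @return Rate in umol/h.
#' @export
metabolic_rate <- function(conc_unbound_umol_l, drug, volume_l) {
  if (any(conc_unbound_umol_l < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  vmax_umol_l_h <- drug$vmax_nmol_l_s * 1e-3 * 3600
  drug$metabolic_scaling * vmax_umol_l_h * conc_unbound_umol_l /
    (drug$km_umol_l + conc_unbound_umol_l) * volume_l
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s (MW %.1f, logP %.2f, fu %.3f)\n",
              x$name, x$molecular_weight, x$logp, x$fu_plasma))
  cat(sprintf("  Km %.0f uM, Vmax %.2f nmol/L/s (scaling %.1f), CL_R %.1f L/h\n",
              x$km_umol_l, x$vmax_nmol_l_s, x$metabolic_scaling,
              x$renal_clearance_l_h))
  invisible(x)
}

#' Read or write drug parameters as YAML
#'
#' @param path File path.
#' @param drug A `drug_parameters` object.
#' @return `read_drug_parameters()` returns a `drug_parameters` object.
#' @export
write_drug_parameters <- function(drug, path) {
  yaml::write_yaml(unclass(drug), path)
  invisible(path)
}

#' @rdname write_drug_parameters
#' @export
read_drug_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(drug_parameters, vals[setdiff(names(vals), "name")])
}
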