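# Virtual individuals: reference anatomy, CKD staging, population sampling.

# Reference anatomy for a 70 kg adult at rest. Organ volumes in L; regional
# blood flows as fractions of cardiac output. The fractions are rounded
# ICRP-style resting values; "rest" closes the flow balance to exactly 1 and
# absorbs unassigned carcass mass. Gut, spleen and pancreas drain into the
# portal vein; the liver fraction below is the hepatic artery only.
REFERENCE_BODY_WEIGHT_KG <- 70
REFERENCE_CARDIAC_OUTPUT_L_H <- 390
REFERENCE_EGFR_ML_MIN <- 110  # healthy adult reference glomerular filtration

reference_organ_table <- function() {
  tibble::tribble(
    ~organ,     ~volume_l, ~flow_fraction,
    "lung",     0.50,      NA,     # receives full cardiac output in series
    "heart",    0.33,      0.040,
    "brain",    1.45,      0.120,
    "muscle",   29.0,      0.170,
    "adipose",  13.0,      0.050,
    "skin",     3.30,      0.050,
    "bone",     10.0,      0.050,
    "kidney",   0.31,      0.190,
    "gut",      1.20,      0.150,
    "spleen",   0.18,      0.030,
    "pancreas", 0.14,      0.010,
    "liver",    1.80,      0.065,
    "rest",     3.20,      0.075
  )
}

PORTAL_ORGANS <- c("gut", "spleen", "pancreas")
SYSTEMIC_ORGANS <- setdiff(reference_organ_table()$organ, "lung")

#' Chronic kidney disease stage parameter sets
#'
#' Returns the pathophysiological parameter set for one CKD stage: estimated
#' glomerular filtration rate (eGFR), gastric emptying time, small-intestinal
#' transit time, hematocrit, and the plasma binding-protein scaling factor
#' applied to albumin concentration. The healthy stage is the reference
#' (scaling 1); moderate and severe stages carry the reduced eGFR, slowed
#' gastrointestinal transit, anemia and hypoalbuminemia characteristic of
#' renal impairment.
#'
#' @param label One of `"healthy"`, `"moderate"`, `"severe"`.
#' @return A one-row tibble with columns `label`, `egfr_ml_min`,
#'   `gastric_emptying_min`, `intestinal_transit_h`, `hematocrit`,
#'   `protein_scaling`.
#' @examples
#' ckd_stage("severe")
#' @export
ckd_stage <- function(label = c("healthy", "moderate", "severe")) {
  label <- match.arg(label)
  stages <- tibble::tribble(
    ~label,     ~egfr_ml_min, ~gastric_emptying_min, ~intestinal_transit_h, ~hematocrit, ~protein_scaling,
    "healthy",  REFERENCE_EGFR_ML_MIN, 15,    2.10, 0.47, 1.00,
    "moderate", 48,           20.63, 2.94, 0.42, 0.93,
    "severe",   29,           39.00, 4.12, 0.37, 0.83
  )
  stages[stages$label == label, ]
}

#' Build a reference virtual individual
#'
#' Constructs a complete physiology for one healthy adult: organ volumes and
#' regional blood flows scaled linearly with body weight from an embedded
#' 70 kg reference table, cardiac output, blood volumes, hematocrit, eGFR,
#' gastrointestinal transit times, and the effective unbound fraction of the
#' drug in plasma (here the healthy value, since the binding-protein scaling
#' is 1).
#'
#' @param body_weight Body weight in kg (30-150).
#' @param sex `"M"` or `"F"`.
#' @param age Age in years (18-85).
#' @param fu_plasma Healthy fraction unbound in plasma used to derive the
#'   individual's effective unbound fraction.
#' @return An object of class `physiology`.
#' @examples
#' phys <- build_reference_individual(70, "M", 30)
#' phys$hematocrit
#' @export
build_reference_individual <- function(body_weight, sex = c("M", "F"), age = 30,
                                       fu_plasma = 0.907) {
  sex <- match.arg(sex)
  if (!is.numeric(body_weight) || length(body_weight) != 1 ||
      body_weight < 30 || body_weight > 150) {
    stop("`body_weight` must be a single value in [30, 150] kg", call. = FALSE)
  }
  if (!is.numeric(age) || length(age) != 1 || age < 18 || age > 85) {
    stop("`age` must be a single value in [18, 85] years", call. = FALSE)
  }
  scale <- body_weight / REFERENCE_BODY_WEIGHT_KG
  co <- REFERENCE_CARDIAC_OUTPUT_L_H * scale
  organs <- reference_organ_table()
  organs <- dplyr::mutate(
    organs,
    volume_l = .data$volume_l * scale,
    flow_l_h = dplyr::if_else(.data$organ == "lung", co, .data$flow_fraction * co)
  )
  organs$flow_fraction <- NULL
  stage <- ckd_stage("healthy")
  phys <- structure(list(
    body_weight = body_weight,
    sex = sex,
    age = age,
    organs = organs,
    cardiac_output = co,
    venous_volume_l = 3.9 * scale,
    arterial_volume_l = 1.7 * scale,
    hematocrit = stage$hematocrit,
    egfr_ml_min = stage$egfr_ml_min,
    gastric_emptying_min = stage$gastric_emptying_min,
    intestinal_transit_h = stage$intestinal_transit_h,
    protein_scaling = stage$protein_scaling,
    fu_plasma = fu_plasma,
    fu_effective = adjust_fu(fu_plasma, stage$protein_scaling),
    stage = "healthy"
  ), class = "physiology")
  validate_physiology(phys)
  phys
}

validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology"))
  org <- phys$organs
  if (any(org$volume_l <= 0) || any(org$flow_l_h <= 0)) {
    stop("all organ volumes and flows must be strictly positive", call. = FALSE)
  }
  systemic <- sum(org$flow_l_h[org$organ != "lung"])
  if (abs(systemic - phys$cardiac_output) > 1e-6 * phys$cardiac_output) {
    stop("systemic organ blood flows must sum to cardiac output", call. = FALSE)
  }
  if (phys$hematocrit <= 0 || phys$hematocrit >= 1) {
    stop("hematocrit must lie in (0, 1)", call. = FALSE)
  }
  if (phys$fu_effective <= 0 || phys$fu_effective > 1) {
    stop("fu_effective must lie in (0, 1]", call. = FALSE)
  }
  invisible(phys)
}

#' Apply a CKD stage to an individual
#'
#' Overwrites the disease-dependent system parameters (eGFR, gastric emptying
#' time, intestinal transit time, hematocrit, plasma-protein scaling) with the
#' stage values and recomputes the effective unbound fraction via
#' [adjust_fu()]. Applying the healthy stage returns the individual unchanged;
#' the operation is idempotent per stage.
#'
#' @param phys A `physiology` object.
#' @param stage A stage label or a one-row tibble from [ckd_stage()].
#' @return A modified copy of `phys`.
#' @examples
#' phys <- build_reference_individual(63.7, "F", 60)
#' apply_ckd(phys, "severe")$egfr_ml_min
#' @export
apply_ckd <- function(phys, stage) {
  validate_physiology(phys)
  if (is.character(stage)) stage <- ckd_stage(stage)
  phys$egfr_ml_min <- stage$egfr_ml_min
  phys$gastric_emptying_min <- stage$gastric_emptying_min
  phys$intestinal_transit_h <- stage$intestinal_transit_h
  phys$hematocrit <- stage$hematocrit
  phys$protein_scaling <- stage$protein_scaling
  phys$fu_effective <- adjust_fu(phys$fu_plasma, stage$protein_scaling)
  phys$stage <- stage$label
  validate_physiology(phys)
  phys
}

#' Sample a virtual population
#'
#' Draws `n` virtual individuals: body weights from a normal distribution
#' truncated to [30, 150] kg, ages uniform over `age_range`, sex Bernoulli
#' with `female_fraction`, and independent log-normal inter-individual
#' variability (coefficient of variation `cv_organs`) on every organ volume
#' and blood flow. Perturbed flows are renormalized so that systemic flows
#' still sum to the individual's cardiac output. The requested CKD stage is
#' applied to every individual. Fully deterministic given `seed`.
#'
#' @param n Number of individuals.
#' @param female_fraction Probability that an individual is female.
#' @param age_range Length-2 numeric, years.
#' @param weight_mean,weight_sd Body-weight distribution, kg.
#' @param stage CKD stage label or tibble (default healthy).
#' @param cv_organs Log-normal CV applied to organ volumes and flows.
#' @param seed Integer seed.
#' @param fu_plasma Healthy plasma fraction unbound.
#' @return A tibble of class `pbpk_population` with one row per individual:
#'   `subject_id`, `body_weight`, `age`, `sex`, `stage`, `fu_effective`, and a
#'   list-column `phys` holding the full `physiology` objects.
#' @examples
#' pop <- sample_population(5, 0.45, c(18, 45), 68.1, 7.1, seed = 1)
#' pop$body_weight
#' @export
sample_population <- function(n, female_fraction = 0.5, age_range = c(18, 45),
                              weight_mean = 70, weight_sd = 10,
                              stage = "healthy", cv_organs = 0.15, seed = 1,
                              fu_plasma = 0.907) {
  stopifnot(n >= 1, weight_sd >= 0, female_fraction >= 0, female_fraction <= 1)
  if (is.character(stage)) stage <- ckd_stage(stage)
  rng <- local_rng(seed)
  weights <- rtruncnorm(n, weight_mean, weight_sd, 30, 150, rng)
  ages <- rng$runif(n, age_range[1], age_range[2])
  sexes <- ifelse(rng$runif(n) < female_fraction, "F", "M")
  sdlog <- sqrt(log(1 + cv_organs^2))
  phys_list <- purrr::pmap(list(weights, sexes, ages), function(w, s, a) {
    phys <- build_reference_individual(w, s, a, fu_plasma = fu_plasma)
    if (cv_organs > 0) {
      k <- nrow(phys$organs)
      vol_mult <- exp(rng$rnorm(k, -sdlog^2 / 2, sdlog))
      flow_mult <- exp(rng$rnorm(k, -sdlog^2 / 2, sdlog))
      phys$organs$volume_l <- phys$organs$volume_l * vol_mult
      phys$organs$flow_l_h <- phys$organs$flow_l_h * flow_mult
      sys <- phys$organs$organ != "lung"
      phys$organs$flow_l_h[sys] <- phys$organs$flow_l_h[sys] *
        phys$cardiac_output / sum(phys$organs$flow_l_h[sys])
      phys$organs$flow_l_h[!sys] <- phys$cardiac_output
    }
    apply_ckd(phys, stage)
  })
  structure(tibble::tibble(
    subject_id = seq_len(n),
    body_weight = weights,
    age = ages,
    sex = sexes,
    stage = stage$label,
    fu_effective = purrr::map_dbl(phys_list, "fu_effective"),
    phys = phys_list
  ), class = c("pbpk_population", class(tibble::tibble())))
}

# Self-contained RNG so population sampling never disturbs (or depends on)
# the global random stream beyond the supplied seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm))
}

rtruncnorm <- function(n, mean, sd, lo, hi, rng) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rng$rnorm(2 * (n - length(out)), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %.1f kg, %.0f y, stage %s\n",
              x$sex, x$body_weight, x$age, x$stage))
  cat(sprintf("  cardiac output %.0f L/h, eGFR %.0f mL/min, hematocrit %.2f, fu %.3f\n",
              x$cardiac_output, x$egfr_ml_min, x$hematocrit, x$fu_effective))
  invisible(x)
}

#' Export a population as a flat table
#'
#' One row per individual with scalar demographic and disease fields
#' (drops the nested physiology objects); suitable for CSV export.
#'
#' @param population A `pbpk_population` tibble.
#' @return A tibble without the `phys` list-column.
#' @export
population_table <- function(population) {
  dplyr::select(tibble::as_tibble(population), -dplyr::any_of("phys"))
}
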