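# CKD dose adjustment: match CKD drug exposure to the healthy reference.

#' Unbound exposure
#'
#' @param auc_total Total AUC (ng.h/mL).
#' @param fu_effective Effective plasma fraction unbound.
#' @return Unbound AUC, the product of the two.
#' @export
unbound_auc <- function(auc_total, fu_effective) {
  stopifnot(all(auc_total >= 0), all(fu_effective > 0), all(fu_effective <= 1))
  auc_total * fu_effective
}

#' Population exposure at one dose
#'
#' Simulates a population at a dose and returns per-subject total and unbound
#' AUC0-inf with a summary.
#'
#' @param population A `pbpk_population`.
#' @param drug A `drug_parameters`.
#' @param dose_mg Oral dose.
#' @param config A `pbpk_config`.
#' @param label Population label carried through to summaries.
#' @return An object of class `exposure_comparison`: tibble with
#'   `subject_id`, `auc_total`, `auc_unbound` plus attributes `label`,
#'   `dose_mg`.
#' @export
population_exposure <- function(population, drug, dose_mg,
                                config = pbpk_config(), label = "population") {
  sims <- pbpk_simulate_population(population, drug,
                                   dose_regimen("oral", dose_mg), config)
  nca <- nca_population(sims)
  fu <- attr(sims, "fu_effective")[as.character(nca$subject_id)]
  out <- tibble::tibble(
    subject_id = nca$subject_id,
    auc_total = nca$auc_inf_ng_h_ml,
    auc_unbound = unbound_auc(nca$auc_inf_ng_h_ml, fu)
  )
  structure(out, class = c("exposure_comparison", class(tibble::tibble())),
            label = label, dose_mg = dose_mg)
}

#' Find the CKD dose matching healthy exposure
#'
#' Bisection search on dose for the CKD population mean AUC0-inf (total or
#' unbound) to match a healthy reference exposure within a relative
#' tolerance. Valid because vildagliptin kinetics are linear at clinical
#' concentrations (well below Km), so exposure is monotone in dose. If CKD
#' exposure at the full initial dose is already below the healthy reference
#' the search cannot bracket and the initial dose is returned with a warning.
#'
#' @param ckd_population A `pbpk_population` with a CKD stage applied.
#' @param drug A `drug_parameters`.
#' @param healthy_reference_exposure Healthy mean AUC0-inf (ng.h/mL), on the
#'   same metric as `metric`.
#' @param initial_dose_mg Starting (full) dose, mg.
#' @param metric `"total"` or `"unbound"`.
#' @param tolerance Relative tolerance on the mean-AUC match (default 5%).
#' @param config A `pbpk_config`.
#' @param max_iter Bisection iteration cap.
#' @return A one-row tibble: `dose_mg`, `percent_of_initial`, `mean_auc`,
#'   `reference_auc`, `metric`, `converged`, `iterations`.
#' @export
find_equivalent_dose <- function(ckd_population, drug,
                                 healthy_reference_exposure,
                                 initial_dose_mg = 50,
                                 metric = c("total", "unbound"),
                                 tolerance = 0.05,
                                 config = pbpk_config(),
                                 max_iter = 12) {
  metric <- match.arg(metric)
  stopifnot(initial_dose_mg > 0, tolerance > 0, tolerance <= 0.2)
  col <- if (metric == "total") "auc_total" else "auc_unbound"
  mean_auc_at <- function(d) {
    exp <- population_exposure(ckd_population, drug, d, config)
    mean(exp[[col]], na.rm = TRUE)
  }
  ref <- healthy_reference_exposure
  full <- mean_auc_at(initial_dose_mg)
  if (full < ref * (1 - tolerance)) {
    warning("CKD exposure at the initial dose is below the healthy reference; ",
            "returning the initial dose", call. = FALSE)
    return(tibble::tibble(dose_mg = initial_dose_mg, percent_of_initial = 100,
                          mean_auc = full, reference_auc = ref,
                          metric = metric, converged = FALSE, iterations = 0L))
  }
  lo <- 0
  hi <- initial_dose_mg
  mid <- initial_dose_mg
  auc_mid <- full
  converged <- abs(full - ref) / ref <= tolerance
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    auc_mid <- mean_auc_at(mid)
    if (abs(auc_mid - ref) / ref <= tolerance) {
      converged <- TRUE
    } else if (auc_mid > ref) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  tibble::tibble(dose_mg = mid, percent_of_initial = 100 * mid / initial_dose_mg,
                 mean_auc = auc_mid, reference_auc = ref, metric = metric,
                 converged = converged, iterations = it)
}

#' Box-plot summary of exposure distributions
#'
#' Median, quartiles and 5-95th percentile whiskers of total and unbound AUC
#' per group, ready for plotting.
#'
#' @param comparisons A list of `exposure_comparison` objects.
#' @return A tibble with one row per group and metric: `label`, `dose_mg`,
#'   `metric`, `p5`, `q1`, `median`, `q3`, `p95`, `mean`, `n`.
#' @export
exposure_boxplot_table <- function(comparisons) {
  if (inherits(comparisons, "exposure_comparison")) {
    comparisons <- list(comparisons)
  }
  purrr::map_dfr(comparisons, function(cmp) {
    if (nrow(cmp) == 0) stop("empty exposure group", call. = FALSE)
    tibble::as_tibble(cmp) |>
      tidyr::pivot_longer(c("auc_total", "auc_unbound"), names_to = "metric") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(
        p5 = stats::quantile(.data$value, 0.05, na.rm = TRUE, names = FALSE),
        q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
        median = stats::median(.data$value, na.rm = TRUE),
        q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
        p95 = stats::quantile(.data$value, 0.95, na.rm = TRUE, names = FALSE),
        mean = mean(.data$value, na.rm = TRUE),
        n = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(label = attr(cmp, "label"), dose_mg = attr(cmp, "dose_mg"),
                    .before = 1)
  })
}
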