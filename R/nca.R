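# Non-compartmental analysis of concentration-time profiles.

#' Non-compartmental analysis of one profile
#'
#' Computes the standard single-dose NCA parameters: Cmax and Tmax from the
#' observed maximum, AUC to the last positive concentration by the linear
#' trapezoid rule, the terminal slope lambda-z by log-linear regression over
#' the best (adjusted R-squared) set of the last 3-6 post-Tmax points,
#' AUC0-inf = AUC_last + C_last / lambda_z, half-life ln2/lambda_z, and
#' apparent clearance CL/F = dose / AUC0-inf (mg and ng/mL converted to L/h).
#' Profiles whose extrapolated AUC fraction exceeds 20% are flagged.
#'
#' @param profile A `pbpk_profile`, or a data frame with columns `time_h` and
#'   `conc_ng_ml` (at least 4 points).
#' @param dose_mg Dose; defaults to the profile's dose.
#' @return A one-row tibble: `cmax_ng_ml`, `tmax_h`, `auc_last_ng_h_ml`,
#'   `auc_inf_ng_h_ml`, `lambda_z_per_h`, `t_half_h`, `cl_over_f_l_h`,
#'   `extrapolated_fraction`, `flag` (NA when clean; otherwise a short
#'   message, e.g. terminal-fit failure or > 20% extrapolation).
#' @examples
#' tt <- seq(0, 24, 0.25)
#' prof <- tibble::tibble(time_h = tt, conc_ng_ml = 100 * exp(-0.2 * tt))
#' compute_nca(prof, dose_mg = 1)
#' @export
compute_nca <- function(profile, dose_mg = NULL) {
  if (inherits(profile, "pbpk_profile")) {
    if (is.null(dose_mg)) dose_mg <- profile$dose_mg
    profile <- profile$data
  }
  stopifnot(all(c("time_h", "conc_ng_ml") %in% names(profile)))
  if (is.null(dose_mg)) stop("`dose_mg` is required", call. = FALSE)
  df <- dplyr::arrange(tibble::as_tibble(profile), .data$time_h)
  if (nrow(df) < 4) stop("NCA needs at least 4 time points", call. = FALSE)
  t <- df$time_h
  c <- df$conc_ng_ml

  cmax <- max(c)
  tmax <- t[which.max(c)]

  # AUC_last: linear trapezoid to the last positive concentration
  pos <- which(c > 0)
  flag <- NA_character_
  if (length(pos) == 0) {
    return(tibble::tibble(cmax_ng_ml = 0, tmax_h = tmax,
                          auc_last_ng_h_ml = 0, auc_inf_ng_h_ml = 0,
                          lambda_z_per_h = NA_real_, t_half_h = NA_real_,
                          cl_over_f_l_h = NA_real_,
                          extrapolated_fraction = NA_real_,
                          flag = "all-zero profile"))
  }
  last <- max(pos)
  auc_last <- sum(diff(t[1:last]) * (utils::head(c[1:last], -1) +
                                       utils::tail(c[1:last], -1)) / 2)

  # lambda_z: best adjusted-R2 log-linear fit over the last 3-6 points after
  # Tmax with positive concentrations
  term <- which(t > tmax & c > 0)
  lambda_z <- NA_real_
  if (length(term) >= 3) {
    best_r2 <- -Inf
    for (k in 3:min(6, length(term))) {
      ix <- utils::tail(term, k)
      fit <- stats::lm(log(c[ix]) ~ t[ix])
      slope <- -stats::coef(fit)[[2]]
      r2 <- suppressWarnings(summary(fit)$adj.r.squared)
      if (is.finite(r2) && r2 > best_r2 && slope > 0) {
        best_r2 <- r2
        lambda_z <- slope
      }
    }
  }
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    lambda_z <- NA_real_
    flag <- "terminal slope estimation failed"
  }

  auc_inf <- if (is.na(lambda_z)) NA_real_ else auc_last + c[last] / lambda_z
  extrap <- if (is.na(auc_inf)) NA_real_ else 1 - auc_last / auc_inf
  if (!is.na(extrap) && extrap > 0.2) flag <- "extrapolated fraction > 20%"
  cl_f <- if (is.na(auc_inf) || auc_inf <= 0) NA_real_ else
    dose_mg * 1e6 / auc_inf / 1000  # ng / (ng.h/mL) -> mL/h -> L/h

  tibble::tibble(
    cmax_ng_ml = cmax, tmax_h = tmax,
    auc_last_ng_h_ml = auc_last, auc_inf_ng_h_ml = auc_inf,
    lambda_z_per_h = lambda_z,
    t_half_h = ifelse(is.na(lambda_z), NA_real_, log(2) / lambda_z),
    cl_over_f_l_h = cl_f,
    extrapolated_fraction = extrap,
    flag = flag
  )
}

#' NCA for every subject of a simulated population
#'
#' @param profile_set A `pbpk_profile_set`.
#' @param dose_mg Dose per subject; defaults to the set's dose attribute.
#' @return A tibble with one NCA row per subject (column `subject_id` first).
#' @export
nca_population <- function(profile_set, dose_mg = attr(profile_set, "dose_mg")) {
  stopifnot(inherits(profile_set, "pbpk_profile_set"))
  profile_set |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ compute_nca(.x, dose_mg = dose_mg)) |>
    dplyr::ungroup()
}

#' Summarize population PK parameters
#'
#' Arithmetic mean, SD, 5th/95th percentiles, minimum and maximum for each
#' numeric NCA parameter across subjects.
#'
#' @param nca_table A tibble of per-subject NCA rows (from [nca_population()]
#'   or [compute_nca()] rows bound together).
#' @return A tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `p5`, `p95`, `min`, `max`, `n`.
#' @export
summarize_population_pk <- function(nca_table) {
  if (nrow(nca_table) < 1) stop("empty PK parameter table", call. = FALSE)
  num <- dplyr::select(nca_table, dplyr::where(is.numeric),
                       -dplyr::any_of("subject_id"))
  tidyr::pivot_longer(num, dplyr::everything(), names_to = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      p5 = stats::quantile(.data$value, 0.05, na.rm = TRUE, names = FALSE),
      p95 = stats::quantile(.data$value, 0.95, na.rm = TRUE, names = FALSE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}
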