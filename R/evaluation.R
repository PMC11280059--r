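# Model-qualification statistics: predicted/observed ratios, average fold
# error, visual predictive checks, two-fold acceptance.

#' Predicted/observed ratio
#'
#' The ratio `R = predicted / observed` of a PK parameter; the fold error is
#' defined by the same quotient, so [fold_error()] is an alias.
#'
#' @param predicted,observed Numeric vectors; `observed` must be positive.
#' @return `predicted / observed`.
#' @examples
#' r_ratio(127, 140)
#' @export
r_ratio <- function(predicted, observed) {
  if (any(observed <= 0)) stop("`observed` must be positive", call. = FALSE)
  predicted / observed
}

#' @rdname r_ratio
#' @export
fold_error <- r_ratio

#' Average fold error
#'
#' `AFE = 10^(mean(log10 FE))`. Under the default magnitude convention the
#' absolute value of the mean log fold error is used, so AFE >= 1 and
#' systematic under- and over-prediction are penalized alike; the signed
#' convention keeps the direction (and equals the geometric mean of the fold
#' errors).
#'
#' @param fold_errors Positive fold errors (predicted/observed).
#' @param convention `"magnitude"` (default) or `"signed"`.
#' @return The average fold error.
#' @examples
#' afe(c(2, 0.5))
#' @export
afe <- function(fold_errors, convention = c("magnitude", "signed")) {
  convention <- match.arg(convention)
  if (length(fold_errors) == 0) stop("empty fold-error list", call. = FALSE)
  if (any(fold_errors <= 0)) stop("fold errors must be positive", call. = FALSE)
  m <- mean(log10(fold_errors))
  if (convention == "magnitude") 10^abs(m) else 10^m
}

#' Mean predicted/observed ratio with 95% confidence interval
#'
#' Arithmetic mean of the ratios with a t-distribution confidence interval on
#' the untransformed values. With a single ratio the CI is undefined and
#' flagged via `NA` bounds.
#'
#' @param ratios Numeric vector of R ratios.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `mean`, `ci_lower`, `ci_upper`, `n`.
#' @export
mean_r_ratio <- function(ratios, conf_level = 0.95) {
  if (length(ratios) == 0) stop("empty ratio list", call. = FALSE)
  n <- length(ratios)
  m <- mean(ratios)
  if (n == 1) {
    return(tibble::tibble(mean = m, ci_lower = NA_real_, ci_upper = NA_real_,
                          n = n))
  }
  se <- stats::sd(ratios) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  tibble::tibble(mean = m, ci_lower = m - tq * se, ci_upper = m + tq * se, n = n)
}

#' Two-fold acceptance flag
#'
#' @param ratios Numeric R ratios.
#' @return Logical: `TRUE` when `0.5 <= R <= 2`.
#' @export
two_fold_pass <- function(ratios) {
  ratios >= 0.5 & ratios <= 2.0
}

#' Evaluate predicted against observed PK parameters
#'
#' Per-profile predicted/observed ratios with two-fold acceptance flags, and
#' per-parameter summaries (AFE under both conventions, mean ratio with 95%
#' CI). Rows with non-positive observed values are flagged and excluded from
#' the summaries rather than aborting the run.
#'
#' @param pk_table A data frame with columns `parameter`, `observed`,
#'   `predicted`, plus any identifier columns (kept).
#' @return An object of class `pk_evaluation`: list with `per_profile` and
#'   `per_parameter` tibbles.
#' @examples
#' tbl <- tibble::tibble(parameter = "auc", observed = c(500, 600),
#'                       predicted = c(450, 700))
#' evaluate_pk(tbl)$per_parameter
#' @export
evaluate_pk <- function(pk_table) {
  stopifnot(all(c("parameter", "observed", "predicted") %in% names(pk_table)))
  per <- tibble::as_tibble(pk_table) |>
    dplyr::mutate(
      valid = .data$observed > 0 & is.finite(.data$predicted) &
        .data$predicted > 0,
      r_ratio = dplyr::if_else(.data$valid,
                               .data$predicted / .data$observed, NA_real_),
      fold_error = .data$r_ratio,
      two_fold_pass = dplyr::if_else(.data$valid, two_fold_pass(.data$r_ratio),
                                     NA)
    )
  summ <- per |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      afe_magnitude = afe(.data$fold_error, "magnitude"),
      afe_signed = afe(.data$fold_error, "signed"),
      mean_r = mean(.data$r_ratio),
      r_ci_lower = mean_r_ratio(.data$r_ratio)$ci_lower,
      r_ci_upper = mean_r_ratio(.data$r_ratio)$ci_upper,
      fraction_two_fold = mean(.data$two_fold_pass),
      .groups = "drop"
    )
  structure(list(per_profile = per, per_parameter = summ),
            class = "pk_evaluation")
}

#' @export
print.pk_evaluation <- function(x, ...) {
  cat("<pk_evaluation>\n")
  print(x$per_parameter)
  invisible(x)
}

#' Visual predictive check
#'
#' Per-time 5th/95th percentiles, arithmetic mean, minimum and maximum of the
#' simulated concentrations, with the observed profile overlaid and the
#' fraction of observed points inside the 5-95% band reported. Simulated
#' profiles are linearly interpolated onto their common grid if needed.
#'
#' @param observed A data frame with `time_h`, `conc_ng_ml` (one profile).
#' @param simulated A `pbpk_profile_set` (or tidy tibble with `subject_id`,
#'   `time_h`, `conc_ng_ml`).
#' @return An object of class `pbpk_vpc`: list with `bands` (tibble `time_h`,
#'   `p5`, `mean`, `p95`, `min`, `max`), `observed`, and
#'   `fraction_within_band`.
#' @export
vpc <- function(observed, simulated) {
  if (inherits(observed, "pbpk_profile")) observed <- observed$data
  if (nrow(simulated) == 0) stop("empty simulation set", call. = FALSE)
  bands <- simulated |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      p5 = stats::quantile(.data$conc_ng_ml, 0.05, names = FALSE),
      mean = mean(.data$conc_ng_ml),
      p95 = stats::quantile(.data$conc_ng_ml, 0.95, names = FALSE),
      min = min(.data$conc_ng_ml),
      max = max(.data$conc_ng_ml),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time_h)
  lo <- stats::approx(bands$time_h, bands$p5, xout = observed$time_h,
                      rule = 2)$y
  hi <- stats::approx(bands$time_h, bands$p95, xout = observed$time_h,
                      rule = 2)$y
  inside <- observed$conc_ng_ml >= lo & observed$conc_ng_ml <= hi
  structure(list(bands = bands, observed = tibble::as_tibble(observed),
                 fraction_within_band = mean(inside)),
            class = "pbpk_vpc")
}

#' @export
print.pbpk_vpc <- function(x, ...) {
  cat(sprintf("<pbpk_vpc> %d band times, %.0f%% of observed points inside 5-95%% band\n",
              nrow(x$bands), 100 * x$fraction_within_band))
  invisible(x)
}
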