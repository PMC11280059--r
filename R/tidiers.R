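# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulated profile
#'
#' @param x A `pbpk_profile`.
#' @param ... Unused.
#' @return The concentration-time tibble (`time_h`, `conc_ng_ml`).
#' @export
tidy.pbpk_profile <- function(x, ...) x$data

#' @rdname tidy.pbpk_profile
#' @export
glance.pbpk_profile <- function(x, ...) {
  bal <- if (!is.null(x$ledger)) max(abs(x$ledger$balance_error)) else NA_real_
  tibble::tibble(dose_mg = x$dose_mg,
                 cmax_ng_ml = max(x$data$conc_ng_ml),
                 tmax_h = x$data$time_h[which.max(x$data$conc_ng_ml)],
                 n_times = nrow(x$data),
                 max_balance_error_mg = bal)
}

#' Tidy an evaluation report
#'
#' @param x A `pk_evaluation`.
#' @param ... Unused.
#' @return `tidy()`: the per-profile ratio table. `glance()`: a one-row
#'   overall summary.
#' @export
tidy.pk_evaluation <- function(x, ...) x$per_profile

#' @rdname tidy.pk_evaluation
#' @export
glance.pk_evaluation <- function(x, ...) {
  valid <- dplyr::filter(x$per_profile, .data$valid)
  tibble::tibble(
    n_profiles = nrow(x$per_profile),
    n_valid = nrow(valid),
    fraction_two_fold = mean(valid$two_fold_pass),
    afe_magnitude_overall = afe(valid$fold_error, "magnitude"),
    mean_r_overall = mean(valid$r_ratio)
  )
}

#' Tidy a visual predictive check
#'
#' @param x A `pbpk_vpc`.
#' @param ... Unused.
#' @return `tidy()`: the percentile-band tibble. `glance()`: one row with the
#'   observed-coverage fraction.
#' @export
tidy.pbpk_vpc <- function(x, ...) x$bands

#' @rdname tidy.pbpk_vpc
#' @export
glance.pbpk_vpc <- function(x, ...) {
  tibble::tibble(n_times = nrow(x$bands),
                 n_observed = nrow(x$observed),
                 fraction_within_band = x$fraction_within_band)
}
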