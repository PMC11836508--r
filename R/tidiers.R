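# broom-style tidiers for the fitted objects.

#' Tidy a Cox hazard-ratio fit
#'
#' @param x an `hr_fit`.
#' @param ... unused.
#' @return one-row tibble with `term`, `estimate` (log HR), `std.error`,
#'   `statistic`, `p.value`, `hr`, `conf.low`, `conf.high`.
#' @method tidy hr_fit
#' @export
tidy.hr_fit <- function(x, ...) {
  tibble::tibble(
    term = "target",
    estimate = x$log_hr,
    std.error = x$se_log_hr,
    statistic = x$log_hr / x$se_log_hr,
    p.value = x$p,
    hr = x$hr,
    conf.low = x$ci_lower,
    conf.high = x$ci_upper
  )
}

#' @rdname tidy.hr_fit
#' @method glance hr_fit
#' @export
glance.hr_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n_t + x$n_c,
    events_t = x$events_t, events_c = x$events_c,
    person_years_t = x$person_years_t, person_years_c = x$person_years_c,
    rate_t = x$rate_t, rate_c = x$rate_c,
    ard_per_1000py = x$ard_per_1000py,
    estimable = x$estimable, ties = x$ties
  )
}

#' Tidy an empirical null distribution
#' @param x a `null_distribution`.
#' @param ... unused.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, ease = ease(x),
                 n_controls_used = x$n_controls_used,
                 n_controls_dropped = x$n_controls_dropped)
}

#' Tidy a meta-analysis result (per-database shrunken estimates)
#' @param x a `meta_result`.
#' @param ... unused.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::tibble(
    database = seq_len(x$n_databases),
    shrunken_log_hr = x$shrunken_log_hr,
    shrunken_hr = exp(x$shrunken_log_hr)
  )
}

#' @rdname tidy.meta_result
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    hr = x$hr, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    log_hr_median = x$log_hr_median, log_hr_mean = x$log_hr_mean,
    tau_median = x$tau_median, ess = x$ess, n_databases = x$n_databases
  )
}

#' Tidy a propensity model (non-zero coefficients)
#' @param x a `propensity_model`.
#' @param ... unused.
#' @method tidy propensity_model
#' @export
tidy.propensity_model <- function(x, ...) {
  tibble::tibble(covariate_id = names(x$coefficients),
                 estimate = unname(x$coefficients)) |>
    dplyr::filter(.data$estimate != 0)
}
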