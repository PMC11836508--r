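# ggplot2 visual summaries for the main result types.

#' Balance (Love) plot
#'
#' Absolute SMD of every covariate before vs after matching, with the
#' conventional 0.1 balance bound.
#'
#' @param object a [balance_table()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot balance_table
#' @export
autoplot.balance_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$smd_before),
                                   y = abs(.data$smd_after))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0.1, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "|SMD| before matching", y = "|SMD| after matching",
                  title = "Covariate balance before vs after 1:1 matching")
}

#' Plot a partial-likelihood profile
#'
#' @param object a [likelihood_profile()].
#' @param ... unused.
#' @return a ggplot of the max-normalized log partial likelihood over the
#'   log-HR grid.
#' @method autoplot likelihood_profile
#' @export
autoplot.likelihood_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_hr, y = .data$log_lik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log hazard ratio",
                  y = "log partial likelihood (max = 0)")
}

#' Posterior of the pooled log hazard ratio
#'
#' @param object a [pool()] result.
#' @param ... unused.
#' @return a ggplot of the posterior draws with the 95% credible bounds.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  df <- object$draws
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_vline(xintercept = log(c(object$ci_lower, object$hr,
                                           object$ci_upper)),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(x = "pooled log hazard ratio", y = "posterior density")
}

#' Forest plot of calibrated per-database hazard ratios
#'
#' @param forest a [forest_table()] (optionally with a `tar_days` column,
#'   as emitted by [run_study()]; supply one window's rows).
#' @return a ggplot on the log-HR axis with the pooled row emphasized.
#' @export
plot_forest <- function(forest) {
  df <- dplyr::mutate(forest,
                      database_id = factor(.data$database_id,
                                           levels = rev(.data$database_id)),
                      pooled = .data$database_id == "pooled")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = .data$database_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled,
                                     size = .data$weight)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(16, 18), guide = "none") +
    ggplot2::scale_size_continuous(range = c(2, 5), guide = "none") +
    ggplot2::labs(x = "calibrated hazard ratio (log scale)", y = NULL)
}

#' Preference-score distributions by arm
#'
#' The empirical-equipoise picture: density of preference scores in the
#' target and comparator cohorts before matching, with the 0.3-0.7 band.
#'
#' @param scores tibble with `arm` and `preference` columns (as stored on
#'   the per-database `scores` of a study run).
#' @return a ggplot.
#' @export
plot_preference_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$preference,
                                       fill = .data$arm)) +
    ggplot2::annotate("rect", xmin = 0.3, xmax = 0.7, ymin = -Inf,
                      ymax = Inf, alpha = 0.12) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "preference score", y = "density", fill = NULL)
}
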