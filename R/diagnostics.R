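#' Evaluate the three pre-defined objective study diagnostics
#'
#' An analysis is valid only if it passes all three checks, each at a
#' strict inequality: (1) covariate balance — the maximum absolute
#' post-matching SMD across all covariates below `thresholds$smd`;
#' (2) empirical equipoise — more than `thresholds$equipoise` of subjects
#' in *both* arms with preference scores in `[0.3, 0.7]`; (3) residual
#' systematic error — EASE below `thresholds$ease`. A missing input marks
#' that check not-evaluable and fails the analysis.
#'
#' @param balance a [balance_table()] (or `NULL`).
#' @param equipoise length-2 numeric of per-arm equipoise fractions
#'   (target, comparator), e.g. from [equipoise_fraction()] (or `NULL`).
#' @param null a fitted [fit_null()] object (or `NULL`).
#' @param thresholds list with `smd`, `equipoise`, `ease`; the defaults
#'   (0.1, 0.2, 0.25) are the study's pre-registered bounds.
#' @param database_id,comparison labels carried into the report.
#' @return one-row `diagnostics_report` tibble with the measured values,
#'   the thresholds used, per-check pass flags and `pass_all`.
#' @export
evaluate_diagnostics <- function(balance, equipoise, null,
                                 thresholds = list(smd = 0.1, equipoise = 0.2,
                                                   ease = 0.25),
                                 database_id = NA_character_,
                                 comparison = "target_vs_comparator") {
  max_smd <- if (is.null(balance)) NA_real_ else max(abs(balance$smd_after))
  eq_t <- if (is.null(equipoise)) NA_real_ else unname(equipoise[1])
  eq_c <- if (is.null(equipoise)) NA_real_ else unname(equipoise[2])
  ease_val <- if (is.null(null)) NA_real_ else ease(null)

  pass_balance <- if (is.na(max_smd)) NA else max_smd < thresholds$smd
  pass_equipoise <- if (is.na(eq_t) || is.na(eq_c)) NA else
    (eq_t > thresholds$equipoise && eq_c > thresholds$equipoise)
  pass_ease <- if (is.na(ease_val)) NA else ease_val < thresholds$ease
  pass_all <- isTRUE(pass_balance) && isTRUE(pass_equipoise) && isTRUE(pass_ease)

  out <- tibble::tibble(
    database_id = database_id,
    comparison = comparison,
    max_abs_smd_after = max_smd,
    equipoise_t = eq_t,
    equipoise_c = eq_c,
    ease_value = ease_val,
    smd_threshold = thresholds$smd,
    equipoise_threshold = thresholds$equipoise,
    ease_threshold = thresholds$ease,
    pass_balance = pass_balance,
    pass_equipoise = pass_equipoise,
    pass_ease = pass_ease,
    pass_all = pass_all
  )
  class(out) <- c("diagnostics_report", class(out))
  out
}

#' Gate estimation results on the study diagnostics
#'
#' Returns exactly the results whose `(database_id, comparison)` report has
#' `pass_all = TRUE`; the exclusions, with the diagnostics that failed, are
#' attached as attribute `"excluded"`.
#'
#' @param reports `diagnostics_report` rows (bind-able tibble).
#' @param results list of `hr_fit` objects, each carrying `database_id`
#'   (and optionally `comparison`) fields.
#' @return the passing subset of `results` (same order), with the
#'   exclusion table attached.
#' @export
gate_for_meta <- function(reports, results) {
  res_db <- vapply(results, function(r) r$database_id %||% NA_character_,
                   character(1))
  res_cmp <- vapply(results, function(r) r$comparison %||% "target_vs_comparator",
                    character(1))
  key <- paste(reports$database_id, reports$comparison)
  missing <- !paste(res_db, res_cmp) %in% key
  if (any(missing))
    stop_bad_arg(paste0("no diagnostics report for: ",
                        paste(unique(res_db[missing]), collapse = ", ")))
  pass <- reports$pass_all[match(paste(res_db, res_cmp), key)]
  excluded <- tibble::tibble(
    database_id = res_db[!pass],
    comparison = res_cmp[!pass],
    reason = vapply(which(!pass), function(i) {
      r <- reports[match(paste(res_db[i], res_cmp[i]), key), ]
      fails <- c("balance", "equipoise", "ease")[
        !vapply(list(r$pass_balance, r$pass_equipoise, r$pass_ease),
                isTRUE, logical(1))]
      paste("failed:", paste(fails, collapse = ", "))
    }, character(1))
  )
  kept <- results[pass]
  if (length(kept) == 0)
    warning("no database-analysis passed all diagnostics; nothing to pool")
  attr(kept, "excluded") <- excluded
  kept
}
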