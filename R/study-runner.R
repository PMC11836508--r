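#' Study configuration
#'
#' Bundles everything [run_study()] needs: the synthetic scenario, the
#' time-at-risk windows (the primary window must be among them), the
#' diagnostic thresholds, the meta-analysis settings, and reporting
#' options. The whole run is deterministic given this object.
#'
#' @param scenario a [scenario_config()].
#' @param tar_days time-at-risk windows to analyze (days).
#' @param primary_tar the primary window (default 60); diagnostics and
#'   gating are computed at this window.
#' @param thresholds diagnostic thresholds, see [evaluate_diagnostics()].
#' @param meta a [meta_config()].
#' @param reg_strength propensity penalty, see [fit_propensity()].
#' @param caliper_sd_mult matching caliper, see [match_1to1()].
#' @param min_cell_count minimum reportable event count (masking).
#' @param comparisons comparison labels; the synthetic network has a single
#'   target-vs-comparator contrast.
#' @param out_dir if non-`NULL`, report tables are written here (CSV/JSON).
#' @export
study_config <- function(scenario = scenario_config(),
                         tar_days = c(30, 60, 90, 365),
                         primary_tar = 60,
                         thresholds = list(smd = 0.1, equipoise = 0.2,
                                           ease = 0.25),
                         meta = meta_config(),
                         reg_strength = "cv",
                         caliper_sd_mult = 0.2,
                         min_cell_count = 5,
                         comparisons = "target_vs_comparator",
                         out_dir = NULL) {
  if (!primary_tar %in% tar_days)
    stop_bad_arg("primary_tar must be among tar_days")
  if (length(comparisons) < 1) stop_bad_arg("need at least one comparison")
  structure(list(scenario = scenario, tar_days = tar_days,
                 primary_tar = primary_tar, thresholds = thresholds,
                 meta = meta, reg_strength = reg_strength,
                 caliper_sd_mult = caliper_sd_mult,
                 min_cell_count = min_cell_count,
                 comparisons = comparisons, out_dir = out_dir),
            class = "study_config")
}

#' Estimate many outcomes on a matched cohort
#'
#' The runner's estimation engine, exported for direct use: fits the Cox
#' treatment-effect model for every requested outcome on one matched
#' cohort at one time-at-risk window, applying each outcome's own 365-day
#' prior-event washout to the matched subjects before extraction.
#'
#' @param db a `synthetic_db`.
#' @param entries matched cohort entries: tibble with `person_id`, `arm`,
#'   `index_date`.
#' @param outcome_ids outcomes to estimate (0 = primary).
#' @param tar_days time-at-risk window.
#' @param grid_bounds,n_points profile grid, see [likelihood_profile()].
#' @param profiles_for outcome ids for which to also compute and attach
#'   the likelihood profile (default: all requested).
#' @return list of `hr_fit` objects in `outcome_ids` order, each with
#'   `outcome_id` (and, where requested, `profile`) fields.
#' @export
estimate_outcomes_matched <- function(db, entries, outcome_ids, tar_days,
                                      grid_bounds = c(-3, 3), n_points = 401,
                                      profiles_for = outcome_ids) {
  base <- entries |>
    dplyr::inner_join(dplyr::select(db$persons, "person_id", "observation_end"),
                      by = "person_id")
  n <- nrow(base)
  n_k <- length(outcome_ids)
  t_cens <- pmax(pmin(tar_days, base$observation_end - base$index_date), 0.5)
  arm <- base$arm

  # flat aggregation over all (outcome, person) event records at once:
  # per pair, whether any event falls in the 365-day washout window and the
  # first post-index qualifying-setting event day
  r <- match(db$outcomes$person_id, base$person_id)
  ko <- match(db$outcomes$outcome_id, outcome_ids)
  sel <- !is.na(r) & !is.na(ko)
  r <- r[sel]; ko <- ko[sel]
  day <- db$outcomes$date[sel]
  qual <- db$outcomes$setting[sel] == "hospital_or_ed"
  idx <- base$index_date[r]
  key <- (ko - 1) * n + r # < 2^31 for all realistic sizes

  pk <- unique(key[day >= idx - 365 & day <= idx - 1])
  prior_by_k <- split((pk - 1) %% n + 1,
                      factor((pk - 1) %/% n + 1, levels = seq_len(n_k)))

  post <- day >= idx & qual
  op <- which(post)
  o <- op[order(key[op], day[op])]
  first <- !duplicated(key[o])
  fk <- key[o][first]
  fday <- day[o][first]
  fpos <- factor((fk - 1) %/% n + 1, levels = seq_len(n_k))
  ev_row_by_k <- split((fk - 1) %% n + 1, fpos)
  ev_day_by_k <- split(fday, fpos)

  lapply(seq_len(n_k), function(j) {
    k <- outcome_ids[j]
    keep <- rep(TRUE, n)
    keep[prior_by_k[[j]]] <- FALSE
    t_event <- rep(NA_real_, n)
    er <- ev_row_by_k[[j]]
    if (length(er)) {
      te <- ev_day_by_k[[j]] - base$index_date[er]
      te[te == 0] <- 0.5
      t_event[er] <- te
    }
    event <- as.integer(!is.na(t_event) & t_event <= t_cens)
    tm <- ifelse(event == 1, t_event, t_cens)[keep]
    surv <- tibble::tibble(
      person_id = base$person_id[keep],
      arm = arm[keep],
      time = tm,
      event = event[keep],
      person_years = tm / 365.25
    )
    fit <- fit_cox(surv)
    if (k %in% profiles_for) {
      fit$profile <- likelihood_profile(surv, grid_bounds, n_points)
    }
    fit$outcome_id <- k
    fit
  })
}

#' Run the complete network study
#'
#' Orchestrates, per database: cohort construction, propensity fitting,
#' preference scores and equipoise, 1:1 matching, covariate balance,
#' per-outcome Cox estimation at every time-at-risk window, empirical-null
#' fitting on the negative controls, calibration of every estimate, and
#' the three-diagnostic report. Databases failing any stage are recorded
#' and skipped (partial-failure contract). Analyses passing all
#' diagnostics are pooled per window with the Bayesian random-effects
#' model on calibrated likelihood profiles. Fully deterministic under a
#' fixed config.
#'
#' Negative-control estimates reuse the primary analysis' matched cohort
#' (with each control's own prior-event washout), mirroring how control
#' estimates share the exposure cohorts of the main analysis.
#'
#' @param config a [study_config()].
#' @return `study_report`: tibbles `estimates` (every database, outcome
#'   and window, with calibrated columns), `diagnostics`, `nulls`,
#'   `attrition`, `forest`; list `meta` keyed by window; `errors`;
#'   `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  scen <- config$scenario
  comparison <- config$comparisons[[1]]
  net <- generate_network(scen)
  outcome_ids <- 0:scen$n_negative_controls

  per_db <- list()
  errors <- list()
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  for (db in net) {
    res <- tryCatch({
      cohort <- build_cohorts(db, config$primary_tar, outcome_id = 0)
      say("db=%s stage=cohort target=%d comparator=%d", db$database_id,
          sum(cohort$arm == "target"), sum(cohort$arm == "comparator"))
      ps <- fit_propensity(db$covariates,
                           cohort$person_id[cohort$arm == "target"],
                           cohort$person_id[cohort$arm == "comparator"],
                           config$reg_strength)
      prev <- ps$prevalence
      scores <- ps$scores |>
        dplyr::mutate(preference = preference_score(
          pmin(pmax(.data$ps, 1e-12), 1 - 1e-12), prev))
      eq <- equipoise_fraction(
        scores$preference[scores$arm == "target"],
        scores$preference[scores$arm == "comparator"])
      matched <- match_1to1(
        scores[scores$arm == "target", c("person_id", "ps")],
        scores[scores$arm == "comparator", c("person_id", "ps")],
        config$caliper_sd_mult)
      say("db=%s stage=match pairs=%d caliper=%.4f", db$database_id,
          nrow(matched), attr(matched, "caliper"))
      balance <- balance_table(db$covariates, cohort, matched)
      entries <- cohort |>
        dplyr::filter(.data$person_id %in% c(matched$target_id,
                                             matched$comparator_id)) |>
        dplyr::select("person_id", "arm", "index_date")

      by_tar <- lapply(config$tar_days, function(tar) {
        fits <- estimate_outcomes_matched(db, entries, outcome_ids, tar,
                                          profiles_for = 0)
        nc <- fits[-1]
        est_ok <- vapply(nc, function(f) f$estimable, logical(1))
        null <- if (sum(est_ok) >= 2) {
          fit_null(vapply(nc, `[[`, numeric(1), "log_hr"),
                   vapply(nc, `[[`, numeric(1), "se_log_hr"))
        } else NULL
        say("db=%s stage=estimate tar=%d controls_estimable=%d",
            db$database_id, tar, sum(est_ok))
        list(tar = tar, fits = fits, null = null)
      })
      names(by_tar) <- as.character(config$tar_days)

      null_primary <- by_tar[[as.character(config$primary_tar)]]$null
      diag <- evaluate_diagnostics(balance, eq, null_primary,
                                   config$thresholds,
                                   database_id = db$database_id,
                                   comparison = comparison)
      list(database_id = db$database_id, cohort = cohort, scores = scores,
           equipoise = eq, matched = matched, balance = balance,
           by_tar = by_tar, diagnostics = diag,
           attrition = attrition(cohort))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[db$database_id]] <- conditionMessage(res)
      say("db=%s stage=error message=%s", db$database_id,
          conditionMessage(res))
    } else {
      per_db[[db$database_id]] <- res
    }
  }
  if (length(per_db) == 0)
    stop_bad_arg(paste0("every database failed; first error: ",
                        errors[[1]]))

  # flat estimates table with calibrated columns
  est_rows <- purrr::map_dfr(per_db, function(pd) {
    purrr::map_dfr(pd$by_tar, function(bt) {
      purrr::map_dfr(bt$fits, function(f) {
        cal <- if (!is.null(bt$null) && f$estimable) {
          calibrate_ci(f$log_hr, f$se_log_hr, bt$null)
        } else NULL
        tibble::tibble(
          database_id = pd$database_id, comparison = comparison,
          outcome_id = f$outcome_id, tar_days = bt$tar,
          log_hr = f$log_hr, se_log_hr = f$se_log_hr, hr = f$hr,
          ci_lower = f$ci_lower, ci_upper = f$ci_upper, p = f$p,
          events_t = f$events_t, events_c = f$events_c,
          events_t_label = mask_count(f$events_t, config$min_cell_count),
          events_c_label = mask_count(f$events_c, config$min_cell_count),
          person_years_t = f$person_years_t, person_years_c = f$person_years_c,
          rate_t = f$rate_t, rate_c = f$rate_c,
          ard_per_1000py = f$ard_per_1000py,
          estimable = f$estimable,
          cal_hr = if (is.null(cal)) NA_real_ else cal$hr,
          cal_ci_lower = if (is.null(cal)) NA_real_ else cal$ci_lower,
          cal_ci_upper = if (is.null(cal)) NA_real_ else cal$ci_upper,
          cal_p = if (is.null(bt$null) || !f$estimable) NA_real_ else
            calibrate_p(f$log_hr, f$se_log_hr, bt$null)
        )
      })
    })
  })

  diagnostics <- purrr::map_dfr(per_db, "diagnostics")
  nulls <- purrr::map_dfr(per_db, function(pd) {
    purrr::map_dfr(pd$by_tar, function(bt) {
      tibble::tibble(
        database_id = pd$database_id, comparison = comparison,
        tar_days = bt$tar,
        mu = if (is.null(bt$null)) NA_real_ else bt$null$mu,
        sigma = if (is.null(bt$null)) NA_real_ else bt$null$sigma,
        ease = if (is.null(bt$null)) NA_real_ else ease(bt$null),
        n_controls_used = if (is.null(bt$null)) 0L else bt$null$n_controls_used
      )
    })
  })
  attrition_tbl <- purrr::map_dfr(per_db, function(pd) {
    dplyr::mutate(pd$attrition, database_id = pd$database_id, .before = 1)
  })

  # gate and pool the primary outcome at each window
  meta <- list()
  forest <- list()
  for (tar in config$tar_days) {
    results <- purrr::map(per_db, function(pd) {
      bt <- pd$by_tar[[as.character(tar)]]
      f <- bt$fits[[1]]
      f$database_id <- pd$database_id
      f$comparison <- comparison
      f$null <- bt$null
      if (!is.null(bt$null)) {
        f$cal_profile <- calibrate_profile(f$profile, bt$null)
        if (f$estimable) {
          f$cal <- calibrate_ci(f$log_hr, f$se_log_hr, bt$null)
          f$cal_p <- calibrate_p(f$log_hr, f$se_log_hr, bt$null)
        }
      }
      f
    })
    gated <- suppressWarnings(gate_for_meta(diagnostics, unname(results)))
    say("tar=%d stage=gate passed=%d of %d", tar, length(gated),
        length(results))
    if (length(gated) > 0) {
      m <- pool(lapply(gated, `[[`, "cal_profile"), config$meta)
      meta[[as.character(tar)]] <- m
      forest[[as.character(tar)]] <-
        dplyr::mutate(forest_table(m, gated, min_cell = config$min_cell_count),
                      tar_days = tar, .before = 1)
    } else {
      meta[as.character(tar)] <- list(NULL)
    }
  }

  report <- structure(
    list(estimates = est_rows, diagnostics = diagnostics, nulls = nulls,
         attrition = attrition_tbl, meta = meta,
         forest = dplyr::bind_rows(forest),
         excluded = attr(suppressWarnings(gate_for_meta(
           diagnostics,
           unname(purrr::map(per_db, function(pd) {
             f <- pd$by_tar[[as.character(config$primary_tar)]]$fits[[1]]
             f$database_id <- pd$database_id
             f$comparison <- comparison
             f
           })))), "excluded"),
         errors = errors, log = log_lines, config = config),
    class = "study_report"
  )
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  databases analyzed: ",
      dplyr::n_distinct(x$estimates$database_id), "\n", sep = "")
  cat("  passing all diagnostics: ", sum(x$diagnostics$pass_all), "\n",
      sep = "")
  m <- x$meta[[as.character(x$config$primary_tar)]]
  if (!is.null(m)) {
    cat(sprintf(
      "  pooled calibrated HR (primary TAR %d d): %.3f (95%% CrI %.3f-%.3f)\n",
      x$config$primary_tar, m$hr, m$ci_lower, m$ci_upper))
  } else {
    cat("  no database passed diagnostics at the primary window\n")
  }
  invisible(x)
}

#' Per-database forest table with pooled summary row
#'
#' One row per gated database — calibrated HR and CI, event rates per 1000
#' person-years, masked event counts — plus the pooled meta-analytic row.
#'
#' @param meta a [pool()] result.
#' @param gated list of gated `hr_fit` objects (each with `database_id`,
#'   calibrated fields).
#' @param masked apply small-cell masking to event counts (default TRUE).
#' @param min_cell masking threshold.
#' @return tibble with fixed column order: `database_id`, `hr`,
#'   `ci_lower`, `ci_upper`, `events_t`, `events_c`, `rate_t`, `rate_c`,
#'   `weight`.
#' @export
forest_table <- function(meta, gated, masked = TRUE, min_cell = 5) {
  if (length(gated) == 0) stop_bad_arg("empty gated set")
  rows <- purrr::map_dfr(gated, function(f) {
    tibble::tibble(
      database_id = f$database_id,
      hr = if (!is.null(f$cal)) f$cal$hr else f$hr,
      ci_lower = if (!is.null(f$cal)) f$cal$ci_lower else f$ci_lower,
      ci_upper = if (!is.null(f$cal)) f$cal$ci_upper else f$ci_upper,
      events_t = if (masked) mask_count(f$events_t, min_cell) else
        as.character(f$events_t),
      events_c = if (masked) mask_count(f$events_c, min_cell) else
        as.character(f$events_c),
      rate_t = f$rate_t, rate_c = f$rate_c,
      weight = if (is.finite(f$se_log_hr %||% NA_real_)) 1 / f$se_log_hr^2
      else NA_real_
    )
  })
  rows$weight <- rows$weight / sum(rows$weight, na.rm = TRUE)
  dplyr::bind_rows(rows, tibble::tibble(
    database_id = "pooled", hr = meta$hr, ci_lower = meta$ci_lower,
    ci_upper = meta$ci_upper, events_t = NA_character_,
    events_c = NA_character_, rate_t = NA_real_, rate_c = NA_real_,
    weight = NA_real_))
}

#' Write a study report's tables to disk
#'
#' `estimates.csv`, `diagnostics.csv`, `attrition.csv`, `forest.csv`,
#' `null.json`, `meta.json` and `run_log.txt` under `dir`. Deterministic:
#' rerunning the same config writes byte-identical files.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$estimates, file.path(dir, "estimates.csv"),
            row.names = FALSE)
  write.csv(report$diagnostics, file.path(dir, "diagnostics.csv"),
            row.names = FALSE)
  write.csv(report$attrition, file.path(dir, "attrition.csv"),
            row.names = FALSE)
  write.csv(report$forest, file.path(dir, "forest.csv"), row.names = FALSE)
  jsonlite::write_json(report$nulls, file.path(dir, "null.json"),
                       auto_unbox = TRUE, digits = NA)
  meta_out <- lapply(report$meta, function(m) {
    if (is.null(m)) return(NULL)
    list(hr = m$hr, ci_lower = m$ci_lower, ci_upper = m$ci_upper,
         log_hr_median = m$log_hr_median, log_hr_mean = m$log_hr_mean,
         tau_median = m$tau_median, ess = m$ess,
         n_databases = m$n_databases,
         shrunken_log_hr = m$shrunken_log_hr,
         config = unclass(m$config))
  })
  jsonlite::write_json(meta_out, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
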