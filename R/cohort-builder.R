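#' Build target and comparator cohorts under the study's eligibility rules
#'
#' Applies, in order, the new-user eligibility chain: (1) the first
#' exposure to any study drug class defines candidacy; persons whose first
#' exposure day carries both drug classes are excluded; (2) age >= 35 years
#' at the index date; (3) at least 365 days of observation before index;
#' (4) an indication record on the index date or within the 7 days before
#' it; (5) no hospitalization on the index date or within the 7 days
#' before it; (6) no event of the analyzed outcome in the 365 days before
#' index (day -365 through day -1). "On or within 7 days prior" is the
#' closed 8-day interval including the index day.
#'
#' @param db a `synthetic_db` (or any list with the same tables).
#' @param tar_days time-at-risk window in days; kept for interface symmetry
#'   and validated, but no eligibility step depends on it.
#' @param outcome_id outcome whose 365-day washout is applied (0 = primary).
#' @return tibble with `person_id`, `arm` ("target"/"comparator"),
#'   `index_date`, `age_at_index`; the per-step exclusion log is attached
#'   as attribute `"attrition"` (also via [attrition()]).
#' @export
#' @examples
#' db <- generate_database(scenario_config(n_databases = 1, n_persons = 300,
#'                                         seed = 2), 1)
#' ch <- build_cohorts(db, tar_days = 60)
#' attrition(ch)
build_cohorts <- function(db, tar_days = 60, outcome_id = 0) {
  if (!tar_days %in% c(30, 60, 90, 365))
    stop_bad_arg("tar_days must be one of 30, 60, 90, 365")
  if (!outcome_id %in% db$truth$outcome_id)
    stop_bad_arg(paste0("unknown outcome_id: ", outcome_id))

  origin <- db$origin_year %||% 2010

  # step 1: first qualifying exposure per person; same-day dual-class
  # qualifiers are excluded rather than assigned
  first_exp <- db$exposures |>
    dplyr::group_by(.data$person_id) |>
    dplyr::filter(.data$start_date == min(.data$start_date)) |>
    dplyr::ungroup()
  dual <- first_exp |>
    dplyr::count(.data$person_id) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$person_id)
  cand <- first_exp |>
    dplyr::filter(!.data$person_id %in% dual) |>
    dplyr::transmute(person_id = .data$person_id,
                     arm = .data$drug_class,
                     index_date = .data$start_date)
  n_candidates <- dplyr::n_distinct(db$exposures$person_id)
  log <- tibble::tibble(step = "candidates (first use of any study drug)",
                        excluded = NA_integer_, remaining = n_candidates)
  add_step <- function(log, label, before, after) {
    dplyr::bind_rows(log, tibble::tibble(step = label,
                                         excluded = before - after,
                                         remaining = after))
  }
  log <- add_step(log, "eligible for a single arm on the index day",
                  n_candidates, nrow(cand))

  cand <- cand |>
    dplyr::inner_join(db$persons, by = "person_id") |>
    dplyr::mutate(age_at_index =
                    floor(.data$index_date / 365.25) + origin - .data$birth_year)

  n0 <- nrow(cand)
  cand <- dplyr::filter(cand, .data$age_at_index >= 35)
  log <- add_step(log, "aged 35 years or older at index", n0, nrow(cand))

  n0 <- nrow(cand)
  cand <- dplyr::filter(cand, .data$observation_start <= .data$index_date - 365)
  log <- add_step(log, ">= 365 days of prior observation", n0, nrow(cand))

  n0 <- nrow(cand)
  ind_ok <- cand |>
    dplyr::left_join(db$indications, by = "person_id",
                     relationship = "many-to-many") |>
    dplyr::filter(!is.na(.data$date),
                  .data$date >= .data$index_date - 7,
                  .data$date <= .data$index_date) |>
    dplyr::distinct(.data$person_id)
  cand <- dplyr::semi_join(cand, ind_ok, by = "person_id")
  log <- add_step(log, "indication recorded on or within 7 days before index",
                  n0, nrow(cand))

  n0 <- nrow(cand)
  hosp_bad <- cand |>
    dplyr::inner_join(db$hospitalizations, by = "person_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$date >= .data$index_date - 7,
                  .data$date <= .data$index_date) |>
    dplyr::distinct(.data$person_id)
  cand <- dplyr::anti_join(cand, hosp_bad, by = "person_id")
  log <- add_step(log, "not hospitalized on or within 7 days before index",
                  n0, nrow(cand))

  n0 <- nrow(cand)
  prior_event <- db$outcomes |>
    dplyr::filter(.data$outcome_id == !!outcome_id) |>
    dplyr::inner_join(dplyr::select(cand, "person_id", "index_date"),
                      by = "person_id") |>
    dplyr::filter(.data$date >= .data$index_date - 365,
                  .data$date <= .data$index_date - 1) |>
    dplyr::distinct(.data$person_id)
  cand <- dplyr::anti_join(cand, prior_event, by = "person_id")
  log <- add_step(log, "no outcome event in the 365 days before index",
                  n0, nrow(cand))

  out <- cand |>
    dplyr::select("person_id", "arm", "index_date", "age_at_index") |>
    dplyr::arrange(.data$person_id)
  attr(out, "attrition") <- log
  attr(out, "outcome_id") <- outcome_id
  out
}

#' Per-step exclusion counts of a built cohort
#' @param cohort result of [build_cohorts()].
#' @return tibble with `step`, `excluded`, `remaining`.
#' @export
attrition <- function(cohort) attr(cohort, "attrition")

#' Extract time-at-risk survival records
#'
#' For each cohort member, follow-up runs from the index date to the first
#' qualifying outcome event (an event of `outcome_id` in the qualifying
#' hospital/ED setting), the end of the time-at-risk window, or the end of
#' observation, whichever comes first (intent-to-treat; no censoring at
#' treatment discontinuation). Events on the index day itself are kept with
#' the survival time set to 0.5 day so that times stay positive.
#'
#' @param cohort tibble from [build_cohorts()] (needs `person_id`, `arm`,
#'   `index_date`).
#' @param db the `synthetic_db` the cohort was built from.
#' @param outcome_id outcome to analyze.
#' @param tar_days time-at-risk window (days after index).
#' @return tibble with `person_id`, `arm`, `time` (days, > 0), `event`
#'   (0/1) and `person_years` (`time / 365.25`). Empty cohort gives an
#'   empty tibble.
#' @export
extract_survival <- function(cohort, db, outcome_id = 0, tar_days = 60) {
  if (nrow(cohort) == 0) {
    return(tibble::tibble(person_id = integer(), arm = character(),
                          time = numeric(), event = integer(),
                          person_years = numeric()))
  }
  base <- cohort |>
    dplyr::select("person_id", "arm", "index_date") |>
    dplyr::inner_join(dplyr::select(db$persons, "person_id", "observation_end"),
                      by = "person_id")

  first_ev <- db$outcomes |>
    dplyr::filter(.data$outcome_id == !!outcome_id,
                  .data$setting == "hospital_or_ed") |>
    dplyr::inner_join(dplyr::select(base, "person_id", "index_date"),
                      by = "person_id") |>
    dplyr::filter(.data$date >= .data$index_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(event_day = min(.data$date), .groups = "drop")

  base |>
    dplyr::left_join(first_ev, by = "person_id") |>
    dplyr::mutate(
      t_event = .data$event_day - .data$index_date,
      t_event = ifelse(!is.na(.data$t_event) & .data$t_event == 0, 0.5,
                       .data$t_event),
      t_cens = pmax(pmin(tar_days, .data$observation_end - .data$index_date),
                    0.5),
      event = as.integer(!is.na(.data$t_event) & .data$t_event <= .data$t_cens),
      time = ifelse(.data$event == 1, .data$t_event, .data$t_cens),
      person_years = .data$time / 365.25
    ) |>
    dplyr::select("person_id", "arm", "time", "event", "person_years")
}
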