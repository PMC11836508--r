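# Shared fixtures: a hand-built miniature database and small pipeline
# helpers used across test files. Everything is constructed in code.

empty_events <- function() {
  tibble::tibble(person_id = integer(), date = integer())
}

# A synthetic_db assembled by hand so each eligibility rule can be probed
# with exact dates.
toy_db <- function(persons,
                   exposures,
                   indications = empty_events(),
                   hospitalizations = empty_events(),
                   outcomes = tibble::tibble(person_id = integer(),
                                             outcome_id = integer(),
                                             date = integer(),
                                             setting = character()),
                   covariates = tibble::tibble(person_id = integer(),
                                               covariate_id = integer(),
                                               value = integer()),
                   n_outcomes = 2) {
  structure(
    list(database_id = "TOY",
         persons = persons,
         covariates = covariates,
         exposures = exposures,
         indications = indications,
         hospitalizations = hospitalizations,
         outcomes = outcomes,
         truth = tibble::tibble(outcome_id = 0:n_outcomes,
                                true_log_hr = 0, bias = 0),
         origin_year = 2010),
    class = "synthetic_db")
}

# person born so that their age at index `idx` equals `age`
birth_for_age <- function(idx, age) 2010 + floor(idx / 365.25) - age

toy_person <- function(id, idx = 400, age = 45, obs_start = 0,
                       obs_end = 2000) {
  tibble::tibble(person_id = id, birth_year = birth_for_age(idx, age),
                 sex = "F", observation_start = obs_start,
                 observation_end = obs_end)
}

# survival tibble shorthand
surv_tbl <- function(arm, time, event) {
  tibble::tibble(person_id = seq_along(arm), arm = arm, time = time,
                 event = as.integer(event), person_years = time / 365.25)
}

# the canonical 4-subject dataset whose Breslow MLE is log(sqrt(2))
four_subject_surv <- function() {
  surv_tbl(c("target", "comparator", "target", "comparator"),
           c(1, 2, 3, 3), c(1, 1, 0, 0))
}

# Independent reference: Breslow partial log-likelihood computed naively
# from its definition (loop over event times, explicit risk sets).
naive_breslow_loglik <- function(beta, surv) {
  x <- as.integer(surv$arm == "target")
  ll <- 0
  for (tt in sort(unique(surv$time[surv$event == 1]))) {
    d_idx <- which(surv$event == 1 & surv$time == tt)
    risk <- which(surv$time >= tt)
    for (i in d_idx) {
      ll <- ll + beta * x[i]
    }
    ll <- ll - length(d_idx) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force grid maximizer of the naive partial likelihood
naive_cox_mle <- function(surv, lo = -4, hi = 4, n = 8001) {
  grid <- seq(lo, hi, length.out = n)
  ll <- vapply(grid, naive_breslow_loglik, numeric(1), surv = surv)
  grid[which.max(ll)]
}

# run the eligibility + propensity + matching front end of the pipeline on
# one generated database, returning everything the later stages need
run_front_end <- function(db, reg_strength = "cv", caliper_sd_mult = 0.2) {
  cohort <- build_cohorts(db, tar_days = 60, outcome_id = 0)
  ps <- fit_propensity(db$covariates,
                       cohort$person_id[cohort$arm == "target"],
                       cohort$person_id[cohort$arm == "comparator"],
                       reg_strength)
  pref <- preference_score(pmin(pmax(ps$scores$ps, 1e-12), 1 - 1e-12),
                           ps$prevalence)
  matched <- match_1to1(
    ps$scores[ps$scores$arm == "target", c("person_id", "ps")],
    ps$scores[ps$scores$arm == "comparator", c("person_id", "ps")],
    caliper_sd_mult)
  entries <- cohort[cohort$person_id %in% c(matched$target_id,
                                            matched$comparator_id),
                    c("person_id", "arm", "index_date")]
  list(cohort = cohort, ps = ps,
       pref_t = pref[ps$scores$arm == "target"],
       pref_c = pref[ps$scores$arm == "comparator"],
       matched = matched, entries = entries,
       balance = balance_table(db$covariates, cohort, matched))
}

# negative-control estimates for a database: fits on the matched cohort
control_estimates <- function(db, entries, n_controls, tar = 60) {
  fits <- estimate_outcomes_matched(db, entries, seq_len(n_controls), tar,
                                    profiles_for = integer(0))
  ok <- vapply(fits, function(f) f$estimable, logical(1))
  list(beta = vapply(fits, function(f) f$log_hr, numeric(1)),
       se = vapply(fits, function(f) f$se_log_hr, numeric(1)),
       estimable = ok)
}
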