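#' Scenario configuration for the synthetic database network
#'
#' Defines one simulation scenario: how many databases, how persons,
#' covariates, treatment assignment, outcomes and (optionally) systematic
#' bias are generated. The defaults describe a moderately confounded
#' multi-database network: binary baseline covariates that raise both the
#' odds of receiving the target drug and the outcome hazard, a rare
#' primary outcome, and 50 true-null negative-control outcomes.
#'
#' Time is an integer day index from a common origin (Jan 1 of
#' `origin_year`); no calendar arithmetic is performed anywhere.
#'
#' @param n_databases number of databases in the network.
#' @param n_persons persons per database.
#' @param n_covariates number of binary baseline covariates.
#' @param covariate_prevalence_range range from which each database draws
#'   its covariate prevalences (uniform, per covariate per database).
#' @param treatment_model list with `intercept` (log-odds) and `coefs`
#'   (length `n_covariates`, log-odds ratios) for the logistic model that
#'   assigns the target vs comparator drug class.
#' @param intercept_range optional length-2 numeric; when supplied, each
#'   database draws its own treatment-model intercept uniformly from this
#'   range, producing database-specific exposure prevalences (and hence
#'   database-specific equipoise).
#' @param baseline_hazard baseline outcome hazard, events per person-day.
#' @param covariate_hazard_coefs log-hazard-ratio per covariate, shared by
#'   every outcome (measured confounding).
#' @param true_log_hr true log hazard ratio (target vs comparator) for the
#'   primary outcome; negative controls always have true log HR 0.
#' @param n_negative_controls number of true-null control outcomes (>= 2).
#' @param bias_mean,bias_sd differential-ascertainment bias: each outcome
#'   (primary and controls) receives a log-HR shift drawn once per outcome
#'   as Normal(bias_mean, bias_sd^2), applied to the target arm's hazard in
#'   every database. This is systematic (network-wide), not random, error.
#' @param unmeasured_confounder `NULL`, or a list with `prevalence`,
#'   `trt_log_odds` and `outcome_log_hazard`: a binary confounder that is
#'   never written to the covariate table.
#' @param observation_length_range days of observation per person (uniform).
#' @param indication_fraction fraction of persons with an indication record
#'   in the 7 days up to the exposure date.
#' @param hospitalization_rate fraction of persons with one hospitalization
#'   at a uniform day in their observation period.
#' @param hospital_setting_fraction fraction of outcome events recorded in
#'   a hospital or emergency-department setting (the qualifying setting).
#' @param birth_year_range,female_fraction,origin_year demographics.
#' @param seed master integer seed; identical configs produce byte-identical
#'   networks.
#'
#' @return an object of class `scenario_config` (a validated list).
#' @export
#' @examples
#' cfg <- scenario_config(n_databases = 2, n_persons = 500, seed = 7)
#' net <- generate_network(cfg)
#' length(net)
scenario_config <- function(n_databases = 14,
                            n_persons = 20000,
                            n_covariates = 20,
                            covariate_prevalence_range = c(0.02, 0.3),
                            treatment_model = list(
                              intercept = -1.2,
                              coefs = rep(0.3, n_covariates)
                            ),
                            intercept_range = NULL,
                            baseline_hazard = 1e-4,
                            covariate_hazard_coefs = rep(0.3, n_covariates),
                            true_log_hr = 0,
                            n_negative_controls = 50,
                            bias_mean = 0,
                            bias_sd = 0,
                            unmeasured_confounder = NULL,
                            observation_length_range = c(1095, 2920),
                            indication_fraction = 0.9,
                            hospitalization_rate = 0.15,
                            hospital_setting_fraction = 0.9,
                            birth_year_range = c(1920, 1985),
                            female_fraction = 0.7,
                            origin_year = 2010,
                            seed = 1) {
  cfg <- list(
    n_databases = as.integer(n_databases),
    n_persons = as.integer(n_persons),
    n_covariates = as.integer(n_covariates),
    covariate_prevalence_range = as.numeric(covariate_prevalence_range),
    treatment_model = treatment_model,
    intercept_range = if (is.null(intercept_range)) NULL else as.numeric(intercept_range),
    baseline_hazard = baseline_hazard,
    covariate_hazard_coefs = as.numeric(covariate_hazard_coefs),
    true_log_hr = true_log_hr,
    n_negative_controls = as.integer(n_negative_controls),
    bias_mean = bias_mean,
    bias_sd = bias_sd,
    unmeasured_confounder = unmeasured_confounder,
    observation_length_range = as.numeric(observation_length_range),
    indication_fraction = indication_fraction,
    hospitalization_rate = hospitalization_rate,
    hospital_setting_fraction = hospital_setting_fraction,
    birth_year_range = as.numeric(birth_year_range),
    female_fraction = female_fraction,
    origin_year = origin_year,
    seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (cfg$n_databases < 1L || cfg$n_persons < 1L || cfg$n_covariates < 1L)
    stop_bad_arg("n_databases, n_persons and n_covariates must be positive")
  pr <- cfg$covariate_prevalence_range
  if (length(pr) != 2 || any(pr < 0) || any(pr > 1) || pr[1] > pr[2])
    stop_bad_arg("covariate_prevalence_range must be an increasing pair in [0, 1]")
  if (cfg$baseline_hazard <= 0)
    stop_bad_arg("baseline_hazard must be > 0")
  if (cfg$n_negative_controls < 2L)
    stop_bad_arg("n_negative_controls must be >= 2")
  if (length(cfg$covariate_hazard_coefs) != cfg$n_covariates)
    stop_bad_arg("covariate_hazard_coefs must have length n_covariates")
  if (length(cfg$treatment_model$coefs) != cfg$n_covariates)
    stop_bad_arg("treatment_model$coefs must have length n_covariates")
  probs <- c(cfg$indication_fraction, cfg$hospitalization_rate,
             cfg$hospital_setting_fraction, cfg$female_fraction)
  if (any(probs < 0 | probs > 1))
    stop_bad_arg("fractions and rates must lie in [0, 1]")
  uc <- cfg$unmeasured_confounder
  if (!is.null(uc)) {
    if (!all(c("prevalence", "trt_log_odds", "outcome_log_hazard") %in% names(uc)))
      stop_bad_arg("unmeasured_confounder needs prevalence, trt_log_odds, outcome_log_hazard")
    if (uc$prevalence < 0 || uc$prevalence > 1)
      stop_bad_arg("unmeasured_confounder$prevalence must lie in [0, 1]")
  }
  if (cfg$bias_sd < 0) stop_bad_arg("bias_sd must be >= 0")
  invisible(cfg)
}

# Per-outcome ascertainment-bias shifts are a network-level property: drawn
# once from the master seed, shared by every database, so that the error
# they induce is systematic rather than random.
network_bias_draws <- function(config) {
  k <- config$n_negative_controls
  with_local_seed(
    substream_seed(config$seed, "outcome-bias"),
    rnorm(k + 1L, config$bias_mean, config$bias_sd)
  )
}

#' Generate one synthetic database
#'
#' Draws a single simulated data source under a scenario: persons with
#' observation periods, sparse binary covariates at database-specific
#' prevalences, one qualifying exposure episode per person whose drug class
#' (target vs comparator) follows the logistic treatment model, indication
#' and hospitalization records, and first-event times for the primary
#' outcome and every negative control from exponential hazards. The true
#' log hazard ratio applies to the primary outcome only; per-outcome
#' ascertainment bias (shared across the network) multiplies the target
#' arm's post-index hazard.
#'
#' Deterministic given `(config$seed, database_index)`.
#'
#' @param config a [scenario_config()].
#' @param database_index which database to generate (1-based).
#' @return an object of class `synthetic_db`: a list with `database_id` and
#'   tibbles `persons`, `covariates` (long sparse, 1-entries only),
#'   `exposures`, `indications`, `hospitalizations`, `outcomes`, and
#'   `truth` (per-outcome true log HR and injected bias).
#' @export
generate_database <- function(config, database_index) {
  validate_scenario_config(config)
  database_index <- as.integer(database_index)
  if (database_index < 1L || database_index > config$n_databases)
    stop_bad_arg("database_index must be in 1..n_databases")

  bias <- network_bias_draws(config)
  db_seed <- substream_seed(config$seed, paste0("database-", database_index))

  with_local_seed(db_seed, {
    n <- config$n_persons
    k_nc <- config$n_negative_controls

    intercept <- if (is.null(config$intercept_range)) {
      config$treatment_model$intercept
    } else {
      runif(1, config$intercept_range[1], config$intercept_range[2])
    }
    prevalence <- runif(config$n_covariates,
                        config$covariate_prevalence_range[1],
                        config$covariate_prevalence_range[2])

    obs_start <- sample.int(1000L, n, replace = TRUE) - 1L
    obs_len <- floor(runif(n, config$observation_length_range[1],
                           config$observation_length_range[2] + 1))
    obs_end <- obs_start + as.integer(obs_len)
    persons <- tibble::tibble(
      person_id = seq_len(n),
      birth_year = sample(seq(config$birth_year_range[1],
                              config$birth_year_range[2]), n, replace = TRUE),
      sex = ifelse(runif(n) < config$female_fraction, "F", "M"),
      observation_start = obs_start,
      observation_end = obs_end
    )

    # sparse binary covariates; accumulate the treatment and hazard linear
    # predictors column-by-column so no dense matrix is ever held
    lp_trt <- numeric(n)
    lp_haz <- numeric(n)
    cov_person <- vector("list", config$n_covariates)
    cov_id <- vector("list", config$n_covariates)
    for (j in seq_len(config$n_covariates)) {
      x <- rbinom(n, 1L, prevalence[j])
      idx <- which(x == 1L)
      cov_person[[j]] <- idx
      cov_id[[j]] <- rep.int(j, length(idx))
      lp_trt <- lp_trt + x * config$treatment_model$coefs[j]
      lp_haz <- lp_haz + x * config$covariate_hazard_coefs[j]
    }
    covariates <- tibble::tibble(
      person_id = unlist(cov_person, use.names = FALSE),
      covariate_id = unlist(cov_id, use.names = FALSE),
      value = 1L
    )

    u <- NULL
    uc <- config$unmeasured_confounder
    if (!is.null(uc)) {
      u <- rbinom(n, 1L, uc$prevalence)
      lp_trt <- lp_trt + u * uc$trt_log_odds
      lp_haz <- lp_haz + u * uc$outcome_log_hazard
    }

    # one qualifying exposure episode per person (new-user design); the
    # index day is placed so most, but not all, persons clear the 365-day
    # prior-observation requirement
    idx_low <- obs_start + 330
    idx_high <- obs_start + pmin(obs_len - 400, 1500)
    index_day <- floor(runif(n, idx_low, idx_high))
    treat <- rbinom(n, 1L, plogis(intercept + lp_trt))
    exposures <- tibble::tibble(
      person_id = seq_len(n),
      drug_class = ifelse(treat == 1L, "target", "comparator"),
      start_date = as.integer(index_day)
    )

    has_ind <- runif(n) < config$indication_fraction
    indications <- tibble::tibble(
      person_id = which(has_ind),
      date = as.integer(index_day[has_ind] -
                          sample(0:7, sum(has_ind), replace = TRUE))
    )

    has_hosp <- runif(n) < config$hospitalization_rate
    nh <- sum(has_hosp)
    hospitalizations <- tibble::tibble(
      person_id = which(has_hosp),
      date = as.integer(floor(runif(nh, obs_start[has_hosp],
                                    obs_end[has_hosp] + 1)))
    )

    # first event per outcome per person: piecewise-exponential — the
    # pre-index hazard carries only baseline + covariate (+ confounder)
    # effects; after the index day the target arm's hazard is multiplied by
    # exp(true effect [primary only] + per-outcome ascertainment bias)
    h_pre <- config$baseline_hazard * exp(lp_haz)
    out_list <- vector("list", k_nc + 1L)
    for (k in 0:k_nc) {
      mult <- exp(treat * (bias[k + 1L] + if (k == 0L) config$true_log_hr else 0))
      t1 <- rexp(n, h_pre)
      pre_hit <- obs_start + t1 < index_day
      day <- rep(NA_real_, n)
      day[pre_hit] <- ceiling(obs_start[pre_hit] + t1[pre_hit])
      late <- !pre_hit
      t2 <- rexp(sum(late), (h_pre * mult)[late])
      post_day <- index_day[late] + t2
      post_hit <- post_day <= obs_end[late]
      day[late][post_hit] <- ceiling(post_day[post_hit])
      hit <- which(!is.na(day))
      setting <- ifelse(runif(length(hit)) < config$hospital_setting_fraction,
                        "hospital_or_ed", "other")
      out_list[[k + 1L]] <- tibble::tibble(
        person_id = hit,
        outcome_id = k,
        date = as.integer(day[hit]),
        setting = setting
      )
    }
    outcomes <- dplyr::bind_rows(out_list)

    truth <- tibble::tibble(
      outcome_id = 0:k_nc,
      true_log_hr = c(config$true_log_hr, rep(0, k_nc)),
      bias = bias
    )

    structure(
      list(
        database_id = sprintf("SYN-%02d", database_index),
        persons = persons,
        covariates = covariates,
        exposures = exposures,
        indications = indications,
        hospitalizations = hospitalizations,
        outcomes = outcomes,
        truth = truth,
        origin_year = config$origin_year
      ),
      class = "synthetic_db"
    )
  })
}

#' Generate the full synthetic database network
#'
#' @param config a [scenario_config()].
#' @return list of [generate_database()] results, one per database, with
#'   independently drawn persons and database-specific treatment-model
#'   intercepts, but a single shared per-outcome bias draw (systematic
#'   error is correlated across the network by construction).
#' @export
generate_network <- function(config) {
  validate_scenario_config(config)
  lapply(seq_len(config$n_databases), function(i) generate_database(config, i))
}

#' @export
print.synthetic_db <- function(x, ...) {
  cat("<synthetic_db> ", x$database_id, "\n", sep = "")
  cat("  persons:   ", nrow(x$persons), "\n", sep = "")
  cat("  covariates:", nrow(x$covariates), " (long sparse 1-entries)\n", sep = "")
  cat("  outcomes:  ", nrow(x$outcomes), " events across ",
      nrow(x$truth), " outcome definitions\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic database as delimited text
#'
#' One directory per database: `persons.csv`, `covariates.csv` (long
#' sparse), `exposures.csv`, `indications.csv`, `hospitalizations.csv`,
#' `outcomes.csv`, plus `truth.json` with per-outcome true log hazard
#' ratios and injected bias terms. All CSVs carry headers; UTF-8.
#'
#' @param db a `synthetic_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (writer); a `synthetic_db` (reader).
#' @export
write_synthetic_db <- function(db, dir) {
  stopifnot(inherits(db, "synthetic_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("persons", "covariates", "exposures", "indications",
              "hospitalizations", "outcomes")
  for (tb in tables) {
    write.csv(db[[tb]], file.path(dir, paste0(tb, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(
    list(database_id = db$database_id, origin_year = db$origin_year,
         truth = db$truth),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_synthetic_db
#' @export
read_synthetic_db <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  db <- list(
    database_id = meta$database_id,
    persons = tibble::as_tibble(read.csv(file.path(dir, "persons.csv"))),
    covariates = tibble::as_tibble(read.csv(file.path(dir, "covariates.csv"))),
    exposures = tibble::as_tibble(read.csv(file.path(dir, "exposures.csv"))),
    indications = tibble::as_tibble(read.csv(file.path(dir, "indications.csv"))),
    hospitalizations = tibble::as_tibble(read.csv(file.path(dir, "hospitalizations.csv"))),
    outcomes = tibble::as_tibble(read.csv(file.path(dir, "outcomes.csv"))),
    truth = tibble::as_tibble(meta$truth),
    origin_year = meta$origin_year
  )
  structure(db, class = "synthetic_db")
}
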