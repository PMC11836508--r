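test_that("generation is deterministic under the same config and index", {
  cfg <- scenario_config(n_databases = 2, n_persons = 800,
                         n_negative_controls = 3, seed = 7)
  expect_identical(generate_database(cfg, 1), generate_database(cfg, 1))
  expect_identical(generate_network(cfg), generate_network(cfg))
  # and leaves the caller's RNG stream untouched
  set.seed(123); before <- .Random.seed
  invisible(generate_database(cfg, 2))
  expect_identical(before, .Random.seed)
})

test_that("config invariants are enforced", {
  expect_error(scenario_config(n_negative_controls = 1), "negative_controls")
  expect_error(scenario_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(scenario_config(covariate_prevalence_range = c(0.5, 1.5)),
               "prevalence_range")
  expect_error(scenario_config(n_persons = 0), "positive")
  cfg <- scenario_config(n_databases = 1, n_persons = 100)
  expect_error(generate_database(cfg, 2), "database_index")
})

test_that("all generated records respect person observation periods", {
  cfg <- scenario_config(n_databases = 1, n_persons = 1500,
                         n_negative_controls = 3, seed = 21)
  db <- generate_database(cfg, 1)
  per <- db$persons
  expect_true(all(per$observation_end > per$observation_start))
  look <- function(tb, col = "date") {
    i <- match(tb$person_id, per$person_id)
    all(tb[[col]] >= per$observation_start[i] &
          tb[[col]] <= per$observation_end[i])
  }
  expect_true(look(db$exposures, "start_date"))
  expect_true(look(db$outcomes))
  expect_true(look(db$hospitalizations))
  expect_true(all(db$covariates$value == 1L))
  expect_setequal(unique(db$exposures$drug_class), c("target", "comparator"))
  # one exposure episode per person
  expect_equal(anyDuplicated(db$exposures$person_id), 0L)
})

test_that("truth table: negative controls are exact nulls without bias", {
  cfg <- scenario_config(n_databases = 1, n_persons = 200,
                         n_negative_controls = 10, true_log_hr = 0.4,
                         bias_mean = 0, bias_sd = 0, seed = 5)
  db <- generate_database(cfg, 1)
  expect_equal(db$truth$true_log_hr, c(0.4, rep(0, 10)))
  expect_equal(db$truth$bias, rep(0, 11))
})

test_that("null scenario yields a crude HR near 1 at large n", {
  cfg <- scenario_config(
    n_databases = 1, n_persons = 20000, n_negative_controls = 2,
    treatment_model = list(intercept = -0.4, coefs = rep(0, 20)),
    covariate_hazard_coefs = rep(0, 20), true_log_hr = 0, seed = 31)
  db <- generate_database(cfg, 1)
  ch <- build_cohorts(db, 365)
  sv <- extract_survival(ch, db, 0, 365)
  hr <- fit_cox(sv)$hr
  expect_gt(hr, 0.85)
  expect_lt(hr, 1.18)
})

test_that("an unmeasured confounder biases the crude HR upward", {
  hrs <- vapply(1:12, function(s) {
    cfg <- scenario_config(
      n_databases = 1, n_persons = 4000, n_negative_controls = 2,
      n_covariates = 2,
      treatment_model = list(intercept = -0.3, coefs = rep(0, 2)),
      covariate_hazard_coefs = rep(0, 2),
      unmeasured_confounder = list(prevalence = 0.3, trt_log_odds = 1.5,
                                   outcome_log_hazard = 1.5),
      true_log_hr = 0, seed = 100 + s)
    db <- generate_database(cfg, 1)
    ch <- build_cohorts(db, 365)
    fit_cox(extract_survival(ch, db, 0, 365))$hr
  }, numeric(1))
  expect_gt(mean(hrs), 1.1)
})

test_that("ground truth hazard ratio is recovered without confounding", {
  cfg <- scenario_config(
    n_databases = 1, n_persons = 20000, n_negative_controls = 2,
    treatment_model = list(intercept = 0, coefs = rep(0, 20)),
    covariate_hazard_coefs = rep(0, 20),
    true_log_hr = log(2), seed = 77)
  db <- generate_database(cfg, 1)
  ch <- build_cohorts(db, 365)
  fit <- fit_cox(extract_survival(ch, db, 0, 365))
  # tolerance ~3 sampling SEs of the estimate
  expect_lt(abs(fit$log_hr - log(2)), 3 * fit$se_log_hr)
})

test_that("a wide intercept range spreads exposure prevalence across sites", {
  cfg <- scenario_config(n_databases = 5, n_persons = 3000,
                         n_negative_controls = 2,
                         intercept_range = c(-2, 1), seed = 13)
  net <- generate_network(cfg)
  expect_length(net, 5)
  expect_length(unique(vapply(net, `[[`, character(1), "database_id")), 5)
  prev <- vapply(net, function(db) mean(db$exposures$drug_class == "target"),
                 numeric(1))
  expect_gt(diff(range(prev)), 0.1)
  # per-outcome bias draws are shared across the network
  expect_identical(net[[1]]$truth, net[[2]]$truth)
})

test_that("csv writer and reader round-trip a database", {
  cfg <- scenario_config(n_databases = 1, n_persons = 150,
                         n_negative_controls = 2, seed = 3)
  db <- generate_database(cfg, 1)
  dir <- withr::local_tempdir()
  write_synthetic_db(db, dir)
  expect_true(file.exists(file.path(dir, "persons.csv")))
  back <- read_synthetic_db(dir)
  for (tb in c("persons", "covariates", "exposures", "indications",
               "hospitalizations", "outcomes")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(db[[tb]]),
                 ignore_attr = TRUE)
  }
  expect_equal(back$truth$bias, db$truth$bias)
})
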