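# Each eligibility rule probed with exact dates on a hand-built database.

make_eligibility_db <- function() {
  idx <- 400
  persons <- dplyr::bind_rows(
    toy_person(1, idx, age = 45),                     # fully eligible target
    toy_person(2, idx, age = 34),                     # too young
    toy_person(3, idx, age = 45, obs_start = idx - 200), # short history
    toy_person(4, idx, age = 45),                     # no indication
    toy_person(5, idx, age = 45),                     # hospitalized at -3
    toy_person(6, idx, age = 45),                     # prior outcome event
    toy_person(7, idx, age = 45)                      # fully eligible comparator
  )
  exposures <- tibble::tibble(
    person_id = 1:7,
    drug_class = c("target", "target", "target", "target", "target",
                   "target", "comparator"),
    start_date = idx
  )
  indications <- tibble::tibble(person_id = c(1, 2, 3, 5, 6, 7),
                                date = idx - 2L)
  hospitalizations <- tibble::tibble(person_id = 5, date = idx - 3L)
  outcomes <- tibble::tibble(person_id = 6, outcome_id = 0L,
                             date = idx - 100L, setting = "hospital_or_ed")
  toy_db(persons, exposures, indications, hospitalizations, outcomes)
}

test_that("each eligibility filter excludes exactly the intended person", {
  db <- make_eligibility_db()
  ch <- build_cohorts(db, 60, outcome_id = 0)
  expect_setequal(ch$person_id, c(1, 7))
  expect_equal(ch$arm[ch$person_id == 1], "target")
  expect_equal(ch$arm[ch$person_id == 7], "comparator")
  log <- attrition(ch)
  # steps: age (p2), prior observation (p3), indication (p4),
  # hospitalization (p5), prior outcome (p6)
  expect_equal(log$excluded[-1], c(0, 1, 1, 1, 1, 1))
  # exclusion counts plus retained equal the candidate pool
  expect_equal(sum(log$excluded[-1]) + nrow(ch), log$remaining[1])
})

test_that("interval edges follow the closed 'on or within' reading", {
  idx <- 400
  # hospitalization exactly 7 days before index excludes; 8 days does not
  db7 <- toy_db(dplyr::bind_rows(toy_person(1, idx), toy_person(2, idx)),
                tibble::tibble(person_id = 1:2,
                               drug_class = c("target", "comparator"),
                               start_date = idx),
                indications = tibble::tibble(person_id = 1:2, date = idx),
                hospitalizations = tibble::tibble(person_id = 1,
                                                  date = idx - 7L))
  expect_setequal(build_cohorts(db7, 60)$person_id, 2)
  db8 <- db7
  db8$hospitalizations$date <- idx - 8L
  expect_setequal(build_cohorts(db8, 60)$person_id, c(1, 2))
  # indication exactly 7 days before index still qualifies
  db_ind <- db7
  db_ind$hospitalizations <- empty_events()
  db_ind$indications <- tibble::tibble(person_id = 1:2, date = idx - 7L)
  expect_setequal(build_cohorts(db_ind, 60)$person_id, c(1, 2))
})

test_that("unknown outcome id is rejected and tar is validated", {
  db <- make_eligibility_db()
  expect_error(build_cohorts(db, 60, outcome_id = 99), "unknown outcome_id")
  expect_error(build_cohorts(db, 45), "tar_days")
})

test_that("survival extraction honors setting, window and censoring", {
  idx <- 400
  persons <- dplyr::bind_rows(
    toy_person(1, idx), toy_person(2, idx), toy_person(3, idx),
    toy_person(4, idx, obs_end = idx + 30), toy_person(5, idx)
  )
  db <- toy_db(
    persons,
    tibble::tibble(person_id = 1:5,
                   drug_class = c("target", "comparator", "target",
                                  "comparator", "target"),
                   start_date = idx),
    indications = tibble::tibble(person_id = 1:5, date = idx),
    outcomes = tibble::tibble(
      person_id = c(1, 2, 5),
      outcome_id = 0L,
      date = c(idx + 61L, idx + 10L, idx),
      setting = c("hospital_or_ed", "other", "hospital_or_ed"))
  )
  ch <- build_cohorts(db, 60)
  sv <- extract_survival(ch, db, 0, 60)
  get <- function(id, col) sv[[col]][sv$person_id == id]
  # event one day past the window: censored at 60
  expect_equal(get(1, "event"), 0L); expect_equal(get(1, "time"), 60)
  # non-qualifying setting never counts as an event
  expect_equal(get(2, "event"), 0L)
  # observation ends at day 30: censored there
  expect_equal(get(4, "time"), 30); expect_equal(get(4, "event"), 0L)
  # index-day event kept with time 0.5
  expect_equal(get(5, "event"), 1L); expect_equal(get(5, "time"), 0.5)
  expect_equal(sv$person_years, sv$time / 365.25)
  # empty cohort is an empty result, not an error
  empty <- ch[0, ]
  expect_equal(nrow(extract_survival(empty, db, 0, 60)), 0)
})

test_that("widening the risk window never shrinks time or events", {
  cfg <- scenario_config(n_databases = 1, n_persons = 2000,
                         n_negative_controls = 2, seed = 17)
  db <- generate_database(cfg, 1)
  ch <- build_cohorts(db, 60)
  tars <- c(30, 60, 90, 365)
  svs <- lapply(tars, function(tar) extract_survival(ch, db, 0, tar))
  for (i in seq_len(length(tars) - 1)) {
    a <- svs[[i]][order(svs[[i]]$person_id), ]
    b <- svs[[i + 1]][order(svs[[i + 1]]$person_id), ]
    expect_true(all(b$time >= a$time))
    expect_true(all(b$event >= a$event))
  }
  # no subject in both arms
  expect_equal(anyDuplicated(ch$person_id), 0L)
})
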