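test_that("the 4-subject closed-form example is reproduced exactly", {
  fit <- fit_cox(four_subject_surv())
  # stationarity condition -x^2 + 2 = 0 gives beta = log(sqrt(2))
  expect_equal(fit$log_hr, log(sqrt(2)), tolerance = 1e-8)
  expect_equal(fit$hr, sqrt(2), tolerance = 1e-8)
  expect_true(fit$estimable)
  # profile peaks at the same point
  pr <- likelihood_profile(four_subject_surv())
  expect_equal(pr$log_hr[which.max(pr$log_lik)], log(sqrt(2)),
               tolerance = (6 / 400))
})

test_that("Newton solution equals brute-force grid maximization on tiny data", {
  set.seed(8)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    surv <- surv_tbl(
      arm = sample(rep(c("target", "comparator"), 3)[1:n]),
      time = sample(1:5, n, replace = TRUE),
      event = rbinom(n, 1, 0.7))
    if (!all(c("target", "comparator") %in% surv$arm)) next
    ev_t <- sum(surv$event[surv$arm == "target"])
    ev_c <- sum(surv$event[surv$arm == "comparator"])
    fit <- fit_cox(surv)
    if (ev_t == 0 || ev_c == 0) {
      expect_false(fit$estimable)
      next
    }
    bf <- naive_cox_mle(surv)
    if (abs(bf) > 3.5) next # maximum effectively at the grid edge
    expect_equal(fit$log_hr, bf, tolerance = 2 * 8 / 8000)
    # and the whole profile agrees with the naive reference, point by point
    pr <- likelihood_profile(surv, c(-2, 2), 401)
    naive <- vapply(pr$log_hr, naive_breslow_loglik, numeric(1), surv = surv)
    expect_equal(pr$log_lik, naive - max(naive), tolerance = 1e-8)
  }
})

test_that("estimates agree with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(33)
  surv <- surv_tbl(
    arm = sample(rep(c("target", "comparator"), 50)),
    time = sample(1:20, 100, replace = TRUE),
    event = rbinom(100, 1, 0.4))
  fit <- fit_cox(surv)
  ref <- survival::coxph(
    survival::Surv(time, event) ~ I(arm == "target"),
    data = surv, ties = "breslow")
  expect_equal(fit$log_hr, unname(ref$coefficients), tolerance = 1e-7)
  expect_equal(fit$se_log_hr, sqrt(unname(ref$var[1, 1])), tolerance = 1e-7)
  # Efron variant agrees with coxph's default ties handling
  fit_e <- fit_cox(surv, ties = "efron")
  ref_e <- survival::coxph(
    survival::Surv(time, event) ~ I(arm == "target"),
    data = surv, ties = "efron")
  expect_equal(fit_e$log_hr, unname(ref_e$coefficients), tolerance = 1e-4)
})

test_that("zero events in one arm gives a one-sided likelihood", {
  surv <- surv_tbl(c("target", "target", "comparator", "comparator"),
                   c(5, 6, 2, 3), c(0, 0, 1, 1))
  fit <- fit_cox(surv)
  expect_false(fit$estimable)
  expect_true(is.na(fit$log_hr))
  pr <- likelihood_profile(surv)
  # no target events: the profile never increases in beta
  expect_true(all(diff(pr$log_lik) <= 1e-12))
})

test_that("null-scenario estimate shrinks toward zero at large n", {
  set.seed(14)
  n <- 50000
  surv <- surv_tbl(
    arm = sample(rep(c("target", "comparator"), n / 2)),
    time = round(rexp(n, 1 / 50) + 1),
    event = rbinom(n, 1, 0.05))
  fit <- fit_cox(surv)
  expect_lt(abs(fit$log_hr), 0.05)
})

test_that("estimate is invariant to id relabeling and time rescaling", {
  set.seed(6)
  surv <- surv_tbl(
    arm = sample(rep(c("target", "comparator"), 30)),
    time = sample(seq(0.5, 30, by = 0.5), 60, replace = TRUE),
    event = rbinom(60, 1, 0.5))
  f1 <- fit_cox(surv)
  shuffled <- surv[sample(nrow(surv)), ]
  shuffled$person_id <- rev(seq_len(nrow(surv)))
  expect_equal(fit_cox(shuffled)$log_hr, f1$log_hr, tolerance = 1e-10)
  scaled <- surv
  scaled$time <- surv$time * 7
  expect_equal(fit_cox(scaled)$log_hr, f1$log_hr, tolerance = 1e-10)
})

test_that("incidence summary is plain event/person-time arithmetic", {
  surv <- tibble::tibble(
    person_id = 1:30,
    arm = rep(c("target", "comparator"), each = 15),
    time = 1, event = c(rep(1L, 10), rep(0L, 5), rep(1L, 5), rep(0L, 10)),
    person_years = rep(500 / 15, 30))
  inc <- incidence_summary(surv)
  expect_equal(inc$rate_t, 20)
  expect_equal(inc$rate_c, 10)
  expect_equal(inc$ard_per_1000py, 10)
  # identical arms: zero rate difference
  same <- surv
  same$event <- rep(c(1L, 0L, 0L), 10)
  expect_equal(incidence_summary(same)$ard_per_1000py, 0)
  expect_error(incidence_summary(surv[0, ]), "empty")
})

test_that("small event counts are masked at the documented boundary", {
  fit <- fit_cox(four_subject_surv())
  fit$events_t <- 4L; fit$events_c <- 5L
  masked <- mask_small_counts(fit)
  expect_equal(masked$events_t_label, "<5")
  expect_equal(masked$events_c_label, "5")
  expect_equal(mask_count(0L), "<5")
  expect_equal(mask_count(c(0L, 4L, 5L, 12L)), c("<5", "<5", "5", "12"))
  # estimation values untouched
  expect_equal(masked$log_hr, fit$log_hr)
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- fit_cox(four_subject_surv())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, fit$log_hr)
  gl <- glance(fit)
  expect_equal(gl$n, 4)
  expect_true(gl$estimable)
})
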