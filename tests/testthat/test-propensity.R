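test_that("preference score matches its defining identity", {
  # P = 0.5 leaves the propensity score unchanged
  expect_equal(preference_score(c(0.2, 0.5, 0.9), 0.5), c(0.2, 0.5, 0.9))
  # ps equal to the prevalence is the equal-likelihood point
  expect_equal(preference_score(0.37, 0.37), 0.5)
  # direct arithmetic: logistic(logit(0.8) - logit(0.6))
  expect_equal(preference_score(0.8, 0.6),
               plogis(qlogis(0.8) - qlogis(0.6)), tolerance = 1e-12)
  expect_equal(round(preference_score(0.8, 0.6), 3), 0.727)
  # strictly monotone in ps at fixed P
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(preference_score(ps, 0.3)) > 0))
  expect_error(preference_score(0, 0.5), "strictly")
  expect_error(preference_score(0.5, 1), "strictly")
})

test_that("SMD reproduces the published worked examples and its algebra", {
  # printed prevalence pairs from the study's baseline table
  expect_equal(round(smd_binary(0.793, 0.842), 2), -0.13)
  expect_equal(round(smd_binary(0.494, 0.457), 2), 0.07)
  expect_equal(round(smd_binary(0.074, 0.060), 2), 0.06)
  # identical arms
  expect_equal(smd_binary(0.3, 0.3), 0)
  # antisymmetry under arm swap
  set.seed(1)
  p <- runif(20, 0.05, 0.95); q <- runif(20, 0.05, 0.95)
  expect_equal(smd_binary(p, q), -smd_binary(q, p))
  # degenerate cases
  expect_equal(compute_smd(0.5, 0.5, 0, 0), 0)
  expect_error(compute_smd(0, 1, 0, 0), "degenerate")
  expect_error(compute_smd(0.5, 0.5, -1, 1), ">= 0")
})

test_that("propensity model recovers structure and rejects bad input", {
  set.seed(42)
  n <- 10000
  x1 <- rbinom(n, 1, 0.3); x2 <- rbinom(n, 1, 0.2)
  covs <- tibble::tibble(
    person_id = c(which(x1 == 1), which(x2 == 1)),
    covariate_id = c(rep(1L, sum(x1)), rep(2L, sum(x2))),
    value = 1L)
  # null assignment: scores carry (almost) no signal
  y0 <- rbinom(n, 1, 0.45)
  m0 <- fit_propensity(covs, which(y0 == 1), which(y0 == 0))
  sc <- m0$scores
  r <- rank(sc$ps); n1 <- sum(sc$arm == "target")
  auc <- (sum(r[sc$arm == "target"]) - n1 * (n1 + 1) / 2) /
    (n1 * (nrow(sc) - n1))
  expect_lte(auc, 0.55)
  # strong single-covariate assignment: sign is recovered
  y1 <- rbinom(n, 1, plogis(-1 + 2.5 * x1))
  m1 <- fit_propensity(covs, which(y1 == 1), which(y1 == 0))
  expect_gt(m1$coefficients[["1"]], 0)
  expect_equal(m1$prevalence, mean(y1))
  # errors
  expect_error(fit_propensity(covs, integer(0), which(y1 == 0)), "non-empty")
  expect_error(fit_propensity(covs, c(1, 2), c(2, 3)), "disjoint")
})

test_that("matching handles the trivial geometries exactly", {
  t_arm <- tibble::tibble(person_id = 1:4, ps = c(0.3, 0.4, 0.5, 0.6))
  c_arm <- tibble::tibble(person_id = 11:14, ps = c(0.3, 0.4, 0.5, 0.6))
  m <- match_1to1(t_arm, c_arm, caliper_sd_mult = 0.2)
  expect_equal(nrow(m), 4)
  expect_equal(sort(m$ps_target), sort(m$ps_comparator))
  # fully separated arms under a tight caliper: nothing matches
  far_t <- tibble::tibble(person_id = 1:3, ps = c(0.91, 0.93, 0.95))
  far_c <- tibble::tibble(person_id = 11:13, ps = c(0.05, 0.07, 0.09))
  expect_equal(nrow(match_1to1(far_t, far_c, 0.2)), 0)
  expect_error(match_1to1(far_t, far_c, -1), ">= 0")
})

test_that("greedy order is deterministic and documented against the optimum", {
  # highest-PS target matches first: 0.60 takes 0.52, leaving 0.70 for 0.50
  t_arm <- tibble::tibble(person_id = 1:2, ps = c(0.50, 0.60))
  c_arm <- tibble::tibble(person_id = 11:12, ps = c(0.52, 0.70))
  m <- match_1to1(t_arm, c_arm, caliper_sd_mult = 100)
  m <- m[order(m$target_id), ]
  expect_equal(m$comparator_id, c(12, 11))
  # exhaustive minimum-total-distance assignment differs here (it pairs
  # 0.60 with 0.70): greedy is by design not globally optimal
  d <- abs(outer(qlogis(t_arm$ps), qlogis(c_arm$ps), "-"))
  greedy_total <- d[2, 1] + d[1, 2]
  optimal_total <- min(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1])
  expect_lt(optimal_total, greedy_total)
})

test_that("matching output always satisfies its structural invariants", {
  for (s in 1:5) {
    set.seed(s)
    t_arm <- tibble::tibble(person_id = 1:40, ps = runif(40, 0.2, 0.8))
    c_arm <- tibble::tibble(person_id = 101:160, ps = runif(60, 0.2, 0.8))
    m <- match_1to1(t_arm, c_arm, 0.2)
    expect_equal(anyDuplicated(m$target_id), 0L)
    expect_equal(anyDuplicated(m$comparator_id), 0L)
    cal <- attr(m, "caliper")
    expect_true(all(abs(qlogis(m$ps_target) - qlogis(m$ps_comparator)) <=
                      cal + 1e-9))
    # reference implementation: naive O(n^2) greedy with the same rules
    lt <- qlogis(t_arm$ps); lc <- qlogis(c_arm$ps)
    used <- logical(60); ref <- integer(0)
    for (ti in order(-t_arm$ps, t_arm$person_id)) {
      dd <- abs(lt[ti] - lc); dd[used] <- Inf
      j <- which(dd == min(dd))[1] # lc has no exact ties under runif
      if (is.finite(dd[j]) && dd[j] <= cal + 1e-12) {
        used[j] <- TRUE
        ref <- rbind(ref, c(t_arm$person_id[ti], c_arm$person_id[j]))
      }
    }
    expect_equal(m$target_id, ref[, 1])
    expect_equal(m$comparator_id, ref[, 2])
  }
})

test_that("balance table isolates and shrinks a measured confounder", {
  cfg <- scenario_config(
    n_databases = 1, n_persons = 8000, n_covariates = 3,
    treatment_model = list(intercept = -0.3, coefs = c(1.5, 0, 0)),
    covariate_hazard_coefs = c(1, 0, 0),
    n_negative_controls = 2, seed = 9)
  db <- generate_database(cfg, 1)
  fe <- run_front_end(db)
  bt <- fe$balance
  conf <- bt[bt$covariate_id == 1, ]
  expect_gt(abs(conf$smd_before), abs(conf$smd_after))
  expect_gt(abs(conf$smd_before), 0.2) # the confounder is visibly imbalanced
  # a covariate absent from both arms has SMD 0
  covs2 <- dplyr::bind_rows(db$covariates,
                            tibble::tibble(person_id = -1L,
                                           covariate_id = 99L, value = 1L))
  bt2 <- balance_table(covs2, fe$cohort, fe$matched)
  expect_equal(bt2$smd_after[bt2$covariate_id == 99], 0)
  expect_equal(bt2$smd_before[bt2$covariate_id == 99], 0)
})

test_that("equipoise fractions count the closed 0.3-0.7 band per arm", {
  expect_equal(unname(equipoise_fraction(rep(0.5, 10), rep(0.5, 4))), c(1, 1))
  expect_equal(unname(equipoise_fraction(rep(0.9, 10), rep(0.9, 4))), c(0, 0))
  expect_equal(unname(equipoise_fraction(c(0.3, 0.7, 0.71), c(0.29, 0.3))),
               c(2 / 3, 1 / 2))
  expect_error(equipoise_fraction(numeric(0), 0.5), "non-empty")
})
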