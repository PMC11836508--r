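# Cox proportional-hazards estimation for a single binary treatment
# covariate, with Breslow handling of ties. For one binary covariate the
# Breslow partial log-likelihood reduces to
#   l(beta) = beta * S - sum_j d_j * log(n1_j * exp(beta) + n0_j)
# over distinct event times j, where d_j is the number of events at time j,
# S the total number of target-arm events, and n1_j / n0_j the at-risk
# counts per arm. Everything downstream (profiles, calibration, pooling)
# consumes this likelihood.

# Risk-set summary: distinct event times with event and at-risk counts.
cox_sufficient_stats <- function(time, event, x) {
  if (any(time <= 0)) stop_bad_arg("survival times must be positive")
  ev <- event == 1L
  ev_t <- time[ev]
  ev_x <- x[ev]
  tj <- sort(unique(ev_t))
  if (length(tj) == 0) {
    return(list(tj = numeric(0), dj = integer(0), sj = integer(0),
                n1 = integer(0), n0 = integer(0), s_total = 0L))
  }
  grp <- match(ev_t, tj)
  dj <- tabulate(grp, length(tj))
  sj <- numeric(length(tj))
  agg <- rowsum(as.numeric(ev_x), grp) # grouped by sorted unique grp values
  sj[sort(unique(grp))] <- agg[, 1]
  t1 <- sort(time[x == 1])
  t0 <- sort(time[x == 0])
  # numeric, not integer: risk-set products appear in the information
  n1 <- as.numeric(length(t1) - findInterval(tj - 1e-9, t1))
  n0 <- as.numeric(length(t0) - findInterval(tj - 1e-9, t0))
  dj <- as.numeric(dj)
  list(tj = tj, dj = dj, sj = sj, n1 = n1, n0 = n0, s_total = sum(sj))
}

cox_loglik <- function(beta, ss, efron = FALSE) {
  vapply(beta, function(b) {
    eb <- exp(b)
    if (!efron) {
      sum(ss$sj) * b - sum(ss$dj * log(ss$n1 * eb + ss$n0))
    } else {
      # Efron's tie correction: average over the tied events' removal order
      tot <- 0
      for (j in seq_along(ss$tj)) {
        d <- ss$dj[j]; s <- ss$sj[j]
        r <- ss$n1[j] * eb + ss$n0[j]
        rd <- s * eb + (d - s)
        l <- (0:(d - 1)) / d
        tot <- tot - sum(log(r - l * rd))
      }
      sum(ss$sj) * b + tot
    }
  }, numeric(1))
}

#' Fit a Cox proportional-hazards model for the treatment effect
#'
#' Newton–Raphson maximization of the Breslow-ties partial likelihood for
#' the single binary treatment covariate (target vs comparator), with the
#' standard error from the observed information, a Wald 95% CI on the HR
#' scale, and a two-sided Wald p-value. When either arm has zero events
#' the likelihood has no interior maximum; the fit is flagged
#' `estimable = FALSE` (point estimate and SE are `NA`) but incidence
#' summaries and a one-sided likelihood profile remain available.
#'
#' @param survival tibble from [extract_survival()]: `arm`, `time`,
#'   `event`, `person_years`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return `hr_fit` object; see [tidy.hr_fit()] and [glance.hr_fit()].
#' @export
#' @examples
#' surv <- tibble::tibble(
#'   person_id = 1:4,
#'   arm = c("target", "comparator", "target", "comparator"),
#'   time = c(1, 2, 3, 3), event = c(1L, 1L, 0L, 0L),
#'   person_years = c(1, 2, 3, 3) / 365.25
#' )
#' fit_cox(surv)$log_hr # log(sqrt(2))
fit_cox <- function(survival, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  arms <- unique(survival$arm)
  if (!all(c("target", "comparator") %in% arms))
    stop_bad_arg("survival records must include both arms")
  x <- as.integer(survival$arm == "target")
  ss <- cox_sufficient_stats(survival$time, survival$event, x)
  inc <- incidence_summary(survival)

  events_t <- inc$events_t
  events_c <- inc$events_c
  estimable <- events_t > 0 && events_c > 0

  log_hr <- NA_real_; se <- NA_real_
  if (estimable) {
    beta <- 0
    for (it in 1:50) {
      eb <- exp(beta)
      den <- ss$n1 * eb + ss$n0
      u <- ss$s_total - sum(ss$dj * ss$n1 * eb / den)
      info <- sum(ss$dj * ss$n1 * ss$n0 * eb / den^2)
      if (info <= 0) { estimable <- FALSE; break }
      step <- u / info
      step <- max(min(step, 2), -2)
      beta <- beta + step
      if (abs(step) < 1e-12) break
    }
    if (ties == "efron") {
      # polish the Breslow solution on the Efron objective by golden search
      obj <- function(b) -cox_loglik(b, ss, efron = TRUE)
      beta <- stats::optimize(obj, c(beta - 1, beta + 1))$minimum
    }
    if (estimable) {
      eb <- exp(beta)
      den <- ss$n1 * eb + ss$n0
      info <- sum(ss$dj * ss$n1 * ss$n0 * eb / den^2)
      log_hr <- beta
      se <- 1 / sqrt(info)
    }
  }

  z <- qnorm(0.975)
  structure(
    list(
      log_hr = log_hr,
      se_log_hr = se,
      hr = exp(log_hr),
      ci_lower = exp(log_hr - z * se),
      ci_upper = exp(log_hr + z * se),
      p = if (estimable) 2 * pnorm(-abs(log_hr / se)) else NA_real_,
      events_t = events_t, events_c = events_c,
      person_years_t = inc$py_t, person_years_c = inc$py_c,
      rate_t = inc$rate_t, rate_c = inc$rate_c,
      ard_per_1000py = inc$ard_per_1000py,
      n_t = sum(x), n_c = sum(1 - x),
      estimable = estimable,
      ties = ties,
      sufficient_stats = ss
    ),
    class = "hr_fit"
  )
}

#' @export
print.hr_fit <- function(x, ...) {
  cat("<hr_fit> Cox (", x$ties, " ties), ", x$n_t, " target / ", x$n_c,
      " comparator subjects\n", sep = "")
  if (x$estimable) {
    cat(sprintf("  HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                x$hr, x$ci_lower, x$ci_upper, x$p))
  } else {
    cat("  not estimable (zero events in at least one arm)\n")
  }
  cat(sprintf("  events %d vs %d; rates %.2f vs %.2f per 1000 PY\n",
              x$events_t, x$events_c, x$rate_t, x$rate_c))
  invisible(x)
}

#' Partial-likelihood profile over a log-HR grid
#'
#' Evaluates the (Breslow) partial log-likelihood on an equally spaced grid
#' of log-HR values and subtracts the maximum. The profile is the
#' non-normal likelihood summary that downstream calibration and
#' meta-analysis consume; between grid points it is interpreted as
#' piecewise linear, and outside the grid as `-Inf`.
#'
#' @param survival survival tibble (both arms).
#' @param grid_bounds log-HR bounds, default `c(-3, 3)` (HR 0.05 to 20).
#' @param n_points grid size, at least 11 (default 401, resolution 0.015).
#' @return `likelihood_profile`: tibble `log_hr`, `log_lik` (max 0) with
#'   the grid bounds as attributes.
#' @export
likelihood_profile <- function(survival, grid_bounds = c(-3, 3),
                               n_points = 401) {
  if (n_points < 11) stop_bad_arg("n_points must be >= 11")
  if (length(grid_bounds) != 2 || grid_bounds[1] >= grid_bounds[2])
    stop_bad_arg("grid_bounds must be an increasing pair")
  x <- as.integer(survival$arm == "target")
  ss <- cox_sufficient_stats(survival$time, survival$event, x)
  grid <- seq(grid_bounds[1], grid_bounds[2], length.out = n_points)
  ll <- if (length(ss$tj) == 0) rep(0, n_points) else cox_loglik(grid, ss)
  new_profile(grid, ll - max(ll))
}

new_profile <- function(grid, loglik) {
  out <- tibble::tibble(log_hr = grid, log_lik = loglik - max(loglik))
  attr(out, "bounds") <- range(grid)
  class(out) <- c("likelihood_profile", class(out))
  out
}

#' Normal approximation as a likelihood profile
#'
#' Builds the quadratic profile `-(x - log_hr)^2 / (2 se^2)` on a grid, the
#' normal-likelihood summary used for already-calibrated estimates.
#'
#' @param log_hr,se point estimate and standard error on the log-HR scale.
#' @inheritParams likelihood_profile
#' @export
profile_from_normal <- function(log_hr, se, grid_bounds = c(-3, 3),
                                n_points = 401) {
  grid <- seq(grid_bounds[1], grid_bounds[2], length.out = n_points)
  new_profile(grid, -(grid - log_hr)^2 / (2 * se^2))
}

# linear interpolation of a profile at arbitrary points; -Inf outside grid
profile_interp <- function(profile, x) {
  grid <- profile$log_hr
  ll <- profile$log_lik
  n <- length(grid)
  lo <- grid[1]; step <- grid[2] - grid[1]
  i <- floor((x - lo) / step) + 1
  out <- rep(-Inf, length(x))
  ok <- i >= 1 & i < n
  w <- (x[ok] - grid[i[ok]]) / step
  out[ok] <- (1 - w) * ll[i[ok]] + w * ll[i[ok] + 1]
  edge <- x == grid[n]
  out[edge] <- ll[n]
  out
}

#' Event and incidence summary per arm
#'
#' Event counts, person-years, incidence rates per 1000 person-years, and
#' the absolute rate difference (target minus comparator).
#'
#' @param survival survival tibble.
#' @return one-row tibble: `events_t`, `events_c`, `py_t`, `py_c`,
#'   `rate_t`, `rate_c`, `ard_per_1000py`.
#' @export
incidence_summary <- function(survival) {
  if (nrow(survival) == 0) stop_bad_arg("empty survival set")
  x <- survival$arm == "target"
  py_t <- sum(survival$person_years[x])
  py_c <- sum(survival$person_years[!x])
  if (py_t <= 0 || py_c <= 0) stop_bad_arg("zero person-years in an arm")
  events_t <- sum(survival$event[x])
  events_c <- sum(survival$event[!x])
  rate_t <- events_t / py_t * 1000
  rate_c <- events_c / py_c * 1000
  tibble::tibble(events_t = events_t, events_c = events_c,
                 py_t = py_t, py_c = py_c,
                 rate_t = rate_t, rate_c = rate_c,
                 ard_per_1000py = rate_t - rate_c)
}

#' Small-cell masking for reporting
#'
#' Event counts below `min_cell` are reported as `"<5"` (or the analogous
#' sentinel for another threshold) to protect privacy in emitted tables;
#' estimation results themselves are never altered.
#'
#' @param result an `hr_fit`.
#' @param min_cell minimum reportable count (default 5; `events = 5` is
#'   reported exactly, `events = 4` is masked).
#' @return the `hr_fit` with character fields `events_t_label`,
#'   `events_c_label` added.
#' @export
mask_small_counts <- function(result, min_cell = 5) {
  result$events_t_label <- mask_count(result$events_t, min_cell)
  result$events_c_label <- mask_count(result$events_c, min_cell)
  result$min_cell <- min_cell
  result
}

#' @rdname mask_small_counts
#' @param x integer count vector.
#' @export
mask_count <- function(x, min_cell = 5) {
  ifelse(x < min_cell, paste0("<", min_cell), as.character(x))
}
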