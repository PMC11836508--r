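#' Fit the large-scale regularized propensity model
#'
#' Penalized (lasso) logistic regression of membership in the target arm on
#' the full set of binary baseline covariates, the standard outcome-blind
#' propensity model for high-dimensional observational data. The intercept
#' is never penalized. With `reg_strength = "cv"` the penalty is chosen by
#' 10-fold cross-validated binomial deviance.
#'
#' @param covariates long sparse covariate tibble (`person_id`,
#'   `covariate_id`, 1-entries only); persons absent from the table have
#'   all covariates zero.
#' @param target_ids,comparator_ids person ids of the two arms (disjoint,
#'   non-empty).
#' @param reg_strength `"cv"` (default) or a non-negative lambda.
#' @return `propensity_model`: coefficients, intercept, lambda, the
#'   training-set target-arm prevalence `prevalence`, and per-person scores
#'   in `$scores` (tibble `person_id`, `arm`, `ps`).
#' @export
fit_propensity <- function(covariates, target_ids, comparator_ids,
                           reg_strength = "cv") {
  target_ids <- unique(target_ids)
  comparator_ids <- unique(comparator_ids)
  if (length(target_ids) == 0 || length(comparator_ids) == 0)
    stop_bad_arg("both arms must be non-empty")
  if (length(intersect(target_ids, comparator_ids)) > 0)
    stop_bad_arg("arms must be disjoint")

  ids <- c(target_ids, comparator_ids)
  y <- c(rep(1L, length(target_ids)), rep(0L, length(comparator_ids)))
  cov <- dplyr::filter(covariates, .data$person_id %in% ids)
  cov_levels <- sort(unique(covariates$covariate_id))
  row_of <- match(cov$person_id, ids)
  col_of <- match(cov$covariate_id, cov_levels)
  x <- Matrix::sparseMatrix(i = row_of, j = col_of, x = 1,
                            dims = c(length(ids), length(cov_levels)))
  colnames(x) <- as.character(cov_levels)

  if (identical(reg_strength, "cv")) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1, nfolds = 10)
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
  } else {
    if (!is.numeric(reg_strength) || reg_strength < 0)
      stop_bad_arg("reg_strength must be \"cv\" or a non-negative number")
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = reg_strength)
    lambda <- reg_strength
  }
  beta <- as.numeric(stats::coef(fit, s = lambda))
  if (any(!is.finite(beta)) || max(abs(beta[-1])) > 25)
    stop_bad_arg(paste0("propensity coefficients diverged (likely complete ",
                        "separation); use a positive reg_strength"))
  lp <- as.numeric(beta[1] + x %*% beta[-1])
  scores <- tibble::tibble(
    person_id = ids,
    arm = ifelse(y == 1L, "target", "comparator"),
    ps = expit(lp)
  )
  structure(
    list(intercept = beta[1],
         coefficients = stats::setNames(beta[-1], colnames(x)),
         lambda = lambda,
         prevalence = mean(y),
         scores = scores),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("<propensity_model> lasso logistic, lambda = ",
      signif(x$lambda, 3), "\n", sep = "")
  cat("  covariates: ", length(x$coefficients), " (", nz, " non-zero)\n",
      sep = "")
  cat("  target-arm prevalence: ", round(x$prevalence, 3), "\n", sep = "")
  invisible(x)
}

#' Preference score
#'
#' Transforms a propensity score to remove the effect of overall exposure
#' prevalence: `logit(F) = logit(ps) - logit(P)`. A preference score of 0.5
#' means the person was equally likely to receive either drug; values near
#' 0 or 1 indicate strong channeling.
#'
#' @param ps propensity score(s) in (0, 1).
#' @param prevalence target-arm prevalence `P` in (0, 1), normally the
#'   pre-matching prevalence stored on the [fit_propensity()] model.
#' @return preference score(s) in (0, 1); strictly increasing in `ps`,
#'   equal to `ps` when `P = 0.5`.
#' @export
#' @examples
#' preference_score(0.8, 0.6) # ~0.727
preference_score <- function(ps, prevalence) {
  if (any(ps <= 0 | ps >= 1)) stop_bad_arg("ps must lie strictly in (0, 1)")
  if (length(prevalence) != 1 || prevalence <= 0 || prevalence >= 1)
    stop_bad_arg("prevalence must be a single value strictly in (0, 1)")
  expit(logit(ps) - logit(prevalence))
}

#' Greedy 1:1 propensity matching on the logit scale
#'
#' Nearest-neighbor matching without replacement on `logit(ps)`, processing
#' target subjects in order of descending propensity score (ties broken by
#' lower person id); a comparator is eligible if within the caliper,
#' `caliper_sd_mult` times the SD of `logit(ps)` in the pooled sample.
#' Equidistant comparators resolve to the lower person id, so the result is
#' fully deterministic.
#'
#' @param target,comparator tibbles with `person_id` and `ps`.
#' @param caliper_sd_mult non-negative caliper width in pooled-SD units
#'   (default 0.2, the conventional choice).
#' @return `matched_cohort`: tibble of pairs (`target_id`, `comparator_id`,
#'   `ps_target`, `ps_comparator`) with the caliper used attached as
#'   attributes `caliper` and `caliper_sd_mult`.
#' @export
match_1to1 <- function(target, comparator, caliper_sd_mult = 0.2) {
  if (caliper_sd_mult < 0) stop_bad_arg("caliper_sd_mult must be >= 0")
  if (nrow(target) == 0 || nrow(comparator) == 0)
    stop_bad_arg("both arms must be non-empty")

  lt <- logit(pmin(pmax(target$ps, 1e-12), 1 - 1e-12))
  lc <- logit(pmin(pmax(comparator$ps, 1e-12), 1 - 1e-12))
  pooled_sd <- sd(c(lt, lc))
  if (!is.finite(pooled_sd)) pooled_sd <- 0
  caliper <- caliper_sd_mult * pooled_sd

  t_ord <- order(-target$ps, target$person_id)
  c_ord <- order(lc, comparator$person_id)
  c_lps <- lc[c_ord]
  c_ids <- comparator$person_id[c_ord]
  c_ps <- comparator$ps[c_ord]
  m <- length(c_lps)
  # skip pointers (with path compression) over consumed comparators:
  # nxt_right[i] = first unconsumed position >= i; nxt_left[i+1] likewise <= i
  nxt_right <- seq_len(m + 1L)
  nxt_left <- 0:m
  find_right <- function(i) {
    j <- i
    while (j <= m && nxt_right[j] != j) j <- nxt_right[j]
    k <- i
    while (k <= m && nxt_right[k] != k) { tmp <- nxt_right[k]; nxt_right[k] <<- j; k <- tmp }
    j
  }
  find_left <- function(i) {
    j <- i
    while (j >= 1L && nxt_left[j + 1L] != j) j <- nxt_left[j + 1L]
    k <- i
    while (k >= 1L && nxt_left[k + 1L] != k) { tmp <- nxt_left[k + 1L]; nxt_left[k + 1L] <<- j; k <- tmp }
    j
  }

  cap <- length(t_ord)
  pair_t <- integer(cap); pair_c <- integer(cap)
  np <- 0L
  for (ti in t_ord) {
    v <- lt[ti]
    pos <- findInterval(v, c_lps)
    li <- find_left(min(pos, m))
    ri <- find_right(pos + 1L)
    dl <- if (li >= 1L) abs(v - c_lps[li]) else Inf
    dr <- if (ri <= m) abs(v - c_lps[ri]) else Inf
    pick <- NA_integer_
    if (is.finite(dl) && is.finite(dr) && abs(dl - dr) < 1e-12) {
      pick <- if (c_ids[li] <= c_ids[ri]) li else ri
    } else if (dl < dr) {
      pick <- li
    } else if (is.finite(dr)) {
      pick <- ri
    }
    if (!is.na(pick) && abs(v - c_lps[pick]) <= caliper + 1e-12) {
      np <- np + 1L
      pair_t[np] <- ti; pair_c[np] <- pick
      nxt_right[pick] <- pick + 1L
      nxt_left[pick + 1L] <- pick - 1L
    }
  }
  pair_t <- pair_t[seq_len(np)]; pair_c <- pair_c[seq_len(np)]
  out <- tibble::tibble(
    target_id = target$person_id[pair_t],
    comparator_id = c_ids[pair_c],
    ps_target = target$ps[pair_t],
    ps_comparator = c_ps[pair_c]
  )
  attr(out, "caliper") <- caliper
  attr(out, "caliper_sd_mult") <- caliper_sd_mult
  attr(out, "scale") <- "logit(ps)"
  class(out) <- c("matched_cohort", class(out))
  out
}

#' Standardized difference of the mean
#'
#' `(mean_t - mean_c) / sqrt((var_t + var_c) / 2)`. For a binary covariate
#' pass the prevalences and their Bernoulli variances `p (1 - p)` (the
#' helper [smd_binary()] does this). Sign convention: target minus
#' comparator. Vectorized.
#'
#' @param mean_t,mean_c per-arm means (prevalences for binary covariates).
#' @param var_t,var_c per-arm variances (>= 0, not both zero unless the
#'   means agree, in which case the SMD is defined as 0).
#' @return SMD value(s).
#' @export
#' @examples
#' smd_binary(0.793, 0.842) # Female row: -0.13 at two decimals
compute_smd <- function(mean_t, mean_c, var_t, var_c) {
  if (any(var_t < 0 | var_c < 0)) stop_bad_arg("variances must be >= 0")
  zero <- (var_t + var_c) == 0
  if (any(zero & mean_t != mean_c))
    stop_bad_arg("degenerate SMD: both variances zero but means differ")
  out <- numeric(length(zero))
  out[zero] <- 0
  nz <- !zero
  out[nz] <- (mean_t[nz] - mean_c[nz]) / sqrt((var_t[nz] + var_c[nz]) / 2)
  out
}

#' @rdname compute_smd
#' @param p_t,p_c binary-covariate prevalences.
#' @export
smd_binary <- function(p_t, p_c) {
  compute_smd(p_t, p_c, p_t * (1 - p_t), p_c * (1 - p_c))
}

#' Covariate balance before and after matching
#'
#' Prevalence of every covariate in each arm, before matching (the full
#' eligible cohorts) and after matching (the matched subjects), with the
#' binary-covariate SMD at both stages. Covariates absent from an arm have
#' prevalence 0; a covariate absent everywhere has SMD 0.
#'
#' @param covariates long sparse covariate tibble.
#' @param cohort pre-matching cohort tibble (from [build_cohorts()]).
#' @param matched a [match_1to1()] result.
#' @return `balance_table` tibble: `covariate_id`, `mean_t_before`,
#'   `mean_c_before`, `smd_before`, `mean_t_after`, `mean_c_after`,
#'   `smd_after`; `max(abs(smd_after))` is attached as attribute
#'   `max_abs_smd_after`.
#' @export
balance_table <- function(covariates, cohort, matched) {
  groups <- list(
    t_before = cohort$person_id[cohort$arm == "target"],
    c_before = cohort$person_id[cohort$arm == "comparator"],
    t_after = matched$target_id,
    c_after = matched$comparator_id
  )
  cov_ids <- sort(unique(covariates$covariate_id))
  prev_in <- function(ids) {
    cnt <- covariates |>
      dplyr::filter(.data$person_id %in% ids) |>
      dplyr::count(.data$covariate_id)
    p <- stats::setNames(rep(0, length(cov_ids)), cov_ids)
    p[as.character(cnt$covariate_id)] <- cnt$n / length(ids)
    p
  }
  p <- lapply(groups, prev_in)
  out <- tibble::tibble(
    covariate_id = cov_ids,
    mean_t_before = unname(p$t_before),
    mean_c_before = unname(p$c_before),
    smd_before = smd_binary(unname(p$t_before), unname(p$c_before)),
    mean_t_after = unname(p$t_after),
    mean_c_after = unname(p$c_after),
    smd_after = smd_binary(unname(p$t_after), unname(p$c_after))
  )
  attr(out, "max_abs_smd_after") <- max(abs(out$smd_after))
  class(out) <- c("balance_table", class(out))
  out
}

#' Empirical-equipoise fractions
#'
#' Per-arm proportion of subjects with a preference score in the closed
#' interval `[0.3, 0.7]`. The study design calls equipoise sufficient when
#' both fractions exceed 0.2.
#'
#' @param pref_t,pref_c preference scores per arm, values in (0, 1).
#' @return named numeric: `target`, `comparator`.
#' @export
equipoise_fraction <- function(pref_t, pref_c) {
  if (length(pref_t) == 0 || length(pref_c) == 0)
    stop_bad_arg("both arms must be non-empty")
  c(target = mean(pref_t >= 0.3 & pref_t <= 0.7),
    comparator = mean(pref_c >= 0.3 & pref_c <= 0.7))
}
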