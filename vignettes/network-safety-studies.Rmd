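---
title: "Methods: comparative-safety cohort studies across database networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative-safety cohort studies across database networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

netcohort implements, end to end, the analysis chain of a distributed
active-comparator new-user cohort study: the design used when a drug
safety question (does drug A raise the risk of a rare outcome relative to
a clinically interchangeable drug B?) must be answered from routinely
collected data spread across many heterogeneous databases, none of which
can share patient-level records. This vignette describes the statistical
machinery, the assumptions behind each stage, and the design decisions
taken where the method family leaves room.

```{r setup}
library(netcohort)
```

## The estimand and the design

Each database contributes a hazard ratio (HR) for first-ever users of the
target drug versus first-ever users of an active comparator, both treated
for the same indication, with follow-up restricted to a fixed time-at-risk
(TAR) window after treatment initiation (the index date). The new-user,
active-comparator design is the field's standard defense against
prevalent-user bias and confounding by indication: both arms consist of
patients sick enough to be treated, observed from the moment therapy
starts.

Eligibility is applied in a fixed order, with per-step attrition logged:
first use of any study drug defines candidacy (patients qualifying for
both arms on the same day are excluded); age at least 35 years at index;
at least 365 days of observation before index; an indication record on the
index day or the 7 days before it; no hospitalization in that same window;
and no event of the analyzed outcome in the 365 days before index. "On or
within 7 days prior" is read as the closed 8-day interval including the
index day. Follow-up is intent-to-treat from index to the first qualifying
outcome event, the end of the TAR window, or the end of observation.
Events on the index day itself are retained with the survival time set to
0.5 day, a documented constant that keeps all times positive for the
partial likelihood.

## Propensity scores, matching, and balance

Within each database the probability of receiving the target drug given
baseline covariates (the propensity score, PS) is fit by lasso-penalized
logistic regression over the full covariate set, with the penalty chosen
by 10-fold cross-validated deviance unless a fixed value is supplied; the
intercept is never penalized. The outcome plays no role in this model.

Arms are matched 1:1 by greedy nearest-neighbor matching without
replacement on logit(PS), processing target subjects in descending PS
order with ties broken by lower person id, under a caliper of 0.2 pooled
standard deviations of logit(PS). The caliper width is the conventional
default in the PS-matching literature and is exposed as configuration;
greedy order and tie-breaks are fixed so the match is reproducible.
Greedy matching is deliberately not globally optimal: the test suite
documents a 2x2 instance where the exhaustive minimum-distance assignment
differs from the greedy result.

Balance is summarized per covariate by the standardized difference of the
mean, `(p_t - p_c) / sqrt((p_t(1-p_t) + p_c(1-p_c))/2)` for binary
covariates, computed before and after matching with the sign convention
target minus comparator. Preference scores remove the effect of overall
exposure prevalence, `logit(F) = logit(PS) - logit(P)`, with `P` taken
from the pre-matching eligible population, because equipoise is a
pre-matching diagnostic of whether clinicians genuinely chose between the
two drugs.

## Estimation

The treatment effect in each database is estimated by a Cox proportional
hazards model with the single binary treatment covariate, maximizing the
Breslow-ties partial likelihood by Newton-Raphson (Efron's correction is
available behind a flag; ties are sparse in the simulated continuous-time
data, and Breslow is the variant that can be verified by hand). The model
is fit unconditionally on the matched set, without pair stratification.
Standard errors come from the observed information; confidence intervals
and p-values are Wald-based, deliberately, because the calibration stage
models normal random error.

Every fit also records the partial log-likelihood on an equally spaced
grid of log-HR values (default 401 points on [-3, 3], i.e. HR 0.05 to 20
at resolution 0.015), max-normalized, interpreted as piecewise linear
between points and minus infinity outside the grid. These profiles, not
normal approximations, are what downstream pooling consumes: when one arm
has zero events the Wald machinery collapses (`estimable = FALSE`), but
the one-sided profile still carries the evidence.

Incidence summaries report events, person-years, rates per 1000
person-years, and the absolute rate difference. Event counts below a
reporting threshold (default 5) are masked as "<5" in emitted tables;
estimates themselves are never altered.

## Empirical calibration and EASE

Negative-control outcomes — outcomes believed causally unrelated to either
drug, so their true HR is 1 — measure residual systematic error. Their
estimates are modeled as `beta_i ~ Normal(mu, sigma^2 + tau_i^2)`, where
`(mu, sigma)` is the systematic-error distribution shared by all outcomes
of a database-comparison analysis and `tau_i` is the control's own
standard error. The pair is fit by maximum likelihood under the constraint
`sigma >= 0` (L-BFGS-B with analytic gradient); controls with zero events
in either arm are excluded and counted.

Calibration subtracts `mu` and adds `sigma^2` to the variance: calibrated
p-values are `2 Phi(-|beta - mu| / sqrt(sigma^2 + tau^2))` and calibrated
intervals are `(beta - mu) +/- z sqrt(sigma^2 + tau^2)` on the log scale.
The expected absolute systematic error (EASE) is `E|X|` for
`X ~ Normal(mu, sigma^2)`, available in closed form and reducing to `|mu|`
at `sigma = 0`.

For pooling, calibrated *profiles* are produced by marginalizing the bias
term out of the likelihood: `L_cal(theta) = integral L(theta + b)
phi(b; mu, sigma^2) db`, evaluated by quadrature on the profile's own
grid. For a near-quadratic profile this reproduces shift-and-widen
calibration; for a zero-event profile it remains honest where no normal
approximation exists. Estimation uncertainty in `(mu, sigma)` is not
propagated into calibrated intervals: the fit uses all available controls
and stays deterministic. The package default fits the null on all
controls; the coverage experiment in the acceptance suite uses the
leave-one-out convention (each control calibrated against a null fitted on
the remaining controls) so that a control never certifies itself.

## Objective diagnostics and gating

Three pre-registered checks decide whether a database-comparison analysis
may enter evidence synthesis, each at a strict inequality: maximum
absolute post-matching SMD below 0.1 across all covariates; more than 20%
of subjects in *both* arms with preference scores in [0.3, 0.7]; and EASE
below 0.25. Values exactly at a threshold fail, following the "less than"
/ "greater than" wording of the thresholds. A missing input marks the
check not-evaluable and fails the analysis. Only analyses passing all
three are pooled; exclusions are reported with the diagnostics that
failed. In the synthetic setting the balance check applies to every
generated covariate, the natural analogue of a pre-defined covariate set.

## Bayesian evidence synthesis

Gated databases are pooled with a random-effects model: per-database
log-HRs `beta_d ~ Normal(theta, tau^2)`, each database's data entering
through its (calibrated) likelihood profile. Priors are weakly informative
on the log-HR scale: `theta ~ Normal(0, 2^2)` and `tau ~ half-Normal(0,
0.5^2)`; both are configuration, and the source publications of this
method family do not pin them down, so they are stated here as package
decisions. Sampling is Metropolis-within-Gibbs: a conjugate Gibbs draw for
`theta`, random-walk Metropolis on each `beta_d` (proposal scale from the
profile curvature, with an occasional five-fold step so flat one-sided
profiles are traversed) and on `log(tau)`, plus a joint translation move
of `theta` and all `beta_d` together. Default 10,000 iterations with
1,000 burn-in, fully determined by the configured seed. The reported 95%
interval is the equal-tailed credible interval.

Two structural choices: with a single database, `tau` is fixed at 0, since
one site cannot identify between-database heterogeneity — the result is
then that profile's own posterior under the priors; and setting the
`tau` prior SD to 0 yields fixed-effect pooling, which the tests verify
against inverse-variance weighting. The sampler itself is verified
against a 2-D grid-quadrature oracle over `(theta, tau)`.

## The synthetic data generator

The generator produces networks of databases with known ground truth so
that every downstream stage is testable without access to real data. Per
database: persons with observation windows on an integer day axis; binary
covariates drawn independently at database-specific prevalences (uniform
on [0.02, 0.3] by default); one exposure episode per person with drug
class assigned by a logistic model; indication records placed within 7
days before index for 90% of persons; hospitalizations for 15%; and
first-event times per outcome from piecewise-exponential hazards —
baseline times covariate effects before index, multiplied after index (in
the target arm) by the true effect (primary outcome only) and by a
per-outcome ascertainment-bias term `exp(b_k)`, `b_k ~ Normal(bias_mean,
bias_sd^2)` drawn once per outcome for the whole network. Drawing the bias
once network-wide is what makes the injected error *systematic* — exactly
the correlated component EASE is designed to detect. An optional
unmeasured confounder raises both treatment odds and every outcome's
hazard and never appears in the covariate table. 90% of events carry the
qualifying hospital/ED setting, exercising the outcome-setting filter.

Default study conditions: 14 databases of 20,000 persons, 20 covariates
shifting treatment log-odds and outcome log-hazard by 0.3 each, baseline
hazard 1e-4 per person-day, 50 negative controls, treatment-model
intercept -1.2. The intercept deserves a comment: it puts the target arm
at roughly 43% of the eligible population, leaving an adequate comparator
reservoir so that 1:1 greedy matching can actually achieve balance, and
produces equipoise fractions around 0.9 — the regime of a database whose
analysis is *valid* under the study's own diagnostics. When the majority
arm is the target instead, greedy matching without replacement exhausts
the comparator pool from below and leaves a systematic matched-pair gap
that fails the balance diagnostic; that scarce-comparator regime (like
databases with injected bias or poor overlap) is deliberately reachable
through `intercept_range`, `bias_mean`/`bias_sd` and
`unmeasured_confounder`, and is exercised in the diagnostics-failure
tests rather than baked into the default.

What the generator does not emulate, and what passing tests therefore do
not establish about real data: covariates are independent Bernoulli draws
(real claims covariates are strongly correlated and number in the tens of
thousands); exposure is a single episode with no discontinuation,
switching, or dose; outcome hazards are constant within each period
(proportional hazards holds by construction); and code-based phenotype
error is reduced to a single ascertainment-bias multiplier and a
qualifying-setting flag. The pipeline's behavior under violations of
proportional hazards or under informative censoring is untested here.

## Problem sizes and numerical choices

The test and acceptance experiments use deliberately chosen scales: the
diagnostic-bound scenarios run one database of 20,000 persons with 50
controls; the coverage experiment runs 5 databases of 10,000 persons with
1,000 true-null controls, leave-one-out nulls, and pooling at 2,500
iterations (500 burn-in) per control — with 1,000 controls the per-control
Monte-Carlo error of a 95% interval averages out of the coverage
percentage; the recovery experiment runs 20 end-to-end studies of 5
databases at 8,000 persons with a true HR of 1.5. Newton-Raphson uses
step clamping at +/-2 and converges at |step| < 1e-12; the empirical-null
optimizer runs L-BFGS-B on `(mu, sigma)` with `sigma in [0, 10]`;
profile-likelihood interpolation is piecewise linear with -Inf outside
the grid. All randomness flows from named substreams of a master seed, so
identical configurations give byte-identical outputs, including the
written report files.

## Known limitations

Per-database cohorts and matches are built once against the primary
outcome's washout; each negative control then applies its own 365-day
prior-event exclusion on the matched set, mirroring how control estimates
share the main analysis' exposure cohorts. Calibrated intervals treat
`(mu, sigma)` as known. The synthetic network has exactly one comparator
class, so a two-comparator study is represented as two configured runs.
Cox fits are unstratified on the matched pairs; a within-pair stratified
variant would be a natural extension. Confidence in the pipeline on real
OMOP-mapped data would additionally require vocabulary handling,
phenotype validation, and correlated high-dimensional covariates, all out
of scope here.
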