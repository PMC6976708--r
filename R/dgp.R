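# Synthetic cohort generator: covariates, Bernoulli treatment assignment on a
# logistic propensity, Weibull survival by inverse-probability transform with
# common random numbers across the two treatment arms, and an independent
# Bernoulli censoring status.

#' Generate baseline covariates
#'
#' Ten covariate columns, by default independent standard normal draws
#' (continuous covariates give smooth propensity overlap); a Bernoulli(0.5)
#' alternative is available for sensitivity checks.
#'
#' @param n number of subjects (>= 1).
#' @param seed optional RNG seed.
#' @param dist `"normal"` (default) or `"bernoulli"`.
#' @return an `n x 10` numeric matrix with columns `x1`..`x10`.
#' @export
generate_covariates <- function(n, seed = NULL, dist = c("normal", "bernoulli")) {
  dist <- match.arg(dist)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    sg_stop("`n` must be a positive count", "sgmatch_bad_n")
  }
  n <- as.integer(n)
  X <- with_seed(seed, switch(dist,
    normal    = matrix(stats::rnorm(n * 10L), n, 10L),
    bernoulli = matrix(stats::rbinom(n * 10L, 1L, 0.5), n, 10L)))
  colnames(X) <- paste0("x", 1:10)
  X
}

#' Assign treatment from the logistic propensity model
#'
#' The true propensity is `plogis(intercept + X[,1:7] %*% treat_coeffs)` and
#' treatment is a Bernoulli draw on it: covariates X1--X7 drive selection.
#'
#' @param X covariate matrix from [generate_covariates()].
#' @param scenario a `"het_scenario"`; its `treat_intercept` is used as is.
#' @param seed optional RNG seed.
#' @return list with `p_true` (true propensity, in (0,1)) and `z` (0/1 vector).
#' @export
assign_treatment <- function(X, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "het_scenario"), is.matrix(X), ncol(X) >= 7L)
  p <- stats::plogis(scenario$treat_intercept +
                       drop(X[, 1:7, drop = FALSE] %*% scenario$treat_coeffs))
  z <- with_seed(seed, stats::rbinom(nrow(X), 1L, p))
  list(p_true = p, z = z)
}

# Inverse-probability transform of the Weibull survival model with shape 2:
# S(t) = exp(-lambda * exp(LP) * t^2), so t = (-log(u) / (lambda e^LP))^(1/2).
# Strictly decreasing in both u (at fixed LP) and LP (at fixed u).
weibull_os <- function(u, lp, lambda) {
  sqrt(-log(u) / (lambda * exp(lp)))
}

#' Generate potential survival outcomes by Weibull inversion
#'
#' For each subject one uniform draw `u` is shared between the two treatment
#' arms (common random numbers), and overall survival under arm `z` is
#' `OS_z = (-log(u) / (lambda * exp(LP_z)))^(1/2)` with linear predictor
#' `LP_z = beta_treat * z + X[,4:10] %*% outcome_coeffs`. Sharing `u` makes the
#' per-subject counterfactual contrast well defined: the ratio `OS1/OS0`
#' collapses to `exp(-beta_treat/2)` exactly, and the subject-specific true
#' survival gain is `SG = OS1 - OS0` (strictly positive when `beta_treat < 0`).
#'
#' @param X covariate matrix (columns x4..x10 used).
#' @param z 0/1 treatment vector, length `nrow(X)`.
#' @param scenario a `"het_scenario"`.
#' @param lambda Weibull scale of the baseline hazard (default 2e-5).
#' @param seed optional RNG seed.
#' @return list with `os1`, `os0`, `os_obs` (factual arm) and `sg_true`
#'   (months; computed for every subject, meaningful for the treated).
#' @export
generate_survival <- function(X, z, scenario, lambda = 2e-5, seed = NULL) {
  stopifnot(inherits(scenario, "het_scenario"), is.matrix(X), ncol(X) >= 10L,
            length(z) == nrow(X), all(z %in% c(0, 1)), lambda > 0)
  lp0 <- drop(X[, 4:10, drop = FALSE] %*% scenario$outcome_coeffs)
  u <- with_seed(seed, stats::runif(nrow(X)))
  os0 <- weibull_os(u, lp0, lambda)
  os1 <- weibull_os(u, lp0 + scenario$beta_treat, lambda)
  list(os1 = os1, os0 = os0,
       os_obs = ifelse(z == 1, os1, os0),
       sg_true = os1 - os0)
}

#' Draw independent censoring status flags
#'
#' Censoring is a status flag only (1 = censored, 0 = observed), drawn
#' Bernoulli(`p_star`) independently of survival and treatment. Recorded OS
#' values are not truncated; downstream a censored OS is read as a lower
#' bound on the true survival time.
#'
#' @param n number of subjects.
#' @param p_star censoring probability in \[0, 1\].
#' @param seed optional RNG seed.
#' @return integer 0/1 vector of length `n`.
#' @export
apply_censoring <- function(n, p_star, seed = NULL) {
  if (!is.numeric(p_star) || length(p_star) != 1L || is.na(p_star) ||
      p_star < 0 || p_star > 1) {
    sg_stop("`p_star` must lie in [0, 1]", "sgmatch_bad_pstar")
  }
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  with_seed(seed, stats::rbinom(as.integer(n), 1L, p_star))
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the full data-generating process: covariates, treatment
#' assignment, potential outcomes, factual OS and censoring status, with the
#' per-subject ground truth (both potential outcomes, true survival gain and
#' true propensity) kept alongside. All draws come from a single stream
#' seeded once, so a given `seed` reproduces the cohort bit for bit.
#'
#' @param n cohort size (default 1000).
#' @param scenario a `"het_scenario"` or a level name passed to
#'   [make_scenario()].
#' @param prop_treated optional target expected treated proportion; when given,
#'   the treatment intercept is calibrated with [calibrate_intercept()]
#'   (overriding the scenario's stored intercept).
#' @param p_censor censoring probability (default 0).
#' @param seed optional RNG seed for the whole cohort.
#' @param lambda Weibull scale (default 2e-5).
#' @param covariate_dist passed to [generate_covariates()].
#' @param n_calib calibration sample size when `prop_treated` is given.
#' @return a `data.frame` of class `"sg_cohort"` with columns `id`, `z`,
#'   `os_months`, `censored`, `os1`, `os0`, `sg_true`, `ps_true`, `x1`..`x10`,
#'   and attributes `scenario` and `lambda`.
#' @examples
#' coh <- simulate_cohort(200, "low", prop_treated = 0.3, p_censor = 0.2,
#'                        seed = 42, n_calib = 5000)
#' table(coh$z)
#' @export
simulate_cohort <- function(n = 1000, scenario = "medium", prop_treated = NULL,
                            p_censor = 0, seed = NULL, lambda = 2e-5,
                            covariate_dist = c("normal", "bernoulli"),
                            n_calib = 100000L) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  stopifnot(inherits(scenario, "het_scenario"))
  covariate_dist <- match.arg(covariate_dist)
  with_seed(seed, {
    if (!is.null(prop_treated)) {
      scenario$treat_intercept <- calibrate_intercept(
        scenario, prop_treated, n_calib = n_calib, covariate_dist = covariate_dist)
    }
    X <- generate_covariates(n, dist = covariate_dist)
    trt <- assign_treatment(X, scenario)
    srv <- generate_survival(X, trt$z, scenario, lambda = lambda)
    cens <- apply_censoring(n, p_censor)
    coh <- data.frame(id = seq_len(n), z = trt$z, os_months = srv$os_obs,
                      censored = cens, os1 = srv$os1, os0 = srv$os0,
                      sg_true = srv$sg_true, ps_true = trt$p_true)
    coh <- cbind(coh, as.data.frame(X))
    attr(coh, "scenario") <- scenario
    attr(coh, "lambda") <- lambda
    class(coh) <- c("sg_cohort", "data.frame")
    coh
  })
}

#' Ground-truth effect summary of a simulated cohort
#'
#' The "true ATE" is the mean true survival gain over treated subjects and
#' the "true variance" V is the sample variance of the true gains over the
#' same subjects; V is the benchmark the matched-set variance estimators are
#' judged against.
#'
#' @param cohort an `"sg_cohort"` (needs `sg_true`; at least 2 treated).
#' @return list with `true_ate` (months) and `true_variance` (months^2).
#' @export
truth_summary <- function(cohort) {
  d <- as.data.frame(cohort)
  if (is.null(d$sg_true)) sg_stop("cohort has no `sg_true` column", "sgmatch_no_truth")
  sg <- d$sg_true[d$z == 1]
  if (length(sg) < 2L) {
    sg_stop("need at least 2 treated subjects for a truth summary",
            "sgmatch_too_few_treated")
  }
  list(true_ate = mean(sg), true_variance = stats::var(sg))
}
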