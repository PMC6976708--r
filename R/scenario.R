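#' Heterogeneity scenarios for the synthetic cohort generator
#'
#' A scenario bundles the regression coefficients that control how strongly
#' the ten baseline covariates drive treatment selection (X1--X7, via a
#' logistic model) and overall survival (X4--X10, via the Weibull linear
#' predictor). Effect sizes are drawn from a five-point ladder of log odds /
#' log hazard ratios: very weak log(1.25), weak log(1.5), moderate log(2),
#' strong log(4) and very strong log(8). The three named levels reproduce
#' increasing confounding intensity:
#'
#' * `low`: mostly very weak/weak effects, one moderate on X7;
#' * `medium`: weak to very strong effects;
#' * `high`: moderate to very strong effects.
#'
#' The conditional treatment effect on the hazard is `exp(beta_treat) = 0.8`
#' in every scenario.
#'
#' @param level one of `"low"`, `"medium"`, `"high"`.
#' @param intercept treatment-model intercept (log-odds scale). Defaults to 0;
#'   use [calibrate_intercept()] to hit a target treated proportion.
#' @return an object of class `"het_scenario"`: a list with elements `level`,
#'   `treat_coeffs` (length 7, named x1..x7), `outcome_coeffs` (length 7,
#'   named x4..x10), `treat_intercept` and `beta_treat`.
#' @examples
#' sc <- make_scenario("low")
#' exp(sc$beta_treat)  # 0.8, the conditional hazard ratio
#' @export
make_scenario <- function(level = c("low", "medium", "high"), intercept = 0) {
  if (length(level) == 1L && !level %in% c("low", "medium", "high")) {
    sg_stop(sprintf("unknown heterogeneity level '%s'", level), "sgmatch_bad_level")
  }
  level <- match.arg(level)
  a <- c(vw = log(1.25), w = log(1.5), m = log(2), s = log(4), vs = log(8))
  treat <- switch(level,
    low    = a[c("vw", "w", "vw", "w", "vw", "w", "m")],
    medium = a[c("w", "m", "s", "w", "m", "s", "vs")],
    high   = a[c("m", "s", "m", "s", "m", "s", "vs")])
  outcome <- switch(level,
    low    = a[c("w", "vw", "w", "m", "vw", "w", "vw")],
    medium = a[c("w", "m", "s", "vs", "w", "m", "s")],
    high   = a[c("s", "m", "s", "vs", "m", "s", "m")])
  structure(list(
    level          = level,
    treat_coeffs   = stats::setNames(unname(treat), paste0("x", 1:7)),
    outcome_coeffs = stats::setNames(unname(outcome), paste0("x", 4:10)),
    treat_intercept = intercept,
    beta_treat     = log(0.8)
  ), class = "het_scenario")
}

#' @export
print.het_scenario <- function(x, ...) {
  cat(sprintf("Heterogeneity scenario: %s\n", x$level))
  cat(sprintf("  treatment intercept: %.4f   conditional HR: %.3f\n",
              x$treat_intercept, exp(x$beta_treat)))
  cat("  treatment log-odds coefficients (x1..x7):\n   ",
      paste(sprintf("%.3f", x$treat_coeffs), collapse = " "), "\n")
  cat("  survival log-hazard coefficients (x4..x10):\n   ",
      paste(sprintf("%.3f", x$outcome_coeffs), collapse = " "), "\n")
  invisible(x)
}

#' Calibrate the treatment-model intercept for a target treated proportion
#'
#' The intercept of the treatment logit indirectly sets the expected fraction
#' of patients treated. This finds, by bisection, the intercept at which the
#' Monte Carlo mean of `plogis(intercept + X %*% treat_coeffs)` over a fixed
#' calibration sample equals the target. The same covariate draws are reused
#' at every bisection step, so the objective is a deterministic, strictly
#' increasing function of the intercept and the root is unique.
#'
#' @param scenario a `"het_scenario"` from [make_scenario()].
#' @param target_treated_prop target expected treated proportion, in (0, 1).
#' @param n_calib size of the calibration sample (default 100000).
#' @param seed optional seed for the calibration draws.
#' @param tol tolerance on the achieved expected proportion (default 0.002).
#' @param bracket search interval for the intercept (default c(-30, 30)).
#' @param covariate_dist covariate generator, passed to [generate_covariates()].
#' @return the calibrated intercept (a single number).
#' @examples
#' a0 <- calibrate_intercept(make_scenario("low"), 0.5, n_calib = 5000, seed = 1)
#' abs(a0) < 0.05  # symmetric covariates: 50% treated needs intercept ~ 0
#' @export
calibrate_intercept <- function(scenario, target_treated_prop, n_calib = 100000L,
                                seed = NULL, tol = 0.002, bracket = c(-30, 30),
                                covariate_dist = c("normal", "bernoulli")) {
  stopifnot(inherits(scenario, "het_scenario"))
  if (!is.numeric(target_treated_prop) || length(target_treated_prop) != 1L ||
      target_treated_prop <= 0 || target_treated_prop >= 1) {
    sg_stop("`target_treated_prop` must lie strictly inside (0, 1)",
            "sgmatch_bad_target")
  }
  covariate_dist <- match.arg(covariate_dist)
  X <- generate_covariates(n_calib, seed = seed, dist = covariate_dist)
  eta <- drop(X[, 1:7, drop = FALSE] %*% scenario$treat_coeffs)
  f <- function(a) mean(stats::plogis(a + eta)) - target_treated_prop
  lo <- bracket[1]; hi <- bracket[2]
  if (f(lo) > 0 || f(hi) < 0) {
    sg_stop("no intercept bracketing the target proportion in the search interval",
            "sgmatch_no_bracket")
  }
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol || (hi - lo) < 1e-12) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  mid
}
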