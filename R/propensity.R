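#' Fit the propensity-score model
#'
#' Plain maximum-likelihood logistic regression of treatment on a chosen
#' covariate set, with an intercept and no regularisation. The default
#' covariate set for simulated cohorts is `x3`..`x10` — the covariates that
#' affect survival — which deliberately differs from the covariates that
#' generated treatment (x1..x7): selecting outcome-affecting covariates is
#' the recommended practice for propensity models, and the resulting mild
#' misspecification is part of the study design, not a defect.
#'
#' @param data an `"sg_cohort"` or any data frame with a 0/1 column `z` and
#'   the requested covariate columns.
#' @param covariates character vector of covariate column names
#'   (default `x3`..`x10`).
#' @return an object of class `"ps_fit"`: list with `coefficients`
#'   (intercept first), `ps_hat` (fitted probabilities, strictly inside
#'   (0,1)), `covariate_names` and `iterations`.
#' @details Convergence is capped at 100 IRLS iterations at relative deviance
#'   tolerance 1e-8. Non-convergence and (quasi-)complete separation raise
#'   classed errors carrying the iteration count; a single-class treatment
#'   column is rejected up front.
#' @examples
#' coh <- simulate_cohort(300, "low", seed = 1)
#' fit <- fit_ps(coh)
#' all.equal(mean(fit$ps_hat), mean(coh$z))  # logit score equation
#' @export
fit_ps <- function(data, covariates = paste0("x", 3:10)) {
  d <- as.data.frame(data)
  missing_cols <- setdiff(c("z", covariates), names(d))
  if (length(missing_cols)) {
    sg_stop(paste("missing columns:", paste(missing_cols, collapse = ", ")),
            "sgmatch_bad_schema")
  }
  if (!all(d$z %in% c(0, 1))) sg_stop("`z` must be 0/1", "sgmatch_bad_schema")
  if (length(unique(d$z)) < 2L) {
    sg_stop("treatment indicator is single-class; cannot fit a propensity model",
            "sgmatch_single_class")
  }
  dat <- d[, c("z", covariates), drop = FALSE]
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(z ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    sg_stop(sprintf("propensity logit did not converge in %d iterations", fit$iter),
            "sgmatch_no_convergence", iterations = fit$iter)
  }
  mu <- fit$fitted.values
  classifies <- max(mu[dat$z == 0]) < 1e-6 && min(mu[dat$z == 1]) > 1 - 1e-6
  if (separated || classifies || any(mu <= 0) || any(mu >= 1)) {
    sg_stop(sprintf("(quasi-)complete separation in the propensity logit after %d iterations",
                    fit$iter),
            "sgmatch_separation", iterations = fit$iter)
  }
  structure(list(coefficients = stats::coef(fit),
                 ps_hat = unname(fit$fitted.values),
                 covariate_names = covariates,
                 iterations = fit$iter),
            class = "ps_fit")
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("Propensity logit on %d covariates (%s), %d subjects\n",
              length(x$covariate_names),
              paste(x$covariate_names, collapse = ", "), length(x$ps_hat)))
  print(round(x$coefficients, 4))
  invisible(x)
}
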