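# Monte Carlo experiment driver: per-iteration pipeline, aggregation over
# iterations, and the three factor sweeps (proportion treated, proportion
# censored, number of matches).

#' Build and validate a Monte Carlo scenario configuration
#'
#' @param heterogeneity `"low"`, `"medium"` or `"high"`.
#' @param n_patients cohort size per iteration (default 1000).
#' @param prop_treated target expected treated proportion (default 0.2).
#' @param p_censor censoring probability (default 0.2).
#' @param method matching scheme, as in [sg_match()].
#' @param k_or_b number of nearest neighbours (k-NN schemes) or bootstrap
#'   resamples (default 15).
#' @param alpha exponential weight decay (default 5).
#' @param threshold_months response threshold (default 3).
#' @param n_iterations Monte Carlo iterations (default 1000; 200 is a
#'   practical reduced profile).
#' @param base_seed seed from which all iteration seeds are derived.
#' @param covariate_dist,n_calib,variance_scope forwarded to the generator,
#'   the intercept calibration and the variance estimator.
#' @param treat_intercept optional pre-calibrated treatment intercept; when
#'   `NULL` it is calibrated on first use (seed `derive_seed(base_seed, 0)`).
#' @return a validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(heterogeneity = "medium", n_patients = 1000L,
                            prop_treated = 0.2, p_censor = 0.2,
                            method = c("knn", "weighted_knn", "one_by_one", "bootstrap"),
                            k_or_b = 15L, alpha = 5, threshold_months = 3,
                            n_iterations = 1000L, base_seed = 1L,
                            covariate_dist = "normal", n_calib = 100000L,
                            variance_scope = "matched", treat_intercept = NULL) {
  method <- match.arg(method)
  stopifnot(heterogeneity %in% c("low", "medium", "high"),
            n_patients >= 10, n_iterations >= 1, k_or_b >= 1, alpha >= 0,
            prop_treated > 0, prop_treated < 1, p_censor >= 0, p_censor < 1,
            threshold_months >= 0)
  structure(list(heterogeneity = heterogeneity,
                 n_patients = as.integer(n_patients),
                 prop_treated = prop_treated, p_censor = p_censor,
                 method = method, k_or_b = as.integer(k_or_b), alpha = alpha,
                 threshold_months = threshold_months,
                 n_iterations = as.integer(n_iterations),
                 base_seed = as.integer(base_seed),
                 covariate_dist = covariate_dist, n_calib = as.integer(n_calib),
                 variance_scope = variance_scope,
                 treat_intercept = treat_intercept),
            class = "scenario_config")
}

# Ensure the config carries a calibrated treatment intercept.
calibrate_config <- function(config) {
  if (!is.null(config$treat_intercept)) return(config)
  scen <- make_scenario(config$heterogeneity)
  config$treat_intercept <- calibrate_intercept(
    scen, config$prop_treated, n_calib = config$n_calib,
    seed = derive_seed(config$base_seed, 0L),
    covariate_dist = config$covariate_dist)
  config
}

#' Run a single Monte Carlo iteration
#'
#' One iteration simulates a cohort under the configured scenario, fits the
#' propensity model on `x3`..`x10`, matches per the configured scheme,
#' estimates all subject-specific gains, variances and labels, and reduces
#' them to the iteration metrics. Iterations that fail (e.g. a degenerate
#' treated group or a separated propensity fit) are redrawn with a derived
#' seed, at most 10 times; the redraw count is reported.
#'
#' @param config a `"scenario_config"`.
#' @param iteration_seed integer seed for this iteration's cohort (and, for
#'   the bootstrap scheme, a derived resampling seed).
#' @return one-row data frame: `mean_ste` (mean gain over treated with a
#'   defined gain, months), `mean_ste_var` (months^2), `var_of_ste_var`
#'   (variance of the per-subject variance across treated units, months^4),
#'   `prop_labels_censored` (fraction of treated whose label is
#'   undetermined), `true_ate`, `true_variance`, `delta_var_rel`
#'   (`(V - mean_ste_var)/V`), `n_labelable`, `n_var_defined`, `redraws`.
#' @export
run_iteration <- function(config, iteration_seed) {
  stopifnot(inherits(config, "scenario_config"))
  config <- calibrate_config(config)
  scen <- make_scenario(config$heterogeneity, intercept = config$treat_intercept)
  attempt <- 0L
  repeat {
    seed_a <- if (attempt == 0L) as.integer(iteration_seed) else
      derive_seed(iteration_seed, 7900000L + attempt)
    out <- tryCatch({
      coh <- simulate_cohort(config$n_patients, scen, p_censor = config$p_censor,
                             seed = seed_a, covariate_dist = config$covariate_dist)
      if (sum(coh$z == 1) < 2L) sg_stop("fewer than 2 treated subjects", "sgmatch_bad_groups")
      need_controls <- if (config$method == "bootstrap") 2L else config$k_or_b
      if (sum(coh$z == 0) < max(2L, need_controls)) {
        sg_stop("control group smaller than k", "sgmatch_bad_groups")
      }
      fit <- sg_match(coh, method = config$method, k = config$k_or_b,
                      b = config$k_or_b, alpha = config$alpha,
                      threshold = config$threshold_months,
                      variance_scope = config$variance_scope,
                      seed = derive_seed(seed_a, 31L))
      ts <- truth_summary(coh)
      est <- fit$estimates
      s <- fit$stats
      data.frame(mean_ste = s$mean_ste, mean_ste_var = s$mean_ste_var,
                 var_of_ste_var = s$var_of_ste_var,
                 prop_labels_censored = s$prop_undetermined,
                 true_ate = ts$true_ate, true_variance = ts$true_variance,
                 delta_var_rel = if (ts$true_variance > 0)
                   (ts$true_variance - s$mean_ste_var) / ts$true_variance
                 else NA_real_,
                 n_labelable = sum(!is.na(est$sg_hat)),
                 n_var_defined = sum(!is.na(est$v_hat)),
                 redraws = attempt)
    }, error = function(e) e)
    if (!inherits(out, "error")) return(out)
    attempt <- attempt + 1L
    if (attempt > 10L) {
      sg_stop(sprintf("iteration failed after 10 redraws: %s", conditionMessage(out)),
              "sgmatch_iteration_failed")
    }
  }
}

#' Aggregate iteration results into a Monte Carlo summary
#'
#' Arithmetic means and Monte Carlo standard errors over iterations for every
#' metric, ignoring undefined per-iteration values but reporting how many
#' were missing. A metric undefined in every iteration stays `NA` (missing,
#' not zero). The across-iteration variance of the per-iteration mean STE
#' variance is reported as `var_across_iter_mean_ste_var`, the alternative
#' reading of "var(V^s)".
#'
#' @param results data frame of rows from [run_iteration()].
#' @return one-row data frame with `<metric>_mean`, `<metric>_se` and
#'   `<metric>_nmiss` columns plus `n_iterations`,
#'   `var_across_iter_mean_ste_var` and `total_redraws`.
#' @export
summarize_iterations <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  metrics <- c("mean_ste", "mean_ste_var", "var_of_ste_var",
               "prop_labels_censored", "true_ate", "true_variance",
               "delta_var_rel")
  out <- list(n_iterations = nrow(results))
  for (m in metrics) {
    v <- results[[m]]
    ok <- v[!is.na(v)]
    out[[paste0(m, "_mean")]] <- if (length(ok)) mean(ok) else NA_real_
    out[[paste0(m, "_se")]] <- if (length(ok) >= 2L) stats::sd(ok) / sqrt(length(ok)) else NA_real_
    out[[paste0(m, "_nmiss")]] <- sum(is.na(v))
  }
  v <- results$mean_ste_var
  out$var_across_iter_mean_ste_var <-
    if (sum(!is.na(v)) >= 2L) stats::var(v[!is.na(v)]) else NA_real_
  out$total_redraws <- sum(results$redraws)
  as.data.frame(out)
}

#' Run all iterations of one scenario
#'
#' @param config a `"scenario_config"`.
#' @param keep_iterations also return the raw per-iteration results.
#' @return list with `summary` (from [summarize_iterations()], prefixed with
#'   the scenario descriptors) and, when requested, `iterations`. Iteration
#'   seeds are `derive_seed(base_seed, i)`, so extending `n_iterations`
#'   leaves earlier iterations unchanged.
#' @export
run_scenario <- function(config, keep_iterations = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  config <- calibrate_config(config)
  iters <- do.call(rbind, lapply(seq_len(config$n_iterations), function(i) {
    run_iteration(config, derive_seed(config$base_seed, i))
  }))
  desc <- data.frame(heterogeneity = config$heterogeneity,
                     method = config$method, n_patients = config$n_patients,
                     prop_treated = config$prop_treated,
                     p_censor = config$p_censor, k_or_b = config$k_or_b,
                     alpha = config$alpha,
                     threshold_months = config$threshold_months,
                     base_seed = config$base_seed)
  res <- list(summary = cbind(desc, summarize_iterations(iters)))
  if (keep_iterations) res$iterations <- iters
  res
}

#' Default factor sweeps of the simulation study
#'
#' Three one-factor-at-a-time sweeps around the central design point (20%
#' treated, 20% censored, k = 15): the proportion treated (no censoring),
#' the proportion censored (20% treated), and the number of matches k
#' (20% treated, 20% censored).
#'
#' @return named list of sweeps, each with `vary` (the varied field of
#'   [scenario_config()]), `values`, and `fixed` overrides.
#' @export
default_sweeps <- function() {
  list(
    prop_treated = list(vary = "prop_treated",
                        values = c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
                        fixed = list(p_censor = 0, k_or_b = 15L)),
    p_censor = list(vary = "p_censor",
                    values = c(0, 0.10, 0.20, 0.30, 0.40, 0.50),
                    fixed = list(prop_treated = 0.2, k_or_b = 15L)),
    k = list(vary = "k_or_b",
             values = c(1L, 2L, 5L, 10L, 15L, 25L, 50L),
             fixed = list(prop_treated = 0.2, p_censor = 0.2)))
}

#' Run the full Monte Carlo grid
#'
#' Crosses every sweep cell with every matching scheme and heterogeneity
#' level, runs `n_iterations` Monte Carlo iterations per cell, and returns
#' one tidy summary row per cell. Calibrated treatment intercepts are cached
#' per (heterogeneity, proportion treated) pair. Optionally writes the tidy
#' CSV and a JSON run manifest.
#'
#' @param sweeps list of sweeps as in [default_sweeps()] (the default).
#' @param heterogeneity,methods levels to cross (defaults: all three
#'   heterogeneity levels and all four matching schemes; drop `"bootstrap"`
#'   for a much cheaper run, since it refits the propensity model in every
#'   resample of every iteration).
#' @param n_iterations iterations per cell (default 200, the reduced
#'   profile; the full study design uses 1000).
#' @param base_seed master seed.
#' @param n_patients cohort size (default 1000).
#' @param out_dir optional directory for `results.csv` and `manifest.json`.
#' @param ... further arguments passed to [scenario_config()].
#' @return tidy data frame: one row per sweep cell x method x heterogeneity,
#'   with a `sweep` column naming the sweep.
#' @export
run_grid <- function(sweeps = default_sweeps(),
                     heterogeneity = c("low", "medium", "high"),
                     methods = c("one_by_one", "knn", "weighted_knn", "bootstrap"),
                     n_iterations = 200L, base_seed = 1L, n_patients = 1000L,
                     out_dir = NULL, ...) {
  stopifnot(length(sweeps) >= 1L)
  calib_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (sw_name in names(sweeps)) {
    sw <- sweeps[[sw_name]]
    for (val in sw$values) {
      for (het in heterogeneity) {
        for (meth in methods) {
          args <- c(list(heterogeneity = het, method = meth,
                         n_patients = n_patients, n_iterations = n_iterations,
                         base_seed = base_seed), sw$fixed, list(...))
          args[[sw$vary]] <- val
          cfg <- do.call(scenario_config, args)
          key <- sprintf("%s|%.6f|%s|%d", het, cfg$prop_treated,
                         cfg$covariate_dist, cfg$n_calib)
          if (is.null(calib_cache[[key]])) {
            calib_cache[[key]] <- calibrate_config(cfg)$treat_intercept
          }
          cfg$treat_intercept <- calib_cache[[key]]
          s <- run_scenario(cfg)$summary
          s$sweep <- sw_name
          rows[[length(rows) + 1L]] <- s
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  res <- res[, c("sweep", setdiff(names(res), "sweep"))]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"),
                   list(sweeps = names(sweeps), heterogeneity = heterogeneity,
                        methods = methods, n_iterations = n_iterations,
                        n_patients = n_patients, base_seed = base_seed,
                        total_redraws = sum(res$total_redraws),
                        n_cells = nrow(res)))
  }
  res
}
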