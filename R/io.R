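# CSV readers/writers for cohorts, matched sets and estimates, plus run
# configuration (YAML/JSON) and run manifests. CSV everywhere: the tables are
# small and plain text diffs cleanly.
#
# Censoring flag convention in every table: 1 = censored, 0 = observed.

cohort_required_cols <- c("id", "z", "os_months", "censored")
cohort_truth_cols <- c("os1", "os0", "sg_true", "ps_true")

#' Write / read a cohort as CSV
#'
#' Columns: `id, z, os_months, censored, os1, os0, sg_true, ps_true,
#' x1..x10`. The truth columns (`os1`, `os0`, `sg_true`, `ps_true`) may be
#' absent for real cohorts, where counterfactuals are unknown. Numbers round
#'-trip at full double precision (15 significant digits).
#'
#' @param cohort an `"sg_cohort"` or conforming data frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `"sg_cohort"` data frame.
#' @export
write_cohort <- function(cohort, path) {
  d <- as.data.frame(cohort)
  stopifnot(all(cohort_required_cols %in% names(d)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) sg_stop(paste("no such file:", path), "sgmatch_io")
  d <- utils::read.csv(path)
  missing_cols <- setdiff(cohort_required_cols, names(d))
  if (length(missing_cols)) {
    sg_stop(paste("cohort file lacks required columns:",
                  paste(missing_cols, collapse = ", ")), "sgmatch_bad_schema")
  }
  if (!all(d$z %in% c(0, 1))) sg_stop("column `z` must be 0/1", "sgmatch_bad_schema")
  if (!all(d$censored %in% c(0, 1))) {
    sg_stop("column `censored` must be 0/1 (1 = censored)", "sgmatch_bad_schema")
  }
  if (any(d$os_months <= 0)) sg_stop("`os_months` must be positive", "sgmatch_bad_schema")
  class(d) <- c("sg_cohort", "data.frame")
  d
}

#' Write matched sets as a long CSV
#'
#' One row per (treated, matched control) pair: `treated_id, control_id,
#' distance, weight, replicate` (`replicate` is the bootstrap resample index,
#' 0 for the non-bootstrap schemes).
#'
#' @param matches list of `"matched_set"` objects.
#' @param path file path.
#' @export
write_matched_sets <- function(matches, path) {
  rows <- lapply(matches, function(m) {
    data.frame(treated_id = m$treated_id, control_id = m$control_ids,
               distance = m$distances, weight = m$weights,
               replicate = m$replicate)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write per-subject estimates as CSV
#'
#' @param estimates data frame from [estimate_all()] (or
#'   `fit$estimates` of an [sg_match()] fit).
#' @param path file path.
#' @export
write_estimates <- function(estimates, path) {
  stopifnot(all(c("treated_id", "sg_hat", "v_hat", "label",
                  "n_controls_used") %in% names(estimates)))
  utils::write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}

run_config_keys <- c("heterogeneity", "n_patients", "prop_treated", "p_censor",
                     "method", "k_or_b", "alpha", "threshold_months",
                     "n_iterations", "base_seed", "covariate_dist", "n_calib",
                     "variance_scope")

#' Read a run configuration from YAML or JSON
#'
#' The file may set any [scenario_config()] field; unknown keys are rejected
#' by name so typos fail loudly rather than silently falling back to
#' defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a `"scenario_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) sg_stop(paste("no such file:", path), "sgmatch_io")
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) sg_stop("config file must hold a mapping", "sgmatch_bad_config")
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    sg_stop(paste("unknown config keys:", paste(unknown, collapse = ", ")),
            "sgmatch_bad_config")
  }
  do.call(scenario_config, cfg)
}

#' Write a JSON run manifest
#'
#' Records what a run did (configuration, seeds, package version, redraw
#' counts, timing) without affecting any computed output.
#'
#' @param path output path.
#' @param info named list of run metadata.
#' @export
write_manifest <- function(path, info) {
  info$package_version <- as.character(utils::packageVersion("sgmatch"))
  info$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
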