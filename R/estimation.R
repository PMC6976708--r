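# Subject-specific survival gain, its matched-set variance, and the
# censoring-aware binary response label.
#
# A censored OS is read throughout as a lower bound on the true survival
# time; the labelling rules only commit to "response" / "non-response" when
# that bound makes the comparison against the threshold unambiguous, and
# return "undetermined" otherwise.

#' Subject-specific survival gain of one matched set
#'
#' The estimated gain is the treated subject's OS minus the weighted mean of
#' the matched controls' OS: `SG = OS_T - sum_j w_j OS_j`.
#'
#' @param treated_os observed OS of the treated subject (months).
#' @param control_os OS values of the matched controls (months).
#' @param weights matching weights (same length, summing to 1).
#' @return the estimated survival gain in months.
#' @examples
#' estimate_sg(20, c(10, 14), c(0.5, 0.5))  # 8
#' @export
estimate_sg <- function(treated_os, control_os, weights) {
  if (length(control_os) == 0L) sg_stop("empty control set", "sgmatch_empty_controls")
  if (length(control_os) != length(weights)) {
    sg_stop("control OS and weight vectors differ in length", "sgmatch_length_mismatch")
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    sg_stop("weights must sum to 1", "sgmatch_bad_weights")
  }
  treated_os - sum(weights * control_os)
}

#' Censoring-aware response label for one treated subject
#'
#' Classifies a treated subject as `response` (estimated gain at least
#' `threshold` months), `non_response`, or `undetermined` when censoring makes
#' the comparison ambiguous. Writing `SG` for the weighted gain over the
#' controls that are allowed to contribute:
#'
#' * all controls censored and treated censored: `undetermined` (no direction
#'   of the comparison is identified);
#' * some but not all controls censored: censored controls are dropped and the
#'   weights renormalised over the observed controls before computing `SG`;
#' * all controls censored, treated observed: `SG` is computed from the
#'   censored values; `SG >= threshold` could be an artefact of the lower
#'   bounds, so the label is `undetermined`; `SG < threshold` can only get
#'   worse as the true control survivals grow, so `non_response`;
#' * treated censored (some control observed): `SG >= threshold` holds a
#'   fortiori for the true treated survival, so `response`; otherwise
#'   `undetermined`;
#' * no relevant censoring: `response` iff `SG >= threshold` (ties count as
#'   response).
#'
#' Whenever the label is `undetermined` because the gain itself is not
#' identified, `sg_hat` is `NA`.
#'
#' @param treated_os treated subject's recorded OS (months).
#' @param treated_censored 0/1 (or logical) censoring flag of the treated.
#' @param control_os recorded OS of the matched controls.
#' @param control_censored 0/1 flags for the controls.
#' @param weights matching weights summing to 1.
#' @param threshold response threshold in months (default 3).
#' @return list with `label` (one of `"response"`, `"non_response"`,
#'   `"undetermined"`), `sg_hat` (months or `NA`), `used` (logical mask of
#'   controls that contribute), `weights_used` (renormalised weights over
#'   `used`, `NA` elsewhere) and `kappa` (1 when the weighted control mean is
#'   usable, `NA` when censoring voids it).
#' @export
classify_label <- function(treated_os, treated_censored, control_os,
                           control_censored, weights, threshold = 3) {
  k <- length(control_os)
  if (k == 0L) sg_stop("empty control set", "sgmatch_empty_controls")
  stopifnot(length(control_censored) == k, length(weights) == k,
            length(treated_os) == 1L, length(treated_censored) == 1L)
  if (abs(sum(weights) - 1) > 1e-8) sg_stop("weights must sum to 1", "sgmatch_bad_weights")
  t_cens <- as.integer(treated_censored) == 1L
  c_cens <- as.integer(control_censored) == 1L

  if (all(c_cens)) {
    if (t_cens) {
      return(list(label = "undetermined", sg_hat = NA_real_,
                  used = rep(FALSE, k), weights_used = rep(NA_real_, k),
                  kappa = NA_real_))
    }
    # Treated observed, every control a lower bound: all controls retained.
    sg <- estimate_sg(treated_os, control_os, weights)
    if (sg >= threshold) {
      return(list(label = "undetermined", sg_hat = NA_real_,
                  used = rep(TRUE, k), weights_used = weights,
                  kappa = NA_real_))
    }
    return(list(label = "non_response", sg_hat = sg,
                used = rep(TRUE, k), weights_used = weights, kappa = 1))
  }

  used <- !c_cens
  if (sum(weights[used]) <= 0) {
    sg_stop("all observed controls carry zero weight; gain undefined",
            "sgmatch_bad_weights")
  }
  w_used <- rep(NA_real_, k)
  w_used[used] <- weights[used] / sum(weights[used])
  sg <- treated_os - sum(w_used[used] * control_os[used])
  if (t_cens) {
    if (sg >= threshold) {
      return(list(label = "response", sg_hat = sg, used = used,
                  weights_used = w_used, kappa = 1))
    }
    return(list(label = "undetermined", sg_hat = NA_real_, used = used,
                weights_used = w_used, kappa = 1))
  }
  list(label = if (sg >= threshold) "response" else "non_response",
       sg_hat = sg, used = used, weights_used = w_used, kappa = 1)
}

#' Variance of the subject-specific survival gain
#'
#' Two estimators, treating the treated subject's OS as a constant:
#'
#' * `"knn"`: the matched-set estimator
#'   `V = sum_j w_j^2 * s2` over the contributing controls, where by default
#'   `s2` is the sample variance of the contributing controls' OS within the
#'   matched set (`scope = "matched"`) or, optionally, the variance of the
#'   full control group's OS (`scope = "full"`). Controls excluded by the
#'   censoring rules do not contribute; weights are renormalised over the
#'   contributors. Fewer than 2 contributing controls leave the local
#'   variance undefined (`NA`).
#' * `"one_by_one_crude"`: one-by-one matching carries no within-set spread,
#'   so a crude estimate is the sample variance of the entire control
#'   group's OS.
#'
#' @param control_os OS of the matched controls (months).
#' @param control_censored 0/1 censoring flags for the controls.
#' @param weights matching weights summing to 1.
#' @param mode `"knn"` or `"one_by_one_crude"`.
#' @param full_control_os OS of the whole control group (required for the
#'   crude mode and for `scope = "full"`).
#' @param scope `"matched"` (default) or `"full"`, see above.
#' @param used optional logical mask of contributing controls (as returned by
#'   [classify_label()]); by default recomputed from the censoring flags
#'   (censored controls excluded unless all are censored).
#' @return estimated variance in months^2, or `NA` when undefined.
#' @examples
#' estimate_variance(c(10, 14), c(0, 0), c(0.5, 0.5), "knn")  # 4
#' @export
estimate_variance <- function(control_os, control_censored, weights,
                              mode = c("knn", "one_by_one_crude"),
                              full_control_os = NULL,
                              scope = c("matched", "full"), used = NULL) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (length(control_os) == 0L) sg_stop("empty control set", "sgmatch_empty_controls")
  if (mode == "one_by_one_crude") {
    if (is.null(full_control_os)) {
      sg_stop("`full_control_os` is required for the crude variance", "sgmatch_need_pool")
    }
    return(stats::var(full_control_os))
  }
  c_cens <- as.integer(control_censored) == 1L
  if (is.null(used)) used <- if (all(c_cens)) rep(TRUE, length(control_os)) else !c_cens
  n_used <- sum(used)
  if (n_used < 2L && scope == "matched") return(NA_real_)
  if (n_used < 1L) return(NA_real_)
  w <- weights[used] / sum(weights[used])
  s2 <- if (scope == "matched") {
    stats::var(control_os[used])
  } else {
    if (is.null(full_control_os)) {
      sg_stop("`full_control_os` is required for scope = \"full\"", "sgmatch_need_pool")
    }
    stats::var(full_control_os)
  }
  sum(w^2) * s2
}

#' Estimate gain, variance and label for every treated subject
#'
#' Applies [estimate_sg()], [classify_label()] and [estimate_variance()]
#' consistently across a list of matched sets: the mask of contributing
#' controls chosen by the labelling rules also drives the variance estimator,
#' and the variance is `NA` exactly when the weighted control mean itself is
#' voided by censoring (`kappa = NA`).
#'
#' @param cohort cohort data frame with `id`, `z`, `os_months`, `censored`.
#' @param matched_sets list of `"matched_set"` objects, one per treated unit.
#' @param threshold response threshold in months (default 3).
#' @param variance_mode `"auto"` (crude when every set has a single control,
#'   matched-set estimator otherwise), `"knn"`, or `"one_by_one_crude"`.
#' @param variance_scope passed to [estimate_variance()].
#' @return data frame with one row per treated subject: `treated_id`,
#'   `sg_hat`, `v_hat`, `label`, `n_controls_used`.
#' @export
estimate_all <- function(cohort, matched_sets, threshold = 3,
                         variance_mode = c("auto", "knn", "one_by_one_crude"),
                         variance_scope = c("matched", "full")) {
  variance_mode <- match.arg(variance_mode)
  variance_scope <- match.arg(variance_scope)
  d <- as.data.frame(cohort)
  stopifnot(all(c("id", "z", "os_months", "censored") %in% names(d)))
  full_pool <- d$os_months[d$z == 0]
  crude_var <- stats::var(full_pool)
  if (variance_mode == "auto") {
    variance_mode <- if (all(vapply(matched_sets, function(m) length(m$control_ids),
                                    1L) == 1L)) "one_by_one_crude" else "knn"
  }
  nt <- length(matched_sets)
  sg <- v <- numeric(nt)
  lab <- character(nt)
  tid <- vector(mode(d$id), nt)
  n_used <- integer(nt)
  for (i in seq_len(nt)) {
    m <- matched_sets[[i]]
    ti <- match(m$treated_id, d$id)
    ci <- match(m$control_ids, d$id)
    if (is.na(ti) || anyNA(ci)) {
      sg_stop("matched set refers to ids absent from the cohort", "sgmatch_bad_ids")
    }
    c_os <- d$os_months[ci]
    c_cs <- d$censored[ci]
    cl <- classify_label(d$os_months[ti], d$censored[ti], c_os, c_cs,
                         m$weights, threshold)
    v[i] <- if (is.na(cl$kappa)) {
      NA_real_
    } else if (variance_mode == "one_by_one_crude") {
      crude_var
    } else {
      estimate_variance(c_os, c_cs, m$weights, mode = "knn",
                        full_control_os = full_pool, scope = variance_scope,
                        used = cl$used)
    }
    sg[i] <- cl$sg_hat
    lab[i] <- cl$label
    tid[i] <- m$treated_id
    n_used[i] <- sum(cl$used)
  }
  data.frame(treated_id = tid, sg_hat = sg, v_hat = v, label = lab,
             n_controls_used = n_used)
}
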