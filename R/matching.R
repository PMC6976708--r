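# Greedy nearest-neighbour matching with replacement on the propensity score,
# exponential distance weighting, and the complex bootstrap scheme (resampled
# control groups, per-resample PS refit, pooled 1:1 matches).

# Matched-set constructor with invariant checks. `distances` may be NA when a
# distance is undefined (degenerate single-control pools).
matched_set <- function(treated_id, control_ids, distances, weights,
                        replicate = rep(0L, length(control_ids))) {
  k <- length(control_ids)
  stopifnot(k >= 1L, length(distances) == k, length(weights) == k,
            all(weights >= 0), abs(sum(weights) - 1) < 1e-12)
  ok <- is.na(distances) | (distances >= -1e-12 & distances <= 1 + 1e-12)
  if (!all(ok)) sg_stop("matched distances must lie in [0, 1]", "sgmatch_bad_distance")
  structure(list(treated_id = treated_id, control_ids = control_ids,
                 distances = distances, weights = weights, replicate = replicate),
            class = "matched_set")
}

#' Greedy k-nearest-neighbour propensity matching with replacement
#'
#' Each treated unit independently takes the `k` controls minimising the
#' absolute propensity-score distance; controls may be reused across treated
#' units (matching with replacement) but never repeat within one matched set.
#' Ties in distance are broken by the smaller control identifier so results
#' are deterministic. `k = 1` is classic one-by-one matching. Weights are
#' uniform `1/k`; see [exp_weights()] for the distance-weighted variant.
#'
#' @param ps_treated propensity scores of treated units.
#' @param ps_control propensity scores of control units (length >= k).
#' @param k number of matches per treated unit.
#' @param treated_ids,control_ids identifiers (default: positional indices).
#' @return list of `"matched_set"` objects, one per treated unit, each with
#'   `treated_id`, `control_ids`, `distances` (|PS_i - PS_j|) and uniform
#'   `weights`.
#' @examples
#' m <- nn_match(0.5, c(0.40, 0.45, 0.80), k = 2)
#' m[[1]]$control_ids  # 2, 1: distances 0.05 and 0.10
#' @export
nn_match <- function(ps_treated, ps_control, k = 1L,
                     treated_ids = seq_along(ps_treated),
                     control_ids = seq_along(ps_control)) {
  stopifnot(length(ps_treated) >= 1L, length(ps_control) >= 1L,
            length(treated_ids) == length(ps_treated),
            length(control_ids) == length(ps_control))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    sg_stop("`k` must be a positive count", "sgmatch_bad_k")
  }
  k <- as.integer(k)
  if (k > length(ps_control)) {
    sg_stop(sprintf("k = %d exceeds the number of controls (%d)",
                    k, length(ps_control)), "sgmatch_k_too_large")
  }
  lapply(seq_along(ps_treated), function(i) {
    d <- abs(ps_control - ps_treated[i])
    o <- order(d, control_ids)[seq_len(k)]
    matched_set(treated_ids[i], control_ids[o], d[o], rep(1 / k, k))
  })
}

#' Exponential distance weights for a matched set
#'
#' Converts propensity distances into normalised weights
#' `w_j = exp(-alpha * d_j) / sum_j exp(-alpha * d_j)`, so that closer
#' controls contribute more to the matched-control mean. `alpha = 0` gives
#' uniform weights; the study default `alpha = 5` leaves near-equal weights
#' at small distances while pushing the weight of a maximally distant control
#' (d = 1) towards zero.
#'
#' @param distances nonempty vector of distances in \[0, 1\].
#' @param alpha decay rate (>= 0, default 5).
#' @return weights, same length as `distances`, summing to 1.
#' @export
exp_weights <- function(distances, alpha = 5) {
  if (length(distances) == 0L) {
    sg_stop("empty distance vector", "sgmatch_empty_distances")
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  if (any(is.na(distances)) || any(distances < -1e-12) || any(distances > 1 + 1e-12)) {
    sg_stop("distances must lie in [0, 1]", "sgmatch_bad_distance")
  }
  w <- exp(-alpha * distances)
  w / sum(w)
}

#' Apply exponential distance weights to matched sets
#'
#' @param matches list of `"matched_set"` objects from [nn_match()].
#' @param alpha passed to [exp_weights()].
#' @return the matched sets with `weights` replaced.
#' @export
weight_matches <- function(matches, alpha = 5) {
  lapply(matches, function(m) {
    m$weights <- exp_weights(m$distances, alpha)
    m
  })
}

#' Complex bootstrap matching
#'
#' Draws `b` bootstrap resamples of the control group (each of the original
#' control-group size, with replacement). Within each resample the propensity
#' model is re-estimated on the union of all treated units and the resampled
#' controls, and every treated unit is 1:1 matched to its nearest resampled
#' control. Pooling over resamples gives each treated unit a multiset of `b`
#' matched original control identities with uniform weights `1/b`; the same
#' control may appear multiple times within one matched set, unlike in
#' [nn_match()].
#'
#' One fixed propensity model form (logit on `ps_covariates`) is reused in
#' every resample. A resample in which the refit fails (separation,
#' non-convergence, single-class resample) is redrawn, at most `max_retries`
#' times, before the whole call errors.
#'
#' @param cohort an `"sg_cohort"` or data frame with `id`, `z` and the
#'   propensity covariates.
#' @param b number of bootstrap resamples (>= 1).
#' @param seed optional RNG seed.
#' @param ps_covariates covariates for the per-resample propensity refit.
#' @param max_retries maximum redraws per failing resample (default 10).
#' @return list of `"matched_set"` objects, one per treated unit; `replicate`
#'   records which resample produced each match.
#' @export
bootstrap_match <- function(cohort, b, seed = NULL,
                            ps_covariates = paste0("x", 3:10),
                            max_retries = 10L) {
  d <- as.data.frame(cohort)
  stopifnot(!is.null(d$z), !is.null(d$id))
  if (!is.numeric(b) || length(b) != 1L || b < 1) {
    sg_stop("`b` must be a positive count", "sgmatch_bad_b")
  }
  b <- as.integer(b)
  tr <- which(d$z == 1)
  ct <- which(d$z == 0)
  if (length(tr) < 1L || length(ct) < 1L) {
    sg_stop("bootstrap matching needs at least 1 treated and 1 control subject",
            "sgmatch_bad_groups")
  }
  nt <- length(tr); nc <- length(ct)
  ids_m <- matrix(NA_real_, nrow = b, ncol = nt)
  dst_m <- matrix(NA_real_, nrow = b, ncol = nt)
  with_seed(seed, {
    for (r in seq_len(b)) {
      if (nc == 1L) {
        # Degenerate pool: the match is forced regardless of the PS model.
        ids_m[r, ] <- d$id[ct]
        next
      }
      attempt <- 0L
      repeat {
        idx <- sample(ct, nc, replace = TRUE)
        boot <- d[c(tr, idx), , drop = FALSE]
        fit <- tryCatch(fit_ps(boot, ps_covariates), error = function(e) e)
        if (!inherits(fit, "error")) break
        attempt <- attempt + 1L
        if (attempt > max_retries) {
          sg_stop(sprintf("propensity refit failed in bootstrap resample %d after %d retries: %s",
                          r, max_retries, conditionMessage(fit)),
                  "sgmatch_bootstrap_refit")
        }
      }
      ps_t <- fit$ps_hat[seq_len(nt)]
      ps_c <- fit$ps_hat[-seq_len(nt)]
      cid <- d$id[idx]
      for (i in seq_len(nt)) {
        dv <- abs(ps_c - ps_t[i])
        j <- order(dv, cid)[1L]
        ids_m[r, i] <- cid[j]
        dst_m[r, i] <- dv[j]
      }
    }
  })
  lapply(seq_len(nt), function(i) {
    matched_set(d$id[tr[i]], ids_m[, i], dst_m[, i], rep(1 / b, b),
                replicate = seq_len(b))
  })
}
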