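# Survival-gain estimator, censoring-aware labelling and variance estimators.

test_that("the survival gain is the weighted control contrast", {
  expect_equal(estimate_sg(20, c(10, 14), c(0.5, 0.5)), 8)
  expect_equal(estimate_sg(20, c(10, 20), c(0.75, 0.25)), 7.5)
  expect_equal(estimate_sg(15, 15, 1), 0)   # matched to its own value
  expect_error(estimate_sg(20, c(10, 14), 1), class = "sgmatch_length_mismatch")
  expect_error(estimate_sg(20, c(10, 14), c(0.7, 0.7)), class = "sgmatch_bad_weights")
  expect_error(estimate_sg(20, numeric(0), numeric(0)), class = "sgmatch_empty_controls")
})

test_that("the labelling rules resolve the published censoring cases", {
  # observed treated, censored control, large gain: lower bound is ambiguous
  r <- classify_label(30, 0, 10, 1, 1, threshold = 3)
  expect_equal(r$label, "undetermined")
  expect_true(is.na(r$sg_hat))
  # censored treated, observed control, large gain: holds a fortiori
  r <- classify_label(30, 1, 10, 0, 1, threshold = 3)
  expect_equal(r$label, "response")
  expect_equal(r$sg_hat, 20)
  # both censored: nothing is identified
  r <- classify_label(30, 1, 10, 1, 1, threshold = 3)
  expect_equal(r$label, "undetermined")
  # mixed control censoring: the censored control is dropped and weights
  # renormalised before the comparison
  r <- classify_label(12, 0, c(10, 11), c(1, 0), c(0.5, 0.5), threshold = 3)
  expect_equal(r$label, "non_response")
  expect_equal(r$sg_hat, 1)
  expect_equal(r$used, c(FALSE, TRUE))
  expect_equal(r$weights_used, c(NA, 1))
  # all controls censored, observed treated, small gain: can only get worse
  r <- classify_label(11, 0, c(10, 10), c(1, 1), c(0.5, 0.5), threshold = 3)
  expect_equal(r$label, "non_response")
  expect_equal(r$sg_hat, 1)
})

test_that("labels agree with the decision-table oracle over random cases", {
  set.seed(91)
  for (rep in 1:300) {
    k <- sample(1:4, 1)
    c_os <- round(runif(k, 1, 40), 1)
    c_c <- rbinom(k, 1, 0.4)
    t_os <- round(runif(1, 1, 40), 1)
    t_c <- rbinom(1, 1, 0.4)
    w <- exp_weights(runif(k), alpha = sample(c(0, 5), 1))
    thr <- sample(c(0.5, 3, 10), 1)
    got <- classify_label(t_os, t_c, c_os, c_c, w, thr)
    expect_equal(got$label, oracle_label(t_os, t_c, c_os, c_c, w, thr))
    # the gain is undefined exactly when the label is undetermined
    expect_equal(is.na(got$sg_hat), got$label == "undetermined")
  }
})

test_that("labelling is monotone in an observed treated survival", {
  set.seed(92)
  for (rep in 1:50) {
    k <- sample(1:4, 1)
    c_os <- runif(k, 1, 40); c_c <- rbinom(k, 1, 0.4)
    w <- rep(1 / k, k)
    t1 <- runif(1, 1, 40)
    lab1 <- classify_label(t1, 0, c_os, c_c, w, 3)$label
    lab2 <- classify_label(t1 + runif(1, 0, 20), 0, c_os, c_c, w, 3)$label
    if (lab1 == "response") expect_true(lab2 %in% c("response", "undetermined"))
  }
})

test_that("zero-weight controls are inert", {
  r1 <- classify_label(20, 0, c(10, 99), c(0, 0), c(1, 0), 3)
  r2 <- classify_label(20, 0, 10, 0, 1, 3)
  expect_equal(r1$label, r2$label)
  expect_equal(r1$sg_hat, r2$sg_hat)
  expect_equal(estimate_variance(c(10, 14, 50), c(0, 0, 0), c(0.5, 0.5, 0), "knn"),
               estimate_variance(c(10, 14, 50), c(0, 0, 0), c(0.5, 0.5, 0), "knn",
                                 used = c(TRUE, TRUE, TRUE)))
})

test_that("with no censoring the label is a pure threshold rule", {
  set.seed(93)
  for (rep in 1:50) {
    k <- sample(1:5, 1)
    c_os <- runif(k, 1, 40)
    t_os <- runif(1, 1, 40)
    w <- rep(1 / k, k)
    sg <- t_os - sum(w * c_os)
    r <- classify_label(t_os, 0, c_os, rep(0, k), w, threshold = 1e-12)
    expect_equal(r$label, if (sg >= 1e-12) "response" else "non_response")
    expect_equal(r$sg_hat, sg)
  }
})

test_that("variance estimators evaluate to their closed forms", {
  # within-set: s2 = var(10, 14) = 8, V = (1/4 + 1/4) * 8 = 4
  expect_equal(estimate_variance(c(10, 14), c(0, 0), c(0.5, 0.5), "knn"), 4)
  # crude one-by-one: variance of the full control pool
  expect_equal(estimate_variance(10, 0, 1, "one_by_one_crude",
                                 full_control_os = c(10, 14)), 8)
  # identical matched OS values give zero variance
  expect_equal(estimate_variance(rep(12, 3), rep(0, 3), rep(1 / 3, 3), "knn"), 0)
  # a single retained control leaves the local variance undefined
  expect_true(is.na(estimate_variance(c(10, 14), c(0, 1), c(0.5, 0.5), "knn")))
  # full-pool scope swaps in the control-group variance as s2
  expect_equal(estimate_variance(c(10, 14), c(0, 0), c(0.5, 0.5), "knn",
                                 full_control_os = c(2, 30, 10, 14),
                                 scope = "full"),
               0.5 * var(c(2, 30, 10, 14)))
})

test_that("estimate_all ties labels, gains and variances together", {
  # no censoring anywhere: no undetermined labels
  coh <- simulate_cohort(300, "low", prop_treated = 0.3, p_censor = 0,
                         seed = 95, n_calib = 2000)
  fit <- fit_ps(coh)
  m <- nn_match(fit$ps_hat[coh$z == 1], fit$ps_hat[coh$z == 0], k = 5,
                treated_ids = coh$id[coh$z == 1], control_ids = coh$id[coh$z == 0])
  est <- estimate_all(coh, m, threshold = 3)
  expect_equal(nrow(est), sum(coh$z == 1))
  expect_false(any(est$label == "undetermined"))
  expect_false(any(is.na(est$sg_hat)))
  expect_equal(est$n_controls_used, rep(5L, nrow(est)))
  # everyone censored: every label undetermined, every estimate undefined
  coh2 <- coh
  coh2$censored <- 1
  est2 <- estimate_all(coh2, m, threshold = 3)
  expect_true(all(est2$label == "undetermined"))
  expect_true(all(is.na(est2$sg_hat)))
  expect_true(all(is.na(est2$v_hat)))
})
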