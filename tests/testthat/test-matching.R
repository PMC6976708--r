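# Matching schemes: greedy k-NN with replacement, exponential distance
# weights, and the complex bootstrap.

test_that("k-NN picks the nearest controls with uniform weights", {
  m <- nn_match(0.50, c(0.40, 0.45, 0.80), k = 2)[[1]]
  expect_equal(m$control_ids, c(2L, 1L))        # distances 0.05, 0.10
  expect_equal(m$distances, c(0.05, 0.10))
  expect_equal(m$weights, c(0.5, 0.5))
  expect_error(nn_match(0.5, c(0.4, 0.6), k = 3), "exceeds", class = "sgmatch_k_too_large")
  expect_error(nn_match(0.5, c(0.4, 0.6), k = 0), class = "sgmatch_bad_k")
})

test_that("equidistant ties go to the smaller control identifier", {
  m <- nn_match(0.50, c(0.40, 0.60), k = 1)[[1]]
  expect_equal(m$control_ids, 1L)
  # same tie with explicit non-positional ids
  m2 <- nn_match(0.50, c(0.60, 0.40), k = 1, control_ids = c(7L, 9L))[[1]]
  expect_equal(m2$control_ids, 7L)
})

test_that("controls can be reused across treated units but not within a set", {
  m <- nn_match(c(0.30, 0.31, 0.32), c(0.30, 0.90, 0.91), k = 2)
  shared <- vapply(m, function(s) 1L %in% s$control_ids, TRUE)
  expect_true(all(shared))                       # with replacement across sets
  for (s in m) expect_false(any(duplicated(s$control_ids)))
})

test_that("exponential weights match their closed form and limits", {
  w <- exp_weights(c(0, 1), alpha = 5)
  expect_equal(w, c(1 / (1 + exp(-5)), exp(-5) / (1 + exp(-5))), tolerance = 1e-12)
  expect_equal(w, c(0.99330714907571527, 0.00669285092428473), tolerance = 1e-12)
  expect_equal(exp_weights(rep(0.3, 4), alpha = 5), rep(0.25, 4))  # equal distances
  expect_equal(exp_weights(c(0.1, 0.5, 0.9), alpha = 0), rep(1 / 3, 3))  # alpha = 0
  expect_error(exp_weights(numeric(0)), class = "sgmatch_empty_distances")
  expect_error(exp_weights(c(0.2, 1.4)), class = "sgmatch_bad_distance")
})

test_that("exponential weights are permutation-equivariant and distance-monotone", {
  set.seed(71)
  for (i in 1:25) {
    d <- runif(sample(2:8, 1))
    w <- exp_weights(d, alpha = 5)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    perm <- sample(length(d))
    expect_equal(exp_weights(d[perm], 5), w[perm], tolerance = 1e-14)
    expect_equal(order(d), order(w, decreasing = TRUE))  # closer never lighter
  }
})

test_that("the bootstrap scheme pools b one-by-one matches per treated unit", {
  coh <- simulate_cohort(150, "low", prop_treated = 0.25, seed = 81,
                         n_calib = 2000)
  m <- bootstrap_match(coh, b = 7, seed = 5)
  expect_length(m, sum(coh$z == 1))
  ctrl_ids <- coh$id[coh$z == 0]
  for (s in m) {
    expect_length(s$control_ids, 7L)
    expect_equal(s$weights, rep(1 / 7, 7))
    expect_equal(s$replicate, 1:7)
    expect_true(all(s$control_ids %in% ctrl_ids))
  }
  # repeats within one pooled set are allowed and do occur somewhere
  expect_true(any(vapply(m, function(s) any(duplicated(s$control_ids)), TRUE)))
  # determinism
  m2 <- bootstrap_match(coh, b = 7, seed = 5)
  expect_identical(lapply(m, `[[`, "control_ids"), lapply(m2, `[[`, "control_ids"))
})

test_that("a single-control pool degenerates to b copies of that control", {
  coh <- toy_cohort(z = c(1, 1, 0), os = c(20, 25, 10), cens = c(0, 0, 0))
  m <- bootstrap_match(coh, b = 4, seed = 1)
  for (s in m) {
    expect_equal(s$control_ids, rep(3, 4))
    expect_equal(s$weights, rep(0.25, 4))
  }
})

test_that("b = 1 bootstrap is one-by-one matching on one resampled pool", {
  coh <- simulate_cohort(120, "low", prop_treated = 0.25, seed = 83,
                         n_calib = 2000)
  m <- bootstrap_match(coh, b = 1, seed = 9)
  for (s in m) {
    expect_length(s$control_ids, 1L)
    expect_equal(s$weights, 1)
  }
})
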