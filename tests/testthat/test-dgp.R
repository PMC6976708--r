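# Data-generating process: coefficient patterns, Weibull inversion,
# treatment assignment, censoring and ground-truth summaries.

test_that("scenario coefficient ladders follow the three heterogeneity patterns", {
  vw <- log(1.25); w <- log(1.5); m <- log(2); s <- log(4); vs <- log(8)
  low <- make_scenario("low")
  expect_equal(unname(low$treat_coeffs), c(vw, w, vw, w, vw, w, m))
  expect_equal(unname(low$outcome_coeffs), c(w, vw, w, m, vw, w, vw))
  med <- make_scenario("medium")
  expect_equal(unname(med$treat_coeffs), c(w, m, s, w, m, s, vs))
  expect_equal(unname(med$outcome_coeffs), c(w, m, s, vs, w, m, s))
  high <- make_scenario("high")
  expect_equal(unname(high$treat_coeffs), c(m, s, m, s, m, s, vs))
  expect_equal(unname(high$outcome_coeffs), c(s, m, s, vs, m, s, m))
  # conditional hazard ratio is 0.8 in every scenario
  for (lev in c("low", "medium", "high")) {
    expect_equal(exp(make_scenario(lev)$beta_treat), 0.8)
  }
  expect_error(make_scenario("extreme"), "unknown heterogeneity")
})

test_that("covariate generation has the right moments, shape and determinism", {
  X <- generate_covariates(1000, seed = 101)
  expect_equal(dim(X), c(1000L, 10L))
  expect_true(all(abs(colMeans(X)) < 0.1))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 0.1))
  expect_identical(X, generate_covariates(1000, seed = 101))
  expect_error(generate_covariates(0), "positive count")
  Xb <- generate_covariates(500, seed = 1, dist = "bernoulli")
  expect_true(all(Xb %in% c(0, 1)))
})

test_that("the Weibull inversion matches its closed form and is monotone", {
  # direct evaluation: u = e^-1, LP = 0, lambda = 2e-5 -> sqrt(50000)
  expect_equal(sgmatch:::weibull_os(exp(-1), 0, 2e-5), sqrt(50000))
  expect_equal(sgmatch:::weibull_os(exp(-1), 0, 2e-5), 223.60679774997896, tolerance = 1e-12)
  # strictly decreasing in LP at fixed u, and in u at fixed LP
  u <- 0.37
  lps <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(sgmatch:::weibull_os(u, lps, 2e-5)) < 0))
  us <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(sgmatch:::weibull_os(us, 0, 2e-5)) < 0))
  # u -> 1 drives survival to 0
  expect_lt(sgmatch:::weibull_os(1 - 1e-12, 0, 2e-5), 2)
})

test_that("potential outcomes share u and keep the exact counterfactual ratio", {
  scen <- make_scenario("medium")
  X <- generate_covariates(500, seed = 7)
  z <- assign_treatment(X, scen, seed = 8)$z
  srv <- generate_survival(X, z, scen, seed = 9)
  expect_equal(srv$os1 / srv$os0, rep(0.8^(-1 / 2), 500), tolerance = 1e-10)
  expect_equal(srv$os_obs, ifelse(z == 1, srv$os1, srv$os0))
  expect_equal(srv$sg_true, srv$os1 - srv$os0)
  expect_true(all(srv$sg_true > 0))  # beta_treat < 0 makes every gain positive
  # the generator reproduces the printed transform: re-derive u from os0
  u <- exp(-2e-5 * exp(drop(X[, 4:10] %*% scen$outcome_coeffs)) * srv$os0^2)
  expect_equal(srv$os1, sgmatch:::weibull_os(u, drop(X[, 4:10] %*% scen$outcome_coeffs) +
                                               scen$beta_treat, 2e-5),
               tolerance = 1e-8)
})

test_that("treatment assignment follows the logistic propensity", {
  scen <- make_scenario("low")
  scen$treat_coeffs[] <- 0
  X <- generate_covariates(200, seed = 3)
  out <- assign_treatment(X, scen, seed = 4)
  expect_equal(out$p_true, rep(0.5, 200))  # all-zero coefficients, intercept 0
  scen$treat_intercept <- -30
  expect_true(all(assign_treatment(X, scen, seed = 5)$z == 0))
})

test_that("intercept calibration hits its target and closes the loop", {
  scen <- make_scenario("low")
  # symmetry: mean-zero covariates put the 50% intercept at ~0
  expect_lt(abs(calibrate_intercept(scen, 0.5, n_calib = 20000, seed = 11)), 0.05)
  # closure: re-simulating 100,000 subjects at the calibrated intercept
  # recovers the target treated proportion
  a0 <- calibrate_intercept(scen, 0.2, n_calib = 100000, seed = 12)
  scen$treat_intercept <- a0
  X <- generate_covariates(100000, seed = 13)
  z <- assign_treatment(X, scen, seed = 14)$z
  expect_gt(mean(z), 0.19)
  expect_lt(mean(z), 0.21)
  expect_error(calibrate_intercept(scen, 1.0), "strictly inside")
})

test_that("censoring is an independent status flag at the requested rate", {
  expect_true(all(apply_censoring(100, 0, seed = 1) == 0))
  expect_true(all(apply_censoring(100, 1, seed = 1) == 1))
  flags <- apply_censoring(100000, 0.2, seed = 2)
  expect_gt(mean(flags), 0.19)
  expect_lt(mean(flags), 0.21)
  expect_error(apply_censoring(10, 1.2), "\\[0, 1\\]")
})

test_that("simulate_cohort is deterministic, schema-complete and truthful", {
  a <- simulate_cohort(300, "high", prop_treated = 0.3, p_censor = 0.2,
                       seed = 21, n_calib = 5000)
  b <- simulate_cohort(300, "high", prop_treated = 0.3, p_censor = 0.2,
                       seed = 21, n_calib = 5000)
  expect_identical(a, b)
  expect_true(all(c("id", "z", "os_months", "censored", "os1", "os0",
                    "sg_true", "ps_true", paste0("x", 1:10)) %in% names(a)))
  expect_true(all(a$ps_true > 0 & a$ps_true < 1))
  expect_equal(a$os_months, ifelse(a$z == 1, a$os1, a$os0))
})

test_that("truth summaries cover the degenerate and generic cases", {
  coh <- simulate_cohort(2000, "low", seed = 31)
  ts <- truth_summary(coh)
  expect_gt(ts$true_ate, 0)
  expect_gt(ts$true_variance, 0)
  # beta_treat = 0 collapses both potential outcomes
  scen <- make_scenario("low")
  scen$beta_treat <- 0
  X <- generate_covariates(50, seed = 1)
  srv <- generate_survival(X, rep(1, 50), scen, seed = 2)
  expect_equal(srv$sg_true, rep(0, 50))
  # constant gains give zero variance
  toy <- toy_cohort(z = c(1, 1, 0), os = c(10, 12, 9), cens = c(0, 0, 0))
  toy$sg_true <- c(5, 5, NA)
  ts2 <- truth_summary(toy)
  expect_equal(ts2$true_ate, 5)
  expect_equal(ts2$true_variance, 0)
  expect_error(truth_summary(toy[c(1, 3), ]), "at least 2 treated")
})
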