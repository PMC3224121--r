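test_that("trapezoid rule integrates ladders correctly", {
  expect_equal(trapezoid_integral(c(0, 0.5, 1), c(0, 1, 2)), 1.0)
  expect_equal(trapezoid_integral(seq(0, 1, 0.25), rep(-7, 5)), -7)
  # C = 6 agrees with a dense ladder within 1% on a smooth curve
  u <- function(b) -5 + 3 * b - 4 * b^2
  b6 <- seq(0, 1, length.out = 6)
  b101 <- seq(0, 1, length.out = 101)
  coarse <- trapezoid_integral(b6, u(b6))
  dense <- trapezoid_integral(b101, u(b101))
  expect_lt(abs(coarse - dense) / abs(dense), 0.01)
  expect_error(trapezoid_integral(c(1, 0), c(1, 2)),
               class = "bd_validation_error")
})

test_that("Bezier first-interval integral matches hand evaluation", {
  expect_equal(bezier_first_interval(0, 0.2, 0.4, -10, -2, -1), -0.588,
               tolerance = 1e-12)
  # flat curve: the integral is just c * width
  expect_equal(bezier_first_interval(0, 0.25, 0.5, -3, -3, -3), -0.75)
  # on the steep near-exponential shapes the first interval actually has,
  # the spline is far closer to the true integral than the trapezoid
  u <- function(b) -500 * exp(-50 * b) + 186
  truth <- stats::integrate(u, 0, 0.2)$value
  bez <- bezier_first_interval(0, 0.2, 0.4, u(0), u(0.2), u(0.4))
  trap <- trapezoid_integral(c(0, 0.2), c(u(0), u(0.2)))
  expect_lt(abs(bez - truth), abs(trap - truth) / 10)
  expect_error(bezier_first_interval(0, 0.2, 0.2, 1, 2, 3),
               class = "bd_validation_error")
})

test_that("beta ladders are evenly spaced over [0, 1]", {
  expect_equal(beta_ladder(6), c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(diff(beta_ladder(11)), rep(0.1, 10))
  expect_error(beta_ladder(2), class = "bd_validation_error")
})

test_that("a constant-likelihood model integrates to that constant", {
  b <- beta_ladder(6)
  u <- rep(-123.4, 6)
  expect_equal(bayesbd:::.integrate_ladder(b, u), -123.4, tolerance = 1e-12)
})

test_that("Bayes factors follow the 2(M1 - M0) scale and labels", {
  bf <- bayes_factor(-100, -103)
  expect_equal(bf$bf, 6)
  expect_equal(bf$label, "strong")
  expect_equal(bayes_factor(-100, -100)$bf, 0)
  expect_equal(bayes_factor(-100, -100)$label, "weak")
  expect_equal(bayes_factor(-101.5, -100)$label, "positive")
  expect_equal(bayes_factor(-103, -100)$bf, -bayes_factor(-100, -103)$bf)
})

test_that("models with different prior bounds are refused", {
  tr <- tree_sample(sim_bd_tree(15, 1, seed = 50))
  cfg <- chain_config(ngen = 4000, sampfreq = 10, seed = 51)
  m1 <- marginal_likelihood(model_spec("pb"), tr, beta_ladder(4), cfg)
  m2 <- marginal_likelihood(model_spec("pb",
                                       priors = prior_spec(rate_max = 5)),
                            tr, beta_ladder(4), cfg)
  expect_error(bayes_factor(m1, m2), "prior bounds",
               class = "bd_validation_error")
})

test_that("Bayes factors are far more accurate than absolute marginal likelihoods", {
  # the steep first-interval bias of the six-class ladder largely cancels
  # between models compared on the same tree and priors
  tr <- sim_bd_tree(100, 0.5, 0.45, seed = 58)
  bt <- branching_times(tr)
  ts <- tree_sample(tr)
  cfg <- chain_config(seed = 59)
  ml_bd <- marginal_likelihood(model_spec("bd"), ts, beta_ladder(6), cfg)
  ml_pb <- marginal_likelihood(model_spec("pb"), ts, beta_ladder(6), cfg)
  bf_tdi <- 2 * (ml_bd$logml - ml_pb$logml)
  bf_quad <- 2 * (oracle_bd_logml(bt) - oracle_pb_logml(bt))
  bias_pb <- abs(ml_pb$logml - oracle_pb_logml(bt))
  expect_gt(bias_pb, 2)                      # absolute value is biased ...
  expect_lt(abs(bf_tdi - bf_quad), 8)        # ... the comparison is usable
})

test_that("marginal likelihood machinery is reproducible and stable in the seed", {
  tr <- tree_sample(sim_bd_tree(25, 1, seed = 52))
  cfg <- chain_config(ngen = 20000, sampfreq = 20, seed = 53)
  ml1 <- marginal_likelihood(model_spec("pb"), tr, beta_ladder(6), cfg)
  ml2 <- marginal_likelihood(model_spec("pb"), tr, beta_ladder(6), cfg)
  expect_identical(ml1$logml, ml2$logml)
  expect_length(ml1$u, 6)
  expect_true(is.finite(ml1$logml))
  # seed-to-seed spread stays within Monte-Carlo error (2 SE over seeds)
  mls <- vapply(1:6, function(s) {
    cfg_s <- chain_config(ngen = 20000, sampfreq = 20, seed = 60 + s)
    marginal_likelihood(model_spec("pb"), tr, beta_ladder(6), cfg_s)$logml
  }, 0)
  expect_lt(max(mls) - min(mls), 6 * sd(mls))  # no outlier seeds
  expect_lt(sd(mls), 1)
})
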