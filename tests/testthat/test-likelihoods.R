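test_that("birth-death likelihood matches hand and oracle evaluations", {
  bt <- branching_times(c(2, 1))
  # (s-1)! lambda^{s-2} e^{lambda x_3} prod e^{-2 lambda x_i} at mu = 0
  expect_equal(pb_loglik(bt, 0.5), -2.5, tolerance = 1e-12)
  expect_equal(bd_loglik(bt, 0.5, 0.25),
               oracle_bd_loglik(c(2, 1), 0.5, 0.25), tolerance = 1e-10)
  set.seed(1)
  for (i in 1:20) {
    x <- sort(runif(sample(2:8, 1), 0.1, 5), decreasing = TRUE)
    lam <- runif(1, 0.2, 2)
    mu <- runif(1, 0, 0.9) * lam
    expect_equal(bd_loglik(x, lam, mu), oracle_bd_loglik(x, lam, mu),
                 tolerance = 1e-10)
  }
})

test_that("pure-birth is the mu = 0 reduction and scales correctly", {
  set.seed(2)
  for (i in 1:10) {
    x <- sort(runif(6, 0.1, 8), decreasing = TRUE)
    lam <- runif(1, 0.1, 3)
    expect_identical(pb_loglik(x, lam), bd_loglik(x, lam, 0))
    # doubling all times with lambda halved changes log L by -(s-2) log 2
    s <- length(x) + 1
    expect_equal(pb_loglik(2 * x, lam / 2) - pb_loglik(x, lam),
                 -(s - 2) * log(2), tolerance = 1e-10)
  }
  # log-concavity in log(lambda): unique maximum
  bt <- branching_times(sim_bd_tree(30, 0.5, seed = 4))
  ll <- vapply(exp(seq(log(0.01), log(5), length.out = 200)),
               function(l) pb_loglik(bt, l), 0)
  expect_equal(sum(diff(sign(diff(ll))) != 0), 1)
})

test_that("sampled likelihood reduces at rho = 1 and matches the p1 oracle", {
  bt <- branching_times(c(3, 2.2, 0.9))
  expect_identical(bd_loglik_sampled(bt, 0.8, 0.3, 1), bd_loglik(bt, 0.8, 0.3))
  # rho < 1: compare log-likelihood *differences* (the two density
  # conventions differ by a parameter-independent constant)
  x <- c(3, 2.2, 0.9)
  for (rho in c(0.25, 0.5, 0.75)) {
    d_pkg <- bd_loglik_sampled(x, 0.8, 0.3, rho) -
      bd_loglik_sampled(x, 0.5, 0.1, rho)
    d_orc <- oracle_sampled_loglik(x, 0.8, 0.3, rho) -
      oracle_sampled_loglik(x, 0.5, 0.1, rho)
    expect_equal(d_pkg, d_orc, tolerance = 1e-10)
    # and the constant offset is exactly -log(rho)
    expect_equal(bd_loglik_sampled(x, 0.8, 0.3, rho) -
                   oracle_sampled_loglik(x, 0.8, 0.3, rho), -log(rho),
                 tolerance = 1e-10)
  }
  expect_error(bd_loglik_sampled(x, 0.8, 0.3, 0), class = "bd_validation_error")
  expect_error(bd_loglik(x, 0.5, 0.6), class = "bd_validation_error")
})

test_that("declining-speciation likelihood has the right limits", {
  x <- c(2, 1)
  # k = 0, mu0 = 0: exactly pure birth, any z
  expect_equal(spvar_loglik(x, 0.5, 0, 0, z = 1e4), pb_loglik(x, 0.5),
               tolerance = 1e-9)
  # k = 0, z very large: constant-rate birth-death
  expect_equal(spvar_loglik(x, 0.5, 0.25, 0, z = 1e9),
               bd_loglik(x, 0.5, 0.25), tolerance = 1e-6)
  bt100 <- branching_times(sim_bd_tree(100, 0.5, seed = 6))
  expect_equal(spvar_loglik(bt100, 0.5, 0.25, 0, z = 1e9),
               bd_loglik(bt100, 0.5, 0.25), tolerance = 1e-6)
  # at z = 1e4 the extinction rate is *not* yet constant: the analytic gap
  # is O(s * mu0 / z), not zero
  gap <- abs(spvar_loglik(bt100, 0.5, 0.25, 0, z = 1e4) -
               bd_loglik(bt100, 0.5, 0.25))
  expect_lt(gap, 2 * bt100$s * 0.25 / 1e4)
  expect_gt(gap, 1e-6)
})

test_that("declining-speciation likelihood matches an adaptive-quadrature oracle", {
  set.seed(3)
  for (i in 1:5) {
    x <- sort(runif(7, 0.2, 6), decreasing = TRUE)
    l0 <- runif(1, 0.5, 4)
    k <- runif(1, 0, 1)
    m0 <- runif(1, 0, 0.3)
    expect_equal(spvar_loglik(x, l0, m0, k, z = 100),
                 oracle_spvar_loglik(x, l0, m0, k, z = 100),
                 tolerance = 1e-8)
  }
})

test_that("shift pure-birth equals the brute-force frame decomposition", {
  expect_equal(pb_shift_loglik(c(2, 1), c(0.2, 0.8), 1.5),
               oracle_pb_shift_loglik(c(2, 1), c(0.2, 0.8), 1.5),
               tolerance = 1e-10)
  set.seed(4)
  for (i in 1:10) {
    x <- sort(runif(9, 0.1, 10), decreasing = TRUE)
    n <- sample(1:3, 1)
    sh <- sort(runif(n, 0.05, x[1] - 0.05))
    lam <- runif(n + 1, 0.1, 2)
    expect_equal(pb_shift_loglik(x, lam, sh),
                 oracle_pb_shift_loglik(x, lam, sh), tolerance = 1e-10)
  }
})

test_that("shift pure-birth reduces to constant rate and ignores dummy shifts", {
  bt <- branching_times(sim_bd_tree(40, 0.6, seed = 7))
  expect_equal(pb_shift_loglik(bt, 0.6), pb_loglik(bt, 0.6),
               tolerance = 1e-12)
  expect_equal(pb_shift_loglik(bt, c(0.6, 0.6), bt$root_age / 2),
               pb_loglik(bt, 0.6), tolerance = 1e-12)
  # a dummy shift splitting a frame with equal rates on both sides of the
  # new boundary changes nothing
  expect_equal(pb_shift_loglik(bt, c(0.3, 0.9, 0.9), c(1, 2)),
               pb_shift_loglik(bt, c(0.3, 0.9), 2), tolerance = 1e-12)
  expect_error(pb_shift_loglik(bt, c(1, 2, 3), c(2, 1)),
               class = "bd_validation_error")
  expect_error(pb_shift_loglik(bt, c(1, 2), bt$root_age + 1),
               class = "bd_validation_error")
})

test_that("clade joint likelihood composes per-clade terms", {
  bt <- branching_times(c(2, 1))
  clades <- list(list(label = "A", bt = bt, rho = 1),
                 list(label = "B", bt = bt, rho = 1))
  single <- bd_loglik(bt, 0.7, 0.2)
  expect_equal(clade_joint_loglik(clades, list(lambda = 0.7, mu = 0.2)),
               2 * single, tolerance = 1e-12)
  # unlinked with distinct parameters
  two <- clade_joint_loglik(clades, list(list(lambda = 0.7, mu = 0.2),
                                         list(lambda = 1.1, mu = 0)))
  expect_equal(two, single + pb_loglik(bt, 1.1), tolerance = 1e-12)
  expect_error(clade_joint_loglik(clades, list(list(lambda = 1)),
                                  grouping = c(1, 3)),
               class = "bd_validation_error")
})

test_that("log-space evaluation survives very large trees and deep roots", {
  set.seed(8)
  x <- sort(c(1000, runif(9998, 0.001, 1000)), decreasing = TRUE)
  expect_true(is.finite(bd_loglik(x, 0.05, 0.02)))
  expect_true(is.finite(pb_shift_loglik(x, c(0.02, 0.05), 300)))
})
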