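test_that("reflected-normal proposals fold at the boundaries", {
  # raw values outside the interval reflect back inside
  expect_equal(bayesbd:::.reflect_cpp(-0.05, 0, 1), 0.05)
  expect_equal(bayesbd:::.reflect_cpp(1.2, 0, 1), 0.8)
  expect_equal(bayesbd:::.reflect_cpp(-2.3, 0, 1), 0.3)  # double fold
  expect_equal(bayesbd:::.reflect_cpp(0.4, 0, 1), 0.4)
  set.seed(10)
  prop <- replicate(2000, propose_reflected_normal(0.9, 0.5, 0, 1))
  expect_true(all(prop >= 0 & prop <= 1))
  expect_error(propose_reflected_normal(0.5, -1, 0, 1),
               class = "bd_validation_error")
  expect_error(propose_reflected_normal(2, 0.1, 0, 1),
               class = "bd_validation_error")
})

test_that("reflected proposal density matches the folded normal (chi-square)", {
  set.seed(11)
  cur <- 0.3
  sc <- 0.4
  n <- 1e5
  prop <- replicate(n, propose_reflected_normal(cur, sc, 0, 1))
  brk <- seq(0, 1, by = 0.05)
  obs <- table(cut(prop, brk))
  # folded-normal density via image points of the reflection group on [0,1]
  foldp <- function(lo, hi) {
    p <- 0
    for (k in -6:6) {
      p <- p + (pnorm(2 * k + hi, cur, sc) - pnorm(2 * k + lo, cur, sc))
      p <- p + (pnorm(2 * k + 2 - lo, cur, sc) - pnorm(2 * k + 2 - hi, cur, sc))
    }
    p
  }
  expp <- vapply(seq_len(length(brk) - 1), function(i)
    foldp(brk[i], brk[i + 1]), 0)
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = expp / sum(expp)))
  expect_gt(chi$p.value, 0.01)
})

test_that("log-scale proposals are symmetric in log space", {
  set.seed(12)
  prop <- replicate(2e4, propose_logscale(1, 0.3))
  expect_equal(median(prop), 1, tolerance = 0.05)
  expect_true(all(log(prop) >= -2.3 & log(prop) <= 2.3))
  # at the boundary the log-proposal reflects inward
  at_edge <- replicate(2e3, propose_logscale(exp(2.3), 0.2))
  expect_true(all(log(at_edge) <= 2.3))
  expect_error(propose_logscale(-1, 0.1), class = "bd_validation_error")
})

test_that("mh_step accepts uphill moves and respects tempering", {
  ll <- function(th) dnorm(th, 2, 0.5, log = TRUE)
  set.seed(13)
  # uphill with flat prior and beta = 1: always accepted
  out <- mh_step(current = 0, proposal = 2, loglik = ll, beta = 1)
  expect_true(out$accepted)
  expect_equal(out$state, 2)
  # beta = 0: acceptance is independent of the likelihood
  acc <- replicate(500, mh_step(0, 5, ll, beta = 0)$accepted)
  expect_true(all(acc))
})

test_that("a two-state toy chain reaches its analytic stationary law", {
  # states 1 and 2 with likelihood ratio 3: expected occupancy 1:3
  ll <- function(s) log(c(1, 3)[s])
  set.seed(14)
  s <- 1L
  counts <- c(0L, 0L)
  llc <- ll(s)
  for (i in 1:2e5) {
    prop <- 3L - s
    st <- mh_step(s, prop, ll, beta = 1, current_loglik = llc)
    s <- st$state
    llc <- st$loglik
    counts[s] <- counts[s] + 1L
  }
  expect_equal(counts[2] / sum(counts), 0.75, tolerance = 0.01)
})

test_that("the prior chain (beta = 0) samples uniform marginals", {
  tr <- sim_bd_tree(20, 0.5, seed = 15)
  # thin enough that the reflected random walk decorrelates between records
  cfg <- chain_config(ngen = 2e5, sampfreq = 200, burnin = 5000, seed = 16)
  ps <- run_chain_over_trees(tree_sample(tr), model_spec("bd"), cfg, beta = 0)
  ks_r <- suppressWarnings(ks.test(ps$r, "punif", 0, 10))
  ks_a <- suppressWarnings(ks.test(ps$a, "punif", 0, 1))
  expect_gt(ks_r$p.value, 0.001)
  expect_gt(ks_a$p.value, 0.001)
})

test_that("posterior concentrates near the Yule analytic MLE", {
  tr <- sim_bd_tree(100, 0.5, seed = 17)
  bt <- branching_times(tr)
  mle <- (bt$s - 2) / (2 * bt$x[1] + sum(bt$x[-1]))
  ps <- run_chain_over_trees(tree_sample(tr), model_spec("pb"),
                             chain_config(seed = 18))
  expect_lt(abs(mean(ps$lambda) - mle), 3 * sd(ps$lambda))
  # recorded log-likelihoods re-evaluate exactly
  idx <- c(1, nrow(ps) %/% 2, nrow(ps))
  for (i in idx)
    expect_equal(ps$loglik[i], pb_loglik(bt, ps$lambda[i]), tolerance = 1e-9)
})

test_that("chains are deterministic under a fixed seed and mix adequately", {
  trees <- tree_sample(lapply(1:2, function(i) sim_bd_tree(100, 0.5, 0.25,
                                                           seed = 20 + i)))
  cfg <- chain_config(seed = 99)
  ps1 <- run_chain_over_trees(trees, model_spec("bd"), cfg)
  ps2 <- run_chain_over_trees(trees, model_spec("bd"), cfg)
  expect_identical(as.data.frame(ps1), as.data.frame(ps2))
  # default run lengths give the good-mixing regime on 100-tip trees
  expect_gt(attr(ps1, "ess")[["lambda"]], 200)
  # log file is Tracer-compatible: header + tab-separated numeric columns
  tf <- withr::local_tempfile()
  write_tracer_log(ps1, tf, provenance = "test run")
  lines <- readLines(tf)
  expect_true(startsWith(lines[1], "# "))
  expect_equal(strsplit(lines[2], "\t")[[1]][1:3],
               c("state", "treeIndex", "logLik"))
  tab <- read.table(tf, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), nrow(ps1))
})

test_that("pooling over trees preserves or widens credibility intervals", {
  trees <- tree_sample(lapply(1:5, function(i) sim_bd_tree(80, 0.5,
                                                           seed = 30 + i)))
  cfg <- chain_config(ngen = 30000, sampfreq = 50, seed = 31)
  ps <- run_chain_over_trees(trees, model_spec("pb"), cfg)
  pooled_w <- diff(hpd(ps$lambda))
  single_w <- vapply(1:5, function(i) diff(hpd(ps$lambda[ps$tree == i])), 0)
  expect_gte(pooled_w, 0.95 * mean(single_w))
})

test_that("model preconditions abort before any sampling", {
  tr <- sim_bd_tree(10, 1, seed = 40)  # young root
  model <- model_spec("pbshift", nshifts = 1,
                      priors = prior_spec(shift = c(50, 60)))
  expect_error(run_chain_over_trees(tree_sample(tr), model,
                                    chain_config(ngen = 1000, sampfreq = 10)),
               "window", class = "bd_validation_error")
})

test_that("shift-window constraints confine the sampled shift times", {
  tr <- sim_pb_shift_tree(60, c(0.8, 0.2), 3, seed = 41)
  model <- model_spec("pbshift", nshifts = 1,
                      priors = prior_spec(shift = c(2.5, 4)))
  ps <- run_chain_over_trees(tree_sample(tr), model,
                             chain_config(ngen = 20000, sampfreq = 20,
                                          seed = 42))
  expect_true(all(ps$shift_1 >= 2.5 & ps$shift_1 <= 4))
})
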