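# Independent reference implementations used as oracles.  These are kept
# deliberately naive (direct formula evaluation, brute force, adaptive
# quadrature) and separate from the package's compiled code paths.

# direct factor-by-factor evaluation of the constant-rate birth-death
# density (safe for small trees only: works in natural space per factor)
oracle_bd_loglik <- function(x, lambda, mu) {
  s <- length(x) + 1
  r <- lambda - mu
  a <- mu / lambda
  lgamma(s) + (s - 2) * log(r) + r * sum(x[-1]) + s * log(1 - a) -
    2 * sum(log(exp(r * x) - a))
}

# rho-corrected density via the Stadler-style p1 function; differs from the
# package's substitution form by a parameter-independent constant, so use
# differences across parameter values when comparing
oracle_sampled_loglik <- function(x, lambda, mu, rho) {
  s <- length(x) + 1
  r <- lambda - mu
  p1 <- function(t) rho * r^2 * exp(-r * t) /
    (rho * lambda + (lambda * (1 - rho) - mu) * exp(-r * t))^2
  lgamma(s) + (s - 2) * log(lambda) - r * x[1] + sum(log(p1(x)))
}

# brute-force frame decomposition for the shift pure-birth model: counts
# events per frame and integrates the piecewise-constant lineage count over
# the elementary intervals between all breakpoints
oracle_pb_shift_loglik <- function(x, lambdas, shifts) {
  s <- length(x) + 1
  bnds <- c(0, shifts, x[1])
  nlin <- function(t) 1 + sum(x >= t)
  ll <- lgamma(s)
  nf <- length(lambdas)
  for (j in seq_len(nf)) {
    lo <- bnds[nf + 1 - j]        # frame j is oldest-first
    hi <- bnds[nf + 2 - j]
    b <- sum(x[-1] > lo & x[-1] <= hi)
    brk <- sort(unique(c(lo, hi, x[x > lo & x < hi])))
    Tj <- 0
    for (q in seq_len(length(brk) - 1))
      Tj <- Tj + nlin((brk[q] + brk[q + 1]) / 2) * (brk[q + 1] - brk[q])
    ll <- ll + b * log(lambdas[j]) - lambdas[j] * Tj
  }
  ll
}

# independent declining-rates likelihood using stats::integrate
oracle_spvar_loglik <- function(x, l0, m0, k, z) {
  s <- length(x) + 1
  phi <- function(t)
    (if (k > 0) l0 * (1 - exp(-k * t)) / k else l0 * t) -
      (m0 * t - m0 * (1 - exp(-z * t)) / z)
  Ifun <- function(t)
    stats::integrate(function(u) l0 * exp(-k * u + phi(u)), 0, t,
                     rel.tol = 1e-12, abs.tol = 1e-13,
                     subdivisions = 2000L)$value
  ll <- lgamma(s) - phi(x[1])
  for (t in x) ll <- ll + phi(t) - 2 * log1p(Ifun(t))
  for (t in x[-1]) ll <- ll + log(l0) - k * t
  ll
}

# brute-force shortest-window HPD
oracle_hpd <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (j in 1:(n - m + 1))
    if (xs[j + m - 1] - xs[j] < best[2] - best[1])
      best <- c(xs[j], xs[j + m - 1])
  best
}

# analytic log marginal likelihood of the pure-birth model under a uniform
# prior lambda ~ U(0, B): the likelihood is Gamma-shaped in lambda
oracle_pb_logml <- function(bt, B = 10) {
  s <- bt$s
  Tl <- 2 * bt$x[1] + sum(bt$x[-1])
  lgamma(s) + lgamma(s - 1) - (s - 1) * log(Tl) +
    stats::pgamma(B * Tl, s - 1, log.p = TRUE) - log(B)
}

# 2-D grid quadrature of the birth-death marginal likelihood over
# r ~ U(0, B), a ~ U(0, 1), vectorised in log space
oracle_bd_logml <- function(bt, B = 10, nr = 2000, na = 600) {
  x <- bt$x
  s <- bt$s
  rg <- seq(B / (2 * nr), B - B / (2 * nr), length.out = nr)
  ag <- seq(0.5 / na, 1 - 0.5 / na, length.out = na)
  l1a <- log1p(-ag)
  rows <- numeric(nr)
  for (i in seq_len(nr)) {
    r <- rg[i]
    # log(exp(r x) - a) = r x + log1p(-a exp(-r x)), outer over (a, x)
    ee <- exp(-r * x)
    term <- r * sum(x) + rowSums(log1p(-outer(ag, ee)))
    lv <- lgamma(s) + (s - 2) * log(r) + r * sum(x[-1]) + s * l1a - 2 * term
    M <- max(lv)
    rows[i] <- M + log(mean(exp(lv - M)))
  }
  M <- max(rows)
  M + log(sum(exp(rows - M)) * (B / nr)) - log(B)
}

# quick tree builders
nwk <- function(txt) ape::read.tree(text = txt)

balanced4 <- function() nwk("((A:1,B:1):2,(C:2,D:2):1);")
caterpillar3 <- function() nwk("((A:1,B:1):1,C:2);")
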