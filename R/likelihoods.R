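## User-facing diversification log-likelihoods.  All are deterministic pure
## functions of the branching times and the parameters; heavy lifting is in
## compiled code (src/loglik.cpp).

.bt_x <- function(x) {
  bt <- branching_times(x)
  if (bt$s < 2) .verr("need at least 2 tips")
  bt$x
}

#' Constant-rate birth-death log-likelihood
#'
#' Log-likelihood of the branching times under the reconstructed
#' constant-rate birth-death process,
#' \deqn{L = (s-1)!\,(\lambda-\mu)^{s-2}
#'   e^{(\lambda-\mu)\sum_{i=3}^{s} x_i} (1-\mu/\lambda)^{s}
#'   \prod_{i=2}^{s} [e^{(\lambda-\mu) x_i} - \mu/\lambda]^{-2},}
#' computed in log space.  The \eqn{(s-1)!} factor is constant in the
#' parameters and is included so that values are comparable across models on
#' the same tree, as Bayes factors require.
#'
#' @param x a `branching_times` object, a `phylo` tree, or a numeric vector
#'   of node ages.
#' @param lambda speciation rate (events/lineage/Myr), > 0.
#' @param mu extinction rate, with `0 <= mu < lambda`.
#' @param rho sampling fraction in (0, 1]; see [bd_loglik_sampled()].
#' @return the log-likelihood (scalar).
#' @export
bd_loglik <- function(x, lambda, mu, rho = 1) {
  if (!is.numeric(lambda) || lambda <= 0) .verr("lambda must be > 0")
  if (!is.numeric(mu) || mu < 0) .verr("mu must be >= 0")
  if (mu >= lambda) .verr("mu >= lambda is outside the model support")
  if (rho <= 0 || rho > 1) .verr("rho must be in (0, 1]")
  ll <- .bd_loglik_cpp(.bt_x(x), lambda, mu, rho)
  if (!is.finite(ll)) .verr("non-finite birth-death log-likelihood at ",
                            "lambda=", lambda, ", mu=", mu, ", rho=", rho)
  ll
}

#' Pure-birth (Yule) log-likelihood
#'
#' Identical to [bd_loglik()] with `mu = 0`; equivalently the number of
#' post-root branching events times `log(lambda)` minus `lambda` times the
#' total lineage-time, plus the same `(s-1)!` constant.
#'
#' @inheritParams bd_loglik
#' @export
pb_loglik <- function(x, lambda, rho = 1) {
  if (!is.numeric(lambda) || lambda <= 0) .verr("lambda must be > 0")
  bd_loglik(x, lambda, 0, rho)
}

#' Birth-death log-likelihood under incomplete uniform taxon sampling
#'
#' Missing species are modelled as uniformly sampled: only a fraction
#' `rho = s/S` of the true diversity appears in the tree.  The density is
#' evaluated through the exact equivalence of the rho-sampled process with a
#' completely sampled process with `lambda' = rho * lambda` and
#' `mu' = mu - lambda (1 - rho)` (the net diversification is invariant), so
#' at `rho = 1` the value is bit-identical to [bd_loglik()].
#'
#' @inheritParams bd_loglik
#' @export
bd_loglik_sampled <- function(x, lambda, mu, rho) {
  bd_loglik(x, lambda, mu, rho)
}

#' Declining-speciation birth-death log-likelihood
#'
#' Time-varying birth-death model with
#' \eqn{\lambda(t) = \lambda_0 e^{-k t}} and
#' \eqn{\mu(t) = \mu_0 (1 - e^{-z t})}, with t the age before the present.
#' With `k = 0` the speciation rate is constant; with very large `z`
#' (default 10,000) the extinction rate is effectively constant at `mu0`,
#' and the value agrees with [bd_loglik()] to well below 1e-6.  The
#' cumulative rate integral has a closed form; the remaining nested
#' integral is evaluated by fixed-order Gauss-Legendre quadrature on each
#' inter-node segment.
#'
#' @inheritParams bd_loglik
#' @param lambda0 initial speciation rate, > 0.
#' @param mu0 final extinction rate, >= 0.
#' @param k magnitude of the speciation decline (per Myr), >= 0.
#' @param z rate of approach of the extinction rate to `mu0`; large values
#'   make extinction effectively constant.
#' @export
spvar_loglik <- function(x, lambda0, mu0, k, z = 1e4) {
  if (!is.numeric(lambda0) || lambda0 <= 0) .verr("lambda0 must be > 0")
  if (mu0 < 0) .verr("mu0 must be >= 0")
  if (k < 0) .verr("k must be >= 0")
  if (z <= 0) .verr("z must be > 0")
  ll <- .spvar_loglik_cpp(.bt_x(x), lambda0, mu0, k, z)
  if (!is.finite(ll))
    .verr("non-finite declining-speciation log-likelihood at lambda0=",
          lambda0, ", mu0=", mu0, ", k=", k)
  ll
}

#' Pure-birth log-likelihood with rate shifts
#'
#' Pure-birth process whose rate is piecewise constant between `n` shift
#' times.  The log-likelihood is the sum over time frames of
#' `b_j log(lambda_j) - lambda_j T_j`, with `b_j` the branching events and
#' `T_j` the lineage-time inside frame `j`, plus the `(s-1)!` constant.
#' With `n = 0` this equals [pb_loglik()] exactly.
#'
#' @inheritParams bd_loglik
#' @param lambdas per-frame speciation rates, length `n + 1`, oldest frame
#'   first.
#' @param shifts shift ages (Myr before present), strictly increasing,
#'   inside `(0, root age)`; may be empty.
#' @export
pb_shift_loglik <- function(x, lambdas, shifts = numeric(0)) {
  xv <- .bt_x(x)
  n <- length(shifts)
  if (length(lambdas) != n + 1)
    .verr("need length(lambdas) == length(shifts) + 1")
  if (any(lambdas <= 0)) .verr("rates must be > 0")
  if (n > 0) {
    if (is.unsorted(shifts, strictly = TRUE)) .verr("shift times must be ",
                                                    "strictly increasing")
    if (any(shifts <= 0) || any(shifts >= xv[1]))
      .verr("shift times must lie inside (0, root age)")
  }
  .pb_shift_loglik_cpp(xv, as.numeric(lambdas), as.numeric(shifts))
}

#' Joint log-likelihood over predefined clades
#'
#' Sums the per-clade birth-death (or pure-birth) log-likelihoods with each
#' clade's own sampling fraction.  Rates may be shared by all clades
#' (`linked`), free per clade (`unlinked`), or tied through an arbitrary
#' grouping.
#'
#' @param clades list as returned by [clade_branching_times()]: each element
#'   has `bt` (branching times) and `rho`, optionally `label`.
#' @param params a list of parameter sets `list(lambda=, mu=)` (`mu` may be
#'   omitted or 0 for pure-birth), one per group.
#' @param grouping vector mapping each clade to an element of `params` (by
#'   name or index).  Defaults to all clades sharing `params[[1]]` when a
#'   single set is given (linked), or to one set per clade when
#'   `length(params) == length(clades)` (unlinked).
#' @return the joint log-likelihood.
#' @export
clade_joint_loglik <- function(clades, params, grouping = NULL) {
  nc <- length(clades)
  if (!is.list(params[[1]])) params <- list(params)
  if (is.null(grouping)) {
    if (length(params) == 1) grouping <- rep(1L, nc)
    else if (length(params) == nc) grouping <- seq_len(nc)
    else .verr("grouping required when groups differ from clades")
  }
  if (length(grouping) != nc) .verr("grouping must have one entry per clade")
  idx <- if (is.character(grouping)) match(grouping, names(params))
         else as.integer(grouping)
  if (anyNA(idx) || any(idx < 1 | idx > length(params)))
    .verr("grouping refers to an unknown parameter set")
  ll <- 0
  for (i in seq_len(nc)) {
    p <- params[[idx[i]]]
    mu <- if (is.null(p$mu)) 0 else p$mu
    ll <- ll + bd_loglik(clades[[i]]$bt, p$lambda, mu,
                         rho = clades[[i]]$rho)
  }
  ll
}
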