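## Birth-death tree simulation conditioned on the number of extant tips.
##
## Pure-birth schedules (constant or with rate shifts at fixed ages before
## the present) are simulated exactly: a unit-rate conditioned Yule tree is
## drawn in operational time (forward simulation stopped just before the
## (n+1)-st birth, so the time spent with k lineages is Exponential(k)),
## and node ages are mapped through the inverse cumulative intensity of the
## schedule.  Shifts therefore fall exactly at the requested ages.
## Constant-rate birth-death trees with extinction are simulated forward in
## time from two crown lineages until the extant count first reaches n + 1,
## with extinct lineages pruned and bounded rejection of fully extinct
## runs.

# random-join assembly of an ultrametric phylo from node ages
.assemble_tree <- function(ages_desc, tip_prefix = "t") {
  ages <- sort(ages_desc, decreasing = FALSE)  # merge youngest first
  n <- length(ages) + 1L
  # node ids: tips 1..n; merge j gets id 2n - j, so the final merge is n+1
  act_id <- seq_len(n)
  act_age <- numeric(n)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  node_age <- numeric(2L * n - 1L)
  for (j in seq_len(n - 1L)) {
    k <- length(act_id)
    pick <- sample.int(k, 2L)
    pid <- 2L * n - j
    node_age[pid] <- ages[j]
    rows <- c(2L * j - 1L, 2L * j)
    edge[rows, 1L] <- pid
    edge[rows, 2L] <- act_id[pick]
    elen[rows] <- ages[j] - act_age[pick]
    act_id <- c(act_id[-pick], pid)
    act_age <- c(act_age[-pick], ages[j])
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0(tip_prefix, seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

# conditioned unit-rate Yule node ages (operational time): the duration
# with k lineages is Exponential(k), k = 2..n
.yule_unit_ages <- function(n) {
  d <- rexp(n - 1L, rate = 2:n)
  rev(cumsum(rev(d)))  # ages x_2 >= ... >= x_n
}

# cumulative intensity of a piecewise-constant schedule and its inverse.
# lambdas oldest-first, shifts ascending ages; returns function w -> age
.schedule_inverse <- function(lambdas, shifts) {
  rates <- rev(lambdas)                      # recent-first
  knots <- c(0, shifts)                      # age starting each frame
  cum <- c(0, cumsum(rates[seq_len(length(knots) - 1L)] * diff(knots)))
  function(w) {
    j <- findInterval(w, cum)                # frame index (recent-first)
    knots[j] + (w - cum[j]) / rates[j]
  }
}

#' Simulate a constant-rate birth-death tree conditioned on its tip count
#'
#' With `mu = 0` the conditioned pure-birth process is simulated in
#' operational time (waiting time from k to k + 1 lineages is
#' Exponential(k lambda)).  With extinction the default is the exact
#' conditioned reconstructed process (uniform prior on the unobserved
#' origin time): the n - 1 branching times are independent draws with
#' inverse CDF `t(u) = log((lambda - u mu) / (lambda (1 - u))) / r`, and
#' the topology is assembled by random joins.  `method = "forward"`
#' instead simulates the full process forward from two crown lineages
#' until the extant count first reaches `n_tips + 1`, anchors the present
#' just before that birth, prunes extinct lineages and rejects fully
#' extinct runs (bounded).
#'
#' @param n_tips number of extant tips (>= 3).
#' @param lambda speciation rate, must exceed `mu`.
#' @param mu extinction rate, >= 0.
#' @param seed optional seed (caller's RNG state is restored).
#' @param method conditioning scheme when `mu > 0`; see above.
#' @param max_attempts bound on rejection of extinct runs (forward method).
#' @return an ultrametric `phylo` with exactly `n_tips` tips.
#' @export
sim_bd_tree <- function(n_tips, lambda, mu = 0, seed = NULL,
                        method = c("conditioned", "forward"),
                        max_attempts = 10000) {
  method <- match.arg(method)
  if (n_tips < 3) .verr("n_tips must be >= 3")
  if (!(lambda > mu) || mu < 0) .verr("need lambda > mu >= 0")
  .with_seed(seed, {
    if (mu == 0) {
      ages <- .yule_unit_ages(n_tips) / lambda
      .assemble_tree(ages)
    } else if (method == "conditioned") {
      u <- runif(n_tips - 1L)
      ages <- log((lambda - u * mu) / (lambda * (1 - u))) / (lambda - mu)
      .assemble_tree(sort(ages, decreasing = TRUE))
    } else {
      .sim_bd_forward(n_tips, lambda, mu, max_attempts)
    }
  })
}

# forward birth-death simulation from two crown lineages
.sim_bd_forward <- function(n, lambda, mu, max_attempts) {
  pbirth <- lambda / (lambda + mu)
  for (att in seq_len(max_attempts)) {
    cap <- 4L * n + 16L
    parent <- integer(cap)
    btime <- numeric(cap)
    dtime <- rep(NA_real_, cap)
    nl <- 2L                       # lineages 1, 2 born at the crown, t = 0
    alive <- integer(n + 1L)
    alive[1:2] <- 1:2
    nalive <- 2L
    t <- 0
    present <- NA_real_
    repeat {
      t <- t + rexp(1L, nalive * (lambda + mu))
      j <- sample.int(nalive, 1L)
      if (runif(1L) < pbirth) {
        if (nalive == n) {         # present sits just before this birth
          present <- t
          break
        }
        nl <- nl + 1L
        if (nl > cap) {
          cap <- 2L * cap
          parent <- c(parent, integer(cap %/% 2L))
          btime <- c(btime, numeric(cap %/% 2L))
          dtime <- c(dtime, rep(NA_real_, cap %/% 2L))
        }
        parent[nl] <- alive[j]
        btime[nl] <- t
        nalive <- nalive + 1L
        alive[nalive] <- nl
      } else {
        dtime[alive[j]] <- t
        alive[j] <- alive[nalive]
        nalive <- nalive - 1L
        if (nalive == 0L) break    # clade died out: reject and retry
      }
    }
    if (!is.na(present))
      return(.reconstruct_tree(parent[1:nl], btime[1:nl], dtime[1:nl],
                               present))
  }
  .verr("simulation failed: clade went extinct in every attempt")
}

# newick reconstruction of the tree of surviving lineages
.reconstruct_tree <- function(parent, btime, dtime, present) {
  nl <- length(parent)
  surv <- is.na(dtime)
  for (i in nl:1)
    if (surv[i] && parent[i] > 0L) surv[parent[i]] <- TRUE
  kids <- vector("list", nl)
  for (i in seq_len(nl))
    if (parent[i] > 0L && surv[i])
      kids[[parent[i]]] <- c(kids[[parent[i]]], i)  # in birth order
  rec <- function(i, t0) {
    # reconstructed subtree of lineage i's surviving descendants after t0
    ds <- kids[[i]]
    ds <- ds[btime[ds] > t0]
    if (!length(ds))                     # extant with no later splits
      return(list(str = paste0("t", i), time = present))
    d1 <- ds[1L]
    tb <- btime[d1]
    # a reconstructed node exists at tb only if i's own continuation after
    # tb also has surviving descendants; otherwise the branch just passes
    # through to the daughter's subtree
    if (is.na(dtime[i]) || length(ds) > 1L) {
      left <- rec(i, tb)
      right <- rec(d1, tb)
      list(str = paste0("(", left$str, ":",
                        format(left$time - tb, digits = 15), ",",
                        right$str, ":",
                        format(right$time - tb, digits = 15), ")"),
           time = tb)
    } else {
      rec(d1, tb)
    }
  }
  txt <- if (surv[1L] && surv[2L]) {
    l <- rec(1L, 0)
    r <- rec(2L, 0)
    paste0("(", l$str, ":", format(l$time, digits = 15), ",", r$str, ":",
           format(r$time, digits = 15), ");")
  } else {
    paste0(rec(if (surv[1L]) 1L else 2L, 0)$str, ";")
  }
  ape::read.tree(text = txt)
}

#' Simulate a pure-birth tree with rate shifts at fixed ages
#'
#' The per-lineage branching intensity follows a piecewise-constant
#' schedule in age before the present; node ages of a conditioned unit-rate
#' pure-birth tree are mapped through the inverse cumulative intensity, so
#' the shifts fall exactly at the requested ages and the tree has exactly
#' `n_tips` tips.
#'
#' @inheritParams sim_bd_tree
#' @param lambdas per-frame rates, length `length(shift_times) + 1`, oldest
#'   frame first.
#' @param shift_times strictly increasing shift ages (Myr before present).
#' @export
sim_pb_shift_tree <- function(n_tips, lambdas, shift_times, seed = NULL) {
  if (n_tips < 3) .verr("n_tips must be >= 3")
  if (any(lambdas <= 0)) .verr("rates must be > 0")
  if (length(lambdas) != length(shift_times) + 1)
    .verr("need length(lambdas) == length(shift_times) + 1")
  if (length(shift_times) &&
      (is.unsorted(shift_times, strictly = TRUE) || any(shift_times <= 0)))
    .verr("shift times must be positive and strictly increasing")
  .with_seed(seed, {
    w <- .yule_unit_ages(n_tips)
    inv <- .schedule_inverse(lambdas, shift_times)
    .assemble_tree(inv(w))
  })
}

#' Prune a tree to a random subset of its tips
#'
#' Retains `round(rho * s)` uniformly chosen tips and drops the rest,
#' preserving branch lengths (the standard emulation of incomplete uniform
#' taxon sampling).
#'
#' @inheritParams sim_bd_tree
#' @param tree a `phylo`.
#' @param rho fraction of tips to keep, in (0, 1].
#' @export
subsample_tips <- function(tree, rho, seed = NULL) {
  if (rho <= 0 || rho > 1) .verr("rho must be in (0, 1]")
  if (rho == 1) return(tree)
  s <- ape::Ntip(tree)
  keep_n <- round(rho * s)
  if (keep_n < 3) .verr("subsampling would leave fewer than 3 tips")
  .with_seed(seed, {
    keep <- sample(tree$tip.label, keep_n)
    ape::keep.tip(tree, keep)
  })
}

#' Simulate a staged approximation of exponentially declining speciation
#'
#' Builds a piecewise-constant schedule with `n_shifts` equally spaced
#' shift ages spanning the expected crown age, with each epoch's rate equal
#' to `lambda0 * exp(-k * t_mid)` at the epoch midpoint, and simulates a
#' pure-birth tree under that schedule (constant extinction `mu > 0` uses
#' an approximate forward simulation anchored at the expected span).  The
#' expected crown age solves `lambda0 (1 - e^{-kT}) / k = H_n - 1` (the
#' expected operational-time root age of the conditioned process); if no
#' solution exists the decline is too fast for the requested tip count.
#'
#' @inheritParams sim_bd_tree
#' @param lambda0 initial speciation rate.
#' @param k exponential decline of the speciation rate (per Myr).
#' @param n_shifts number of equally spaced shifts (default nine).
#' @export
sim_spvar_approx <- function(n_tips, lambda0, mu = 0, k, seed = NULL,
                             n_shifts = 9) {
  if (n_tips < 3) .verr("n_tips must be >= 3")
  if (!(lambda0 > 0) || k < 0 || mu < 0) .verr("invalid rates")
  if (k == 0) return(sim_bd_tree(n_tips, lambda0, mu, seed = seed))
  target <- sum(1 / (2:n_tips))            # expected unit-rate root age
  if (target * k >= lambda0)
    .verr("decline too fast: expected span infeasible for ", n_tips,
          " tips (lambda0/k = ", format(lambda0 / k), " < H_n - 1 = ",
          format(target), ")")
  T_span <- -log(1 - target * k / lambda0) / k
  ne <- n_shifts + 1L
  shifts <- seq_len(n_shifts) * T_span / ne
  mids <- (seq_len(ne) - 0.5) * T_span / ne      # recent-first midpoints
  lams <- rev(lambda0 * exp(-k * mids))          # oldest-first
  if (mu == 0) {
    sim_pb_shift_tree(n_tips, lams, shifts, seed = seed)
  } else {
    if (any(lams <= mu)) .verr("mu exceeds an epoch speciation rate")
    .with_seed(seed, .sim_bd_forward_schedule(n_tips, lams, shifts, mu,
                                              anchor = T_span))
  }
}

# forward birth-death with piecewise-constant birth rate indexed by age
# before an anchored present; approximate in that the realised present
# drifts from the anchor by the stopping time.  Thinning on max(lambda).
.sim_bd_forward_schedule <- function(n, lambdas, shifts, mu, anchor,
                                     max_attempts = 10000) {
  lmax <- max(lambdas)
  rate_at_age <- function(age) {
    if (age <= 0) return(lambdas[length(lambdas)])
    j <- findInterval(age, shifts)       # 0 = youngest frame
    rev(lambdas)[j + 1L]
  }
  for (att in seq_len(max_attempts)) {
    cap <- 4L * n + 16L
    parent <- integer(cap); btime <- numeric(cap)
    dtime <- rep(NA_real_, cap)
    nl <- 2L; alive <- integer(n + 1L); alive[1:2] <- 1:2; nalive <- 2L
    t <- 0; present <- NA_real_
    repeat {
      t <- t + rexp(1L, nalive * (lmax + mu))
      u <- runif(1L)
      lam_t <- rate_at_age(anchor - t)
      if (u < lam_t / (lmax + mu)) {
        if (nalive == n) { present <- t; break }
        nl <- nl + 1L
        if (nl > cap) {
          cap <- 2L * cap
          parent <- c(parent, integer(cap %/% 2L))
          btime <- c(btime, numeric(cap %/% 2L))
          dtime <- c(dtime, rep(NA_real_, cap %/% 2L))
        }
        j <- sample.int(nalive, 1L)
        parent[nl] <- alive[j]; btime[nl] <- t
        nalive <- nalive + 1L; alive[nalive] <- nl
      } else if (u < (lam_t + mu) / (lmax + mu)) {
        j <- sample.int(nalive, 1L)
        dtime[alive[j]] <- t
        alive[j] <- alive[nalive]; nalive <- nalive - 1L
        if (nalive == 0L) break
      }                                   # else: thinned pseudo-event
    }
    if (!is.na(present))
      return(.reconstruct_tree(parent[1:nl], btime[1:nl], dtime[1:nl],
                               present))
  }
  .verr("simulation failed: clade went extinct in every attempt")
}

#' Simulate a sample of replicate trees
#'
#' Convenience wrapper generating `n_trees` independent replicates under a
#' common setting, with reproducible per-tree sub-seeds and a manifest of
#' the true parameters attached.
#'
#' @inheritParams sim_bd_tree
#' @param n_trees number of replicate trees.
#' @param generator `"bd"`, `"pbshift"` or `"spvar"`.
#' @param ... passed to the chosen simulator.
#' @param rho if < 1, each tree is additionally pruned to this sampling
#'   fraction.
#' @return a `tree_sample` with a `manifest` attribute recording the
#'   generator, its arguments and the seed.
#' @export
sim_tree_sample <- function(n_trees, n_tips,
                            generator = c("bd", "pbshift", "spvar"), ...,
                            rho = 1, seed = NULL) {
  generator <- match.arg(generator)
  fn <- switch(generator, bd = sim_bd_tree, pbshift = sim_pb_shift_tree,
               spvar = sim_spvar_approx)
  seeds <- .spawn_seeds(seed, 2L * n_trees)
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- fn(n_tips, ..., seed = seeds[i])
    if (rho < 1) tr <- subsample_tips(tr, rho, seed = seeds[n_trees + i])
    # replicates get a common label set so they form a valid tree_sample
    tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
    trees[[i]] <- tr
  }
  out <- tree_sample(trees, provenance = list(generator = generator,
                                              seed = seed))
  attr(out, "manifest") <- c(list(generator = generator, n_trees = n_trees,
                                  n_tips = n_tips, rho = rho, seed = seed),
                             list(...))
  out
}
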