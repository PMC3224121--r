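## Metropolis-Hastings sampling of diversification-model parameters over a
## posterior distribution of trees.  Single-tree chains for the standard
## model families run in compiled code; clade-partitioned models use an
## R-level sweep over per-group parameters.

#' Chain configuration
#'
#' @param ngen generations per tree.
#' @param sampfreq record every `sampfreq`-th post-burn-in generation.
#' @param burnin burn-in per tree: a fraction of `ngen` if < 1, otherwise an
#'   absolute number of generations.
#' @param scales named numeric vector of proposal standard deviations,
#'   overriding the default of 10% of each parameter's prior range.
#' @param tune if `TRUE`, proposal scales are adapted during the burn-in
#'   (Robbins-Monro, frozen afterwards so detailed balance holds for the
#'   recorded sample).
#' @param target_acc target acceptance rate for the tuner.
#' @param seed master seed; per-tree (and per-rung) sub-seeds are derived
#'   from it, so identical input and seed give identical output.
#' @return object of class `chain_config`.
#' @export
chain_config <- function(ngen = 110000, sampfreq = 100, burnin = 0.1,
                         scales = NULL, tune = FALSE, target_acc = 0.3,
                         seed = NULL) {
  b <- if (burnin < 1) round(ngen * burnin) else as.integer(burnin)
  if (ngen <= b) .verr("ngen must exceed the burn-in")
  if (sampfreq < 1 || sampfreq > ngen - b) .verr("invalid sampling frequency")
  structure(list(ngen = as.integer(ngen), sampfreq = as.integer(sampfreq),
                 burnin = as.integer(b), scales = scales, tune = tune,
                 target_acc = target_acc, seed = seed),
            class = "chain_config")
}

#' Prior specification (uniform bounds)
#'
#' All priors are uniform with finite bounds, which keeps them proper so
#' that the tempered chain at beta = 0 samples a well-defined distribution
#' (required by thermodynamic integration).  `rate_max` bounds all rate-like
#' parameters (`r`, `lambda`, `lambda0`, `mu0`); the extinction fraction `a`
#' is uniform on [0, 1); the decline parameter `k` on [0, 10]; the
#' meta-analysis mean rate `m` on [0, 10] and `log(F)` on [-2.3, 2.3].
#' Shift-time priors default to uniform on (0, root age) per tree; `shift`
#' may give a window `c(lo, hi)` applied to every shift, or a list of
#' windows, one per shift.
#'
#' The declining-speciation model carries its own extinction bound
#' `mu0_max` (default 1 event/lineage/Myr): its final extinction rate is
#' only weakly identified from reconstructed trees, and the model is
#' intended for clades with absent or low, constant extinction — an
#' unbounded flat prior on `mu0` drags the decline parameter `k` towards
#' zero through the ridge between the two parameters.
#'
#' @param rate_max upper bound for rate-like parameters (events/lineage/Myr).
#' @param mu0_max upper bound of the declining-speciation extinction prior.
#' @param shift optional shift-time window(s).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(rate_max = 10, mu0_max = 1, shift = NULL) {
  if (!(rate_max > 0) || !(mu0_max > 0)) .verr("prior bounds must be > 0")
  structure(list(rate_max = rate_max,
                 r = c(0, rate_max), a = c(0, 1),
                 lambda = c(0, rate_max),
                 lambda0 = c(0, rate_max), mu0 = c(0, mu0_max),
                 k = c(0, 10), m = c(0, 10), logF = c(-2.3, 2.3),
                 n = c(0, 1), shift = shift),
            class = "prior_spec")
}

#' Model specification
#'
#' @param family model family: `"pb"` (pure-birth), `"bd"` (birth-death,
#'   sampled in net diversification `r` and extinction fraction `a`),
#'   `"pbshift"` (pure-birth with `nshifts` rate shifts), `"spvar"`
#'   (exponentially declining speciation, constant extinction) or `"clade"`
#'   (clade-partitioned constant-rate model).
#' @param nshifts number of rate shifts (pbshift only).
#' @param rho sampling fraction in (0, 1] (pb/bd/spvar).
#' @param z fixed extinction-saturation parameter of the declining model.
#' @param priors a [prior_spec()].
#' @param partition a [clade_partition()] (clade family only).
#' @param process `"pb"` or `"bd"` for the clade family.
#' @param grouping `"linked"` (one rate set for all clades), `"unlinked"`
#'   (default, free rates per clade) or a vector mapping each clade to a
#'   group.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("pb", "bd", "pbshift", "spvar", "clade"),
                       nshifts = 1, rho = 1, z = 1e4,
                       priors = prior_spec(), partition = NULL,
                       process = c("pb", "bd"), grouping = "unlinked") {
  family <- match.arg(family)
  process <- match.arg(process)
  if (rho <= 0 || rho > 1) .verr("rho must be in (0, 1]")
  if (family == "pbshift" && nshifts < 1) .verr("pbshift needs nshifts >= 1")
  if (family == "clade" && !inherits(partition, "clade_partition"))
    .verr("clade family requires a clade_partition")
  structure(list(family = family, nshifts = as.integer(nshifts), rho = rho,
                 z = z, priors = priors, partition = partition,
                 process = process, grouping = grouping),
            class = "model_spec")
}

#' Reflected-normal proposal
#'
#' Draws from a normal centred on the current value and folds the draw back
#' into `[lower, upper]` by repeated reflection at the boundaries, giving a
#' symmetric proposal (Hastings ratio 1) confined to the prior support.
#'
#' @param current current value, inside `[lower, upper]`.
#' @param scale proposal standard deviation, > 0.
#' @param lower,upper reflection boundaries.
#' @return the proposed value.
#' @export
propose_reflected_normal <- function(current, scale, lower, upper) {
  if (!(scale > 0)) .verr("proposal scale must be > 0")
  if (current < lower || current > upper)
    .verr("current value outside [lower, upper]")
  .reflect_cpp(current + rnorm(1L) * scale, lower, upper)
}

#' Log-scale proposal for ratio parameters
#'
#' Proposes from a log-normal centred on the current value, i.e. a normal
#' in log space, reflected into `[lower, upper]` on the log scale, so the
#' proposal is symmetric in `log(F)`.
#'
#' @param currentF current (positive) value.
#' @param scale standard deviation of the log-scale normal.
#' @param lower,upper bounds on `log(F)`.
#' @return the proposed value (natural scale).
#' @export
propose_logscale <- function(currentF, scale, lower = -2.3, upper = 2.3) {
  if (!(currentF > 0)) .verr("currentF must be > 0")
  if (!(scale > 0)) .verr("proposal scale must be > 0")
  exp(.reflect_cpp(log(currentF) + rnorm(1L) * scale, lower, upper))
}

#' One Metropolis-Hastings step
#'
#' Accepts `proposal` over `current` with probability
#' `min(1, [L(prop)/L(cur)]^beta * prior(prop)/prior(cur))`, assuming the
#' proposal itself is symmetric.  With uniform priors the prior ratio is 1
#' inside the support; at `beta = 0` acceptance is independent of the
#' likelihood, so the chain samples the prior.
#'
#' @param current,proposal parameter states (numeric vectors).
#' @param loglik function mapping a state to its log-likelihood.
#' @param beta likelihood-tempering exponent in [0, 1].
#' @param log_prior optional function mapping a state to its log prior
#'   density (`-Inf` outside support); `NULL` means flat within support.
#' @param current_loglik cached value of `loglik(current)` to avoid
#'   re-evaluation.
#' @return list with `state`, `loglik` (of the returned state) and
#'   `accepted`.
#' @export
mh_step <- function(current, proposal, loglik, beta = 1, log_prior = NULL,
                    current_loglik = NULL) {
  lpr <- if (is.null(log_prior)) 0 else log_prior(proposal) - log_prior(current)
  if (identical(lpr, -Inf))
    return(list(state = current, loglik = current_loglik, accepted = FALSE))
  llc <- if (is.null(current_loglik)) loglik(current) else current_loglik
  llp <- if (beta > 0 || is.null(current_loglik)) loglik(proposal) else llc
  if (beta > 0 && !is.finite(llp)) {
    warning("non-finite likelihood at proposal; rejected")
    return(list(state = current, loglik = llc, accepted = FALSE))
  }
  logratio <- beta * (llp - llc) + lpr
  if (!is.finite(logratio)) logratio <- if (is.finite(llp)) Inf else -Inf
  if (logratio >= 0 || runif(1L) < exp(logratio))
    list(state = proposal, loglik = llp, accepted = TRUE)
  else
    list(state = current, loglik = llc, accepted = FALSE)
}

# resolve per-shift windows against a tree's root age
.shift_windows <- function(priors, nshifts, root_age) {
  w <- priors$shift
  mk <- function(lo, hi) {
    hi <- min(hi, root_age)
    if (lo >= hi)
      .verr("shift window [", lo, ", ", hi, "] empty for root age ",
            format(root_age))
    c(lo, hi)
  }
  if (is.null(w)) return(replicate(nshifts, c(0, root_age), simplify = FALSE))
  if (is.numeric(w) && length(w) == 2)
    return(replicate(nshifts, mk(w[1], w[2]), simplify = FALSE))
  if (is.list(w) && length(w) == nshifts)
    return(lapply(w, function(v) mk(v[1], v[2])))
  .verr("shift prior must be NULL, c(lo, hi), or a list of length nshifts")
}

# parameter layout + prior-draw initialisation for the compiled families
.chain_setup <- function(bt, model, cfg) {
  pr <- model$priors
  fam <- model$family
  if (fam == "pb") {
    lo <- pr$lambda[1]; hi <- pr$lambda[2]
    set <- list(code = 0L, pnames = "lambda", lo = lo, hi = hi)
  } else if (fam == "bd") {
    set <- list(code = 1L, pnames = c("r", "a"),
                lo = c(pr$r[1], pr$a[1]), hi = c(pr$r[2], pr$a[2]))
  } else if (fam == "spvar") {
    set <- list(code = 3L, pnames = c("lambda0", "mu0", "k"),
                lo = c(pr$lambda0[1], pr$mu0[1], pr$k[1]),
                hi = c(pr$lambda0[2], pr$mu0[2], pr$k[2]))
  } else if (fam == "pbshift") {
    n <- model$nshifts
    wins <- .shift_windows(pr, n, bt$root_age)
    set <- list(code = 2L,
                pnames = c(paste0("lambda_", seq_len(n + 1)),
                           paste0("shift_", seq_len(n))),
                lo = c(rep(pr$lambda[1], n + 1),
                       vapply(wins, `[`, 0, 1)),
                hi = c(rep(pr$lambda[2], n + 1),
                       vapply(wins, `[`, 0, 2)))
  } else .verr("no compiled sampler for family ", fam)
  np <- length(set$pnames)
  # step-1 initialisation: independent uniform draws within the priors
  for (try in 1:100) {
    init <- runif(np, set$lo, set$hi)
    if (fam == "pbshift") {
      n <- model$nshifts
      sh <- sort(init[(n + 2):np])
      if (any(duplicated(sh))) next
      init[(n + 2):np] <- sh
      if (any(sh < set$lo[(n + 2):np] | sh > set$hi[(n + 2):np])) next
    }
    if (fam == "bd" && init[1] == 0) next
    break
  }
  scales <- 0.1 * (set$hi - set$lo)
  scales[!is.finite(scales)] <- 1
  if (!is.null(cfg$scales)) {
    ovr <- intersect(names(cfg$scales), set$pnames)
    scales[match(ovr, set$pnames)] <- cfg$scales[ovr]
  }
  c(set, list(init = init, scales = scales))
}

# run one tempered chain on one tree; returns a data.frame of records
.run_one_chain <- function(bt, model, cfg, beta = 1, seed = NULL) {
  .with_seed(seed, {
    if (model$family == "clade")
      return(.run_clade_chain(bt, model, cfg, beta))
    su <- .chain_setup(bt, model, cfg)
    res <- .mcmc_chain_cpp(bt$x, su$code, model$rho, model$z, su$init,
                           su$lo, su$hi, su$scales, cfg$ngen, cfg$sampfreq,
                           cfg$burnin, beta, cfg$tune, cfg$target_acc)
    m <- res$samples
    colnames(m) <- c("gen", "loglik", su$pnames)
    df <- as.data.frame(m)
    if (model$family == "bd") {
      df$lambda <- df$r / (1 - df$a)
      df$mu <- df$lambda * df$a
    }
    attr(df, "acceptance") <- setNames(res$acceptance, su$pnames)
    attr(df, "scales") <- setNames(res$scales, su$pnames)
    df
  })
}

# R-level sweep sampler for clade-partitioned models
.run_clade_chain <- function(clades, model, cfg, beta = 1) {
  nc <- length(clades)
  labels <- vapply(clades, function(cl) cl$label, "")
  g <- model$grouping
  if (identical(g, "linked")) g <- rep(1L, nc)
  else if (identical(g, "unlinked")) g <- seq_len(nc)
  else if (is.character(g)) g <- match(g, unique(g))
  if (length(g) != nc) .verr("grouping must have one entry per clade")
  ngroup <- max(g)
  pr <- model$priors
  bd <- model$process == "bd"
  ppg <- if (bd) 2L else 1L
  pnames <- if (bd)
    c(t(outer(c("r", "a"), seq_len(ngroup), paste, sep = "_")))
  else paste0("lambda_", seq_len(ngroup))
  lo <- if (bd) rep(c(pr$r[1], pr$a[1]), ngroup) else rep(pr$lambda[1], ngroup)
  hi <- if (bd) rep(c(pr$r[2], pr$a[2]), ngroup) else rep(pr$lambda[2], ngroup)
  scales <- 0.1 * (hi - lo)
  if (!is.null(cfg$scales)) {
    ovr <- intersect(names(cfg$scales), pnames)
    scales[match(ovr, pnames)] <- cfg$scales[ovr]
  }
  cl_ll <- function(i, th) {
    gi <- (g[i] - 1L) * ppg
    if (bd) {
      r <- th[gi + 1L]; a <- th[gi + 2L]
      if (r <= 0 || a >= 1) return(-Inf)
      lam <- r / (1 - a)
      .bd_loglik_cpp(clades[[i]]$bt$x, lam, lam * a, clades[[i]]$rho)
    } else {
      if (th[gi + 1L] <= 0) return(-Inf)
      .bd_loglik_cpp(clades[[i]]$bt$x, th[gi + 1L], 0, clades[[i]]$rho)
    }
  }
  th <- runif(length(pnames), lo, hi)
  clls <- vapply(seq_len(nc), cl_ll, 0, th = th)
  nsamp <- (cfg$ngen - cfg$burnin) %/% cfg$sampfreq
  out <- matrix(NA_real_, nsamp, 2 + length(pnames),
                dimnames = list(NULL, c("gen", "loglik", pnames)))
  row <- 0L
  acc <- tries <- numeric(length(pnames))
  for (gen in seq_len(cfg$ngen)) {
    for (p in seq_along(pnames)) {
      old <- th[p]
      th[p] <- .reflect_cpp(old + rnorm(1L) * scales[p], lo[p], hi[p])
      members <- which(g == ((p - 1L) %/% ppg + 1L))
      new_clls <- vapply(members, cl_ll, 0, th = th)
      lnew <- sum(new_clls)
      lold <- sum(clls[members])
      tries[p] <- tries[p] + 1
      accept <-
        if (beta == 0) TRUE
        else if (!is.finite(lnew)) FALSE
        else if (!is.finite(lold)) TRUE
        else {
          lr <- beta * (lnew - lold)
          lr >= 0 || runif(1L) < exp(lr)
        }
      if (accept) {
        clls[members] <- new_clls
        acc[p] <- acc[p] + 1
      } else th[p] <- old
    }
    if (gen > cfg$burnin && (gen - cfg$burnin) %% cfg$sampfreq == 0 &&
        row < nsamp) {
      row <- row + 1L
      if (beta == 0)
        clls <- vapply(seq_len(nc), cl_ll, 0, th = th)
      out[row, ] <- c(gen, sum(clls), th)
    }
  }
  df <- as.data.frame(out)
  attr(df, "acceptance") <- setNames(acc / pmax(tries, 1), pnames)
  attr(df, "groups") <- setNames(g, labels)
  df
}

# data object a chain consumes for one tree, by family
.chain_data <- function(tree, model, tree_index = NA) {
  if (model$family == "clade")
    clade_branching_times(tree, model$partition, tree_index = tree_index)
  else branching_times(tree)
}

#' Run the MCMC over a posterior sample of trees
#'
#' For each tree: assign initial values by uniform draws within the priors,
#' run the Metropolis-Hastings chain, discard the burn-in and record every
#' `sampfreq`-th state; records are then pooled over trees so that the
#' marginal posterior reflects both parameter and divergence-time
#' uncertainty.  Each tree gets an independent, reproducible sub-seed
#' derived from `cfg$seed`.
#'
#' @param trees a `tree_sample` or single `phylo`.
#' @param model a [model_spec()].
#' @param cfg a [chain_config()].
#' @param beta likelihood-tempering exponent (used by the marginal
#'   likelihood machinery; leave at 1 for posterior sampling).
#' @return object of class `posterior_sample`: a data.frame with columns
#'   `tree`, `gen`, `loglik` and the model parameters, with per-parameter
#'   effective sample sizes (summed over trees) and acceptance rates as
#'   attributes.
#' @export
run_chain_over_trees <- function(trees, model, cfg = chain_config(),
                                 beta = 1) {
  if (inherits(trees, "phylo")) trees <- tree_sample(trees)
  if (!inherits(trees, "tree_sample")) trees <- tree_sample(trees)
  # validate the model against every tree before any sampling starts
  data <- lapply(seq_along(trees), function(i)
    .chain_data(trees[[i]], model, tree_index = i))
  if (model$family == "pbshift")
    for (i in seq_along(data))
      .shift_windows(model$priors, model$nshifts, data[[i]]$root_age)
  seeds <- .spawn_seeds(cfg$seed, length(data))
  recs <- vector("list", length(data))
  accs <- NULL
  for (i in seq_along(data)) {
    df <- .run_one_chain(data[[i]], model, cfg, beta = beta,
                         seed = seeds[i])
    accs <- rbind(accs, attr(df, "acceptance"))
    df <- cbind(tree = i, df)
    recs[[i]] <- df
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  pn <- setdiff(colnames(out), c("tree", "gen", "loglik"))
  ess_tot <- vapply(pn, function(p) {
    sum(vapply(recs, function(df) ess(df[[p]]), 0))
  }, 0)
  root_max <- if (model$family == "clade") NA_real_ else
    max(vapply(data, function(d) d$root_age, 0))
  structure(out, class = c("posterior_sample", "data.frame"),
            model = model, cfg = cfg, params = pn,
            n_trees = length(data), ess = ess_tot,
            acceptance = colMeans(accs), root_max = root_max)
}

#' Write a Tracer-compatible log file
#'
#' Tab-delimited with a comment header (provenance) and columns `state`,
#' `treeIndex`, `logLik`, then the parameters; loadable in Tracer.
#'
#' @param ps a `posterior_sample`.
#' @param path output file.
#' @param provenance character vector of header comment lines.
#' @return `path`, invisibly.
#' @export
write_tracer_log <- function(ps, path, provenance = character(0)) {
  pn <- attr(ps, "params")
  df <- data.frame(state = seq_len(nrow(ps)) - 1L, treeIndex = ps$tree,
                   logLik = ps$loglik, ps[pn], check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (line in provenance) writeLines(paste0("# ", line), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
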