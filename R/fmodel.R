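## Meta-analysis F-model: N data sets, each split a priori into two
## partitions p and q (clades, or time frames sharing one tree), whose
## speciation rates are tied through a data-set mean rate m_i and a single
## ratio F = lambda^(p) / lambda^(q) shared by all data sets:
##   lambda_i^(p) = 2 m_i F / (1 + F),   lambda_i^(q) = 2 m_i / (1 + F).
## Under the birth-death extension the same mapping is applied to the mean
## net diversification (ratio F_r) and, with per-data-set mean extinction
## fractions n_i, to the extinction fraction (ratio F_a).

#' Partition rates implied by a mean rate and ratio
#'
#' @param m mean rate (> 0).
#' @param F rate ratio `lambda_p / lambda_q` (> 0).
#' @return named vector `c(p, q)`; the mean of the two rates is `m` and
#'   their ratio `F` for every input.
#' @export
f_rates <- function(m, F) {
  if (any(m <= 0) || any(F <= 0)) .verr("m and F must be > 0")
  c(p = 2 * m * F / (1 + F), q = 2 * m / (1 + F))
}

#' Define one F-model data set
#'
#' Either two clade partitions (each with its own branching times and
#' sampling fraction), or a single tree split into two time frames at
#' `split_time`, in which case partition `p` is the recent frame
#' (ages < `split_time`) and `q` the older frame.
#'
#' @param label data-set label.
#' @param bt_p,bt_q branching times of the two clade partitions.
#' @param rho_p,rho_q sampling fractions.
#' @param bt,split_time whole-tree branching times and the frame boundary
#'   age, for the time-frame variant.
#' @return object of class `fdataset`.
#' @export
fdataset <- function(label, bt_p = NULL, bt_q = NULL, rho_p = 1, rho_q = 1,
                     bt = NULL, split_time = NULL) {
  if (!is.null(bt)) {
    bt <- branching_times(bt)
    if (is.null(split_time) || split_time <= 0 || split_time >= bt$root_age)
      .verr("split_time must lie inside (0, root age)")
    structure(list(label = label, type = "frames", bt = bt,
                   split_time = split_time),
              class = "fdataset")
  } else {
    if (is.null(bt_p) || is.null(bt_q)) .verr("both partitions required")
    structure(list(label = label, type = "clades",
                   bt_p = branching_times(bt_p),
                   bt_q = branching_times(bt_q),
                   rho_p = rho_p, rho_q = rho_q),
              class = "fdataset")
  }
}

# log-likelihood of one data set given its two partition rates (pure birth)
# or (r, a) pairs (birth-death)
.fdataset_loglik <- function(d, lam_p, lam_q, a_p = 0, a_q = 0) {
  if (d$type == "frames") {
    # Yule frame decomposition of the single tree; (s-1)! constant added once
    lgamma(d$bt$s) +
      .pb_frame_loglik_cpp(d$bt$x, lam_p, 0, d$split_time) +
      .pb_frame_loglik_cpp(d$bt$x, lam_q, d$split_time, Inf)
  } else {
    lp <- if (a_p > 0) .bd_loglik_cpp(d$bt_p$x, lam_p, lam_p * a_p, d$rho_p)
          else .bd_loglik_cpp(d$bt_p$x, lam_p, 0, d$rho_p)
    lq <- if (a_q > 0) .bd_loglik_cpp(d$bt_q$x, lam_q, lam_q * a_q, d$rho_q)
          else .bd_loglik_cpp(d$bt_q$x, lam_q, 0, d$rho_q)
    lp + lq
  }
}

#' Joint F-model log-likelihood over all data sets
#'
#' @param datasets list of [fdataset()] objects.
#' @param state list with `m` (length-N mean rates) and `F`; for
#'   `process = "bd"` additionally `n` (length-N mean extinction
#'   fractions), `Fr` and `Fa` (`F` is ignored and `m` is the mean net
#'   diversification).
#' @param process `"pb"` or `"bd"`.
#' @return the joint log-likelihood (sum over data sets of both partition
#'   likelihoods).
#' @export
fmodel_joint_loglik <- function(datasets, state, process = c("pb", "bd")) {
  process <- match.arg(process)
  N <- length(datasets)
  if (length(state$m) != N) .verr("state$m must have one entry per data set")
  ll <- 0
  for (i in seq_len(N)) {
    if (process == "pb") {
      lr <- f_rates(state$m[i], state$F)
      ll <- ll + .fdataset_loglik(datasets[[i]], lr[["p"]], lr[["q"]])
    } else {
      if (length(state$n) != N) .verr("state$n must have one entry per data set")
      rr <- f_rates(state$m[i], state$Fr)          # partition net rates
      aa <- f_rates(max(state$n[i], 1e-12), state$Fa)
      a_p <- .reflect_cpp(aa[["p"]], 0, 1)         # fold back into [0, 1)
      a_q <- .reflect_cpp(aa[["q"]], 0, 1)
      if (a_p >= 1 || a_q >= 1) return(-Inf)
      lam_p <- rr[["p"]] / (1 - a_p)
      lam_q <- rr[["q"]] / (1 - a_q)
      ll <- ll + .fdataset_loglik(datasets[[i]], lam_p, lam_q, a_p, a_q)
    }
  }
  ll
}

# one tempered F-model chain over one replicate (a list of N fdatasets)
.run_fmodel_chain <- function(datasets, cfg, beta = 1, process = "pb",
                              priors = prior_spec(), fixed_F = FALSE) {
  N <- length(datasets)
  bd <- process == "bd"
  mnames <- paste0("m_", seq_len(N))
  pnames <- c(mnames, if (bd) paste0("n_", seq_len(N)), "F",
              if (bd) "Fa")
  state <- list(m = runif(N, priors$m[1], priors$m[2]),
                F = if (fixed_F) 1 else exp(runif(1, priors$logF[1],
                                                  priors$logF[2])),
                n = if (bd) runif(N, 0, 1) else NULL,
                Fa = if (bd) exp(runif(1, priors$logF[1], priors$logF[2]))
                     else NULL)
  if (bd) state$Fr <- state$F
  sync <- function(st) { if (bd) st$Fr <- st$F; st }
  state <- sync(state)
  ll_of <- function(st) fmodel_joint_loglik(datasets, st, process)
  cur <- ll_of(state)
  sc_m <- 0.1 * diff(priors$m)
  sc_f <- 0.1 * diff(priors$logF)
  nsamp <- (cfg$ngen - cfg$burnin) %/% cfg$sampfreq
  out <- matrix(NA_real_, nsamp, 2 + length(pnames),
                dimnames = list(NULL, c("gen", "loglik", pnames)))
  row <- 0L
  do_step <- function(prop) {
    lnew <- ll_of(prop)
    ok <- if (beta == 0) TRUE
      else if (!is.finite(lnew)) FALSE
      else if (!is.finite(cur)) TRUE
      else {
        lr <- beta * (lnew - cur)
        lr >= 0 || runif(1L) < exp(lr)
      }
    if (ok) {
      state <<- prop
      cur <<- lnew
    }
  }
  for (gen in seq_len(cfg$ngen)) {
    for (i in seq_len(N)) {
      prop <- state
      prop$m[i] <- .reflect_cpp(state$m[i] + rnorm(1L) * sc_m,
                                priors$m[1], priors$m[2])
      do_step(sync(prop))
    }
    if (bd) for (i in seq_len(N)) {
      prop <- state
      prop$n[i] <- .reflect_cpp(state$n[i] + rnorm(1L) * 0.1, 0, 1)
      do_step(prop)
    }
    if (!fixed_F) {
      prop <- state
      prop$F <- propose_logscale(state$F, sc_f, priors$logF[1],
                                 priors$logF[2])
      do_step(sync(prop))
    }
    if (bd) {
      prop <- state
      prop$Fa <- propose_logscale(state$Fa, sc_f, priors$logF[1],
                                  priors$logF[2])
      do_step(prop)
    }
    if (gen > cfg$burnin && (gen - cfg$burnin) %% cfg$sampfreq == 0 &&
        row < nsamp) {
      row <- row + 1L
      if (beta == 0) cur <- ll_of(state)
      out[row, ] <- c(gen, cur, state$m, if (bd) state$n, state$F,
                      if (bd) state$Fa)
    }
  }
  as.data.frame(out)
}

#' Test for an overall rate difference between partitions (F-model)
#'
#' Runs the F-model MCMC over tree replicates with `F` free and with `F`
#' constrained to 1 (equal rates), computes both marginal likelihoods by
#' thermodynamic integration, and reports the Bayes factor
#' `2 (logL_free - logL_constrained)` together with posterior summaries of
#' `F` and the per-data-set partition rates.
#'
#' @param replicates list over tree replicates; each element is a list of N
#'   [fdataset()] objects (the same data sets extracted from the j-th
#'   posterior tree of each group).
#' @param cfg a [chain_config()].
#' @param process `"pb"` or `"bd"`.
#' @param priors a [prior_spec()].
#' @param ladder a [beta_ladder()].
#' @return list with `posterior` (pooled free-F records), `F_mean`,
#'   `F_hpd`, `rates` (per data set posterior mean partition rates),
#'   `logml_free`, `logml_fixed` and `bf` (a [bayes_factor()]).
#' @export
fmodel_test <- function(replicates, cfg = chain_config(),
                        process = c("pb", "bd"), priors = prior_spec(),
                        ladder = beta_ladder()) {
  process <- match.arg(process)
  if (!length(replicates)) .verr("need at least one replicate")
  betas <- sort(as.numeric(ladder))
  nr <- length(replicates)
  nb <- length(betas)
  seeds <- array(.spawn_seeds(cfg$seed, nr * nb * 2L + nr), c(nr, nb, 2L))
  post_seeds <- .spawn_seeds(if (is.null(cfg$seed)) NULL else cfg$seed + 1L,
                             nr)
  u_free <- u_fix <- matrix(NA_real_, nr, nb)
  posts <- vector("list", nr)
  for (j in seq_len(nr)) {
    for (b in seq_len(nb)) {
      dff <- .with_seed(seeds[j, b, 1],
                        .run_fmodel_chain(replicates[[j]], cfg, betas[b],
                                          process, priors, fixed_F = FALSE))
      dfx <- .with_seed(seeds[j, b, 2],
                        .run_fmodel_chain(replicates[[j]], cfg, betas[b],
                                          process, priors, fixed_F = TRUE))
      u_free[j, b] <- mean(dff$loglik[is.finite(dff$loglik)])
      u_fix[j, b] <- mean(dfx$loglik[is.finite(dfx$loglik)])
      if (b == nb) posts[[j]] <- cbind(replicate = j, dff)
    }
  }
  post <- do.call(rbind, posts)
  lm_free <- .integrate_ladder(betas, colMeans(u_free))
  lm_fix <- .integrate_ladder(betas, colMeans(u_fix))
  N <- length(replicates[[1]])
  rates <- t(vapply(seq_len(N), function(i) {
    lr <- f_rates(mean(post[[paste0("m_", i)]]), mean(post$F))
    c(p = lr[["p"]], q = lr[["q"]])
  }, c(p = 0, q = 0)))
  rownames(rates) <- vapply(replicates[[1]], function(d) d$label, "")
  list(posterior = post, F_mean = mean(post$F), F_hpd = hpd(post$F),
       rates = rates, logml_free = lm_free, logml_fixed = lm_fix,
       bf = bayes_factor(lm_free, lm_fix))
}
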