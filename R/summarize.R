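## Posterior summaries: HPD intervals, histogram modes, effective sample
## sizes, rates-through-time grids and relative-error scoring.

#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted samples containing
#' `ceiling(mass * n)` of them.
#'
#' @param samples numeric vector (>= 20 values).
#' @param mass probability mass, default 0.95.
#' @return named vector `c(lower, upper)`.
#' @export
hpd <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 20) .verr("need at least 20 samples for an HPD interval")
  if (mass <= 0 || mass > 1) .verr("mass must be in (0, 1]")
  xs <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  w <- xs[m:n] - xs[1:(n - m + 1)]
  j <- which.min(w)
  c(lower = xs[j], upper = xs[j + m - 1])
}

#' Histogram mode of a posterior sample
#'
#' Midpoint of the highest-frequency histogram bin (Freedman-Diaconis bin
#' width), approximating the maximum-a-posteriori value; used in
#' particular for shift-time estimates.
#'
#' @param samples numeric vector (>= 100 values unless degenerate).
#' @return the modal value.
#' @export
posterior_mode <- function(samples) {
  ux <- unique(samples)
  if (length(ux) == 1L) return(ux)
  if (length(samples) < 100) .verr("need at least 100 samples for a mode")
  h <- graphics::hist(samples, breaks = "FD", plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Effective sample size of an autocorrelated chain
#'
#' `n / (1 + 2 * sum of autocorrelations)`, with the sum truncated at the
#' first negative autocorrelation (the convention used by Tracer).
#'
#' @param samples numeric vector (>= 10 values).
#' @return the effective sample size (capped at `n`, floored at 1).
#' @export
ess <- function(samples) {
  n <- length(samples)
  if (n < 10) .verr("need at least 10 samples for an ESS")
  if (sd(samples) == 0 || !all(is.finite(samples))) return(1)
  maxlag <- min(n - 1L, 2000L)
  ac <- acf(samples, lag.max = maxlag, plot = FALSE, demean = TRUE)$acf[-1]
  neg <- which(ac < 0)
  K <- if (length(neg)) neg[1] - 1L else length(ac)
  act <- 1 + 2 * sum(ac[seq_len(K)])
  min(n, max(1, n / max(act, 1e-12)))
}

#' Summary table for a posterior sample
#'
#' Mean, histogram mode, 95% HPD bounds and effective sample size for every
#' model parameter; the ESS is the sum of per-tree chain ESS values, and
#' both mean and mode are reported because strongly skewed posteriors (for
#' example the extinction rate at low extinction fractions) are summarised
#' poorly by the mean alone.
#'
#' @param ps a `posterior_sample` from [run_chain_over_trees()].
#' @param mass HPD mass.
#' @return data.frame with one row per parameter.
#' @export
summarize_posterior <- function(ps, mass = 0.95) {
  pn <- attr(ps, "params")
  ess_by <- attr(ps, "ess")
  rows <- lapply(pn, function(p) {
    v <- ps[[p]]
    h <- hpd(v, mass)
    data.frame(parameter = p, mean = mean(v), mode = posterior_mode(v),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               ess = if (!is.null(ess_by) && p %in% names(ess_by))
                 ess_by[[p]] else ess(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rates-through-time grid
#'
#' For every posterior sample and time bin, evaluates the speciation rate
#' in force at the bin midpoint given that sample's shift times and
#' per-frame rates, then summarises each bin by its marginal mean and HPD.
#' The per-bin sampling frequency of the shift times (counts and
#' proportions) approximates the probability of a rate shift in that bin.
#'
#' @param ps a `posterior_sample` from a pure-birth shift model (constant
#'   models give a flat grid).
#' @param bin_width bin width in Myr (default 1).
#' @param max_age oldest bin edge; defaults to the oldest sampled root age
#'   recorded in the model run (bins requested beyond it are dropped with a
#'   warning).
#' @return data.frame with columns `bin_mid`, `mean`, `hpd_lower`,
#'   `hpd_upper`, `shift_count`, `shift_freq`.
#' @export
rtt <- function(ps, bin_width = 1, max_age = NULL) {
  pn <- attr(ps, "params")
  lam_cols <- grep("^lambda(_[0-9]+)?$", pn, value = TRUE)
  shift_cols <- grep("^shift_[0-9]+$", pn, value = TRUE)
  if (!length(lam_cols)) .verr("no rate columns found in posterior sample")
  root_max <- attr(ps, "root_max")
  if (is.null(root_max)) root_max <- NA
  lim <- if (!is.null(max_age)) max_age else
    if (is.finite(root_max)) root_max else
      if (length(shift_cols)) max(ps[[shift_cols[length(shift_cols)]]]) else
        bin_width
  if (is.finite(root_max) && lim > root_max) {
    warning("bins beyond the oldest sampled root age dropped")
    lim <- root_max
  }
  mids <- seq(bin_width / 2, lim, by = bin_width)
  lam <- as.matrix(ps[lam_cols])
  nshift <- length(shift_cols)
  sh <- if (nshift) as.matrix(ps[shift_cols]) else NULL
  rows <- lapply(mids, function(tm) {
    # frame index per sample: 1 + number of shifts older than the midpoint
    # counted from the oldest frame; lambda columns are oldest-first
    frame <- if (nshift) 1L + rowSums(sh > tm) else
      rep(1L, nrow(lam))
    rate <- lam[cbind(seq_len(nrow(lam)), frame)]
    h <- hpd(rate)
    cnt <- if (nshift)
      sum(sh >= tm - bin_width / 2 & sh < tm + bin_width / 2) else 0L
    data.frame(bin_mid = tm, mean = mean(rate), hpd_lower = h[["lower"]],
               hpd_upper = h[["upper"]], shift_count = cnt)
  })
  out <- do.call(rbind, rows)
  total <- if (nshift) nshift * nrow(ps) else 1L
  out$shift_freq <- out$shift_count / total
  out
}

#' Signed relative error of a rate estimate
#'
#' `(est - truth) / truth`; positive values indicate overestimation.
#'
#' @param est estimated value.
#' @param truth true value (non-zero).
#' @export
relative_error <- function(est, truth) {
  if (any(truth == 0)) .verr("truth must be non-zero")
  (est - truth) / truth
}

#' Relative error of a shift-time estimate
#'
#' `(t_est - t_true) / T`, scaled by the average root age `T` of the
#' analysed trees rather than by the true shift time.
#'
#' @param t_est estimated shift time.
#' @param t_true true shift time.
#' @param T average root age (> 0).
#' @export
shift_relative_error <- function(t_est, t_true, T) {
  if (any(T <= 0)) .verr("average root age must be > 0")
  (t_est - t_true) / T
}
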