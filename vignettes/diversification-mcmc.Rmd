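---
title: "Estimating diversification rates over tree posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diversification rates over tree posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dated molecular phylogenies of extant species carry information about the
per-lineage speciation rate $\lambda$ and extinction rate $\mu$, even
though extinct lineages are unobserved.  Point estimates on a single
consensus tree ignore the often substantial uncertainty in the node ages;
`bayesbd` instead runs a Metropolis--Hastings sampler over a *posterior
sample* of dated trees (for example the output of a relaxed molecular
clock analysis) and pools the post-burn-in records, so the marginal rate
posteriors reflect both parameter and divergence-time uncertainty.

The sufficient statistic for every model in the package is the vector of
branching times $x = (x_2, \dots, x_s)$: the ages of the $s-1$ internal
nodes of an ultrametric tree with $s$ tips, measured backward from the
present in Myr and sorted in non-increasing order ($x_2$ is the root age,
i.e. the age of the branching that created the second lineage).

## Likelihoods

**Constant-rate birth--death.** The reconstructed-process density

$$L(x;\lambda,\mu) = (s-1)!\,(\lambda-\mu)^{s-2}
  e^{(\lambda-\mu)\sum_{i=3}^{s} x_i}\,(1-\mu/\lambda)^{s}
  \prod_{i=2}^{s}\left[e^{(\lambda-\mu)x_i}-\mu/\lambda\right]^{-2}$$

is evaluated in log space throughout (no underflow up to $s = 10{,}000$
tips and root ages of 1000 Myr).  The $(s-1)!$ factor is constant in the
parameters; it is included deliberately so that log-likelihoods — and
therefore marginal likelihoods — are comparable across model families on
the same tree, which Bayes factors require.  With $\mu = 0$ the density
reduces exactly to the pure-birth (Yule) likelihood.

**Incomplete taxon sampling.** When only a fraction $\rho = s/S$ of the
true diversity is sampled (uniformly at random), the reconstructed process
is exactly equivalent to a completely sampled process with
$\lambda' = \rho\lambda$ and $\mu' = \mu - \lambda(1-\rho)$; the net
diversification $r = \lambda - \mu$ is invariant.  `bd_loglik_sampled()`
evaluates the density above at $a' = 1 - r/(\rho\lambda)$, which reduces
bit-identically to the complete-sampling value at $\rho = 1$.  The test
suite cross-checks this against an independent implementation of the
sampled density written in terms of the one-surviving-lineage probability
$p_1(t)$; the two agree up to the expected parameter-independent constant
$-\log\rho$.

**Declining speciation.** The continuously varying model uses
$\lambda(t) = \lambda_0 e^{-kt}$ and $\mu(t) = \mu_0(1 - e^{-zt})$ with
$z$ fixed at 10,000 by default, making extinction effectively constant at
$\mu_0$.  Writing $\phi(t) = \int_0^t (\lambda - \mu)\,du$ (closed form)
and $E(t) = e^{\phi(t)}/(1 + \int_0^t \lambda(u)e^{\phi(u)}du)$, the
package evaluates

$$L = (s-1)!\left[\prod_{i=3}^{s}\lambda(x_i)\right] e^{-\phi(x_2)}
      \prod_{i=2}^{s} p_1(x_i), \qquad p_1(t) = E(t)^2 e^{-\phi(t)},$$

which reduces *algebraically* to the constant-rate density when the rates
are constant (verified to 1e-10 in the tests).  The remaining integral is
computed by 12-point Gauss--Legendre quadrature on each inter-node
segment, with one extra knot at $t = 10/z$ to resolve the extinction
boundary layer.  One consequence worth knowing: at $z = 10^4$ the model
is *not yet* the constant-extinction model — the log-likelihood gap is of
order $s\,\mu_0/z$ — so exact agreement with `bd_loglik()` is only reached
in the large-$z$ limit.

**Rate shifts.** The pure-birth model with $n$ shifts factorises over time
frames: each frame contributes $b_j \log\lambda_j - \lambda_j T_j$, where
$b_j$ counts the non-root branching events inside the frame and $T_j$ is
the lineage-time (the lineage count integrated over the frame).  Shift
times are parameters with uniform priors on $(0, \text{root age})$ or a
user-supplied window, which is how constrained hypothesis tests (for
example "did the shift fall in a named geological period?") are run.

**Clade partitions and the meta-analysis model.** Clade-partitioned models
sum crown-group likelihoods over predefined, monophyly-checked clades,
each with its own $\rho_c$, with rates linked, unlinked or tied through an
arbitrary grouping.  Crown (not stem) branching times are used because the
density above conditions on the first split; backbone nodes outside every
named clade are excluded by default.  The meta-analysis model ties the two
partition rates of each of $N$ data sets through a shared ratio
$F = \lambda^{(p)}/\lambda^{(q)}$ with
$\lambda_i^{(p)} = 2m_iF/(1+F)$ and $\lambda_i^{(q)} = 2m_i/(1+F)$, so
$m_i$ is always the mean of the two rates.  Evidence for a rate difference
is the Bayes factor between the free-$F$ model and the constraint $F = 1$.

## Sampling machinery

Proposals are normals centred on the current value, folded back into the
prior support by reflection (a symmetric proposal, so the Hastings ratio
is 1); the ratio parameter $F$ uses a log-normal proposal, symmetric in
$\log F$.  The birth--death models are sampled in $(r, a) =
(\lambda - \mu, \mu/\lambda)$ with uniform priors $r \in [0, 10]$ and
$a \in [0, 1)$; the same `rate_max = 10` bounds $\lambda$ in pure-birth
models, matching the method's standard rate-prior bound, and is
deliberately part of the model identity: marginal likelihoods are only
comparable between models with identical bounds, and `bayes_factor()`
refuses anything else.  One sweep updates each parameter in sequence with
its own accept/reject step.  Default proposal scales are 10% of each prior
range; optional Robbins--Monro adaptation (off by default) runs only
during the burn-in and is frozen afterwards, so the recorded sample obeys
detailed balance.  Shift times are kept identifiable by treating the
ordering $s_1 < \dots < s_n$ as part of the prior support (disordering
proposals are rejected); with per-shift windows this is the natural
generalisation of relabelling, and for one shift the two are identical.

Each tree of the sample gets its own chain (110,000 generations, sampling
frequency 100, 10% burn-in by default) initialised by uniform draws within
the priors under an independent sub-seed, and the post-burn-in records are
pooled.  The per-parameter effective sample size is summed over trees.
The extinction-rate posterior is strongly right-skewed at low extinction
fractions, which is why summaries always report the histogram mode
(Freedman--Diaconis bin width) next to the mean.

The declining-speciation model is sampled directly in
$(\lambda_0, \mu_0, k)$.  Its extinction rate is the one place the package
imposes an informative default: $\mu_0 \sim U[0, 1]$ rather than
$U[0, \texttt{rate\_max}]$.  The likelihood surface has a pronounced ridge
between $k$ and $\mu_0$ (recent extinction mimics a weaker decline), and
the model is anyway intended for clades with absent-to-low constant
extinction; a flat prior to 10 events/lineage/Myr puts most of its mass in
the degenerate part of that ridge and visibly drags the posterior of $k$
toward zero on simulated declines.  The bound is a single argument
(`prior_spec(mu0_max = )`) for users who disagree.

## Marginal likelihoods and Bayes factors

The log marginal likelihood is obtained by thermodynamic integration:
$\log L_M = \int_0^1 E_\beta[\log L]\,d\beta$, where the expectation is
under the posterior tempered by $\beta$ on the likelihood.  Six evenly
spaced $\beta$ classes $\{0, 0.2, \dots, 1\}$ are the default; each rung
runs the full over-trees scheme and the per-rung expectations are pooled
across trees (equivalently: the per-tree integrals are averaged — the
integration is linear, so both readings coincide).  The first interval
$[\beta_0, \beta_1]$, where the expectation curve is steepest, is
integrated analytically with a cubic Bezier spline through control
ordinates $c_{y0} = U_0/5 + 4U_1/5$ and
$c_{y1} = (\beta_1U_2 - \beta_2U_1)/(\beta_1 - \beta_2)$, giving
$(\beta_1-\beta_0)(U_0 + 3c_{y0} + 6c_{y1} + 10U_1)/20$; the remaining
intervals use the trapezoid rule.  At $\beta = 0$ the chain samples the
prior and the likelihood is evaluated only for the records.

An honest accuracy statement, measured against exact quadrature on
100-tip trees with the default priors: the *absolute* $\log L_M$ from a
six-class ladder is biased by several log units, because under wide rate
priors the expectation curve falls hundreds of log units between
$\beta = 0$ and $\beta = 0.2$ and no three-point spline can represent
that drop.  *Bayes factors* between models fitted with the same ladder
and priors are far more reliable — the first-interval biases largely
cancel — and in our simulations the six-class Bayes factors track exact
quadrature to within a few log units at magnitudes of 30--70, which is
what model selection needs.  Bayes factors are reported on the
$2(\,\log L_{M_1} - \log L_{M_0})$ scale: values above 2 are positive and
above 6 strong evidence.

## The simulator

The validation experiments are regenerated internally:

* *Pure-birth schedules* (constant, staged shifts at fixed ages before the
  present, and nine-shift staged approximations of an exponential decline)
  are simulated exactly by time-rescaling: a unit-rate conditioned Yule
  tree is drawn in operational time — forward simulation stopped just
  before the $(n+1)$-st birth, so the time spent with $k$ lineages is
  $\mathrm{Exp}(k)$ — and node ages are mapped through the inverse
  cumulative intensity of the schedule.  Shifts land exactly at the
  requested ages, and the Yule waiting-time law
  $\mathrm{Exp}(k\lambda)$ holds by construction.
* *Constant-rate birth--death with extinction* defaults to the exact
  conditioned reconstructed process (uniform prior on the unobserved
  origin): the $n-1$ branching times are iid draws with inverse CDF
  $t(u) = \log[(\lambda-u\mu)/(\lambda(1-u))]/r$, and the topology is
  assembled by random joins.  This is the conditioning used by the
  standard simulators in this field, and the recovery experiments
  reproduce their reference grand means — including the characteristic
  slight underestimation of $\lambda$ — only under it.  A forward
  first-passage variant (`method = "forward"`) is kept for comparison; it
  produces systematically younger trees and correspondingly higher rate
  estimates.
* *Subsampling* removes a uniform random tip set, the standard emulation
  of incomplete uniform sampling.
* The staged-decline generator spaces its nine shifts evenly over the
  expected crown age, solved from
  $\lambda_0(1-e^{-kT})/k = H_n - 1$ (the expected operational-time root
  age of the conditioned process); epoch rates are
  $\lambda_0 e^{-k t_{\mathrm{mid}}}$ at the epoch midpoints.  With
  constant $\mu > 0$ the generator falls back to an anchored forward
  simulation whose realised shift ages drift by the stopping-time
  fluctuation — acceptable for its purpose, and documented here because
  it is the one approximate code path in the module.

What the generator does *not* emulate: molecular data.  Real posterior
tree samples carry correlated node-age uncertainty from a clock model;
the simulated "samples" used in the tests are independent replicate
trees or single trees.  Passing recovery tests therefore demonstrate
correctness of the likelihoods, samplers and summaries under the stated
processes — not robustness to clock-model misspecification, non-uniform
taxon sampling, or diversification processes outside the implemented
families.

## Numerical choices

* Ultrametricity tolerance: $10^{-4}\times$ root age (clock outputs carry
  rounding noise); node ages are always recomputed from branch lengths.
* $\log(e^{rx} - a)$ is evaluated as $rx + \log(1 - ae^{-rx})$; all
  likelihood code returns $-\infty$ (sampler reject) rather than erroring
  on invalid parameters, while the user-facing wrappers validate inputs.
* HPD intervals are the exact shortest contiguous window containing
  $\lceil 0.95\,n\rceil$ sorted samples (brute-force-verified); ESS uses
  the autocorrelation sum truncated at the first negative lag.
* Ties and degenerate inputs: zero-length quadrature segments are skipped;
  equal-rate shift models collapse exactly onto the constant-rate value;
  a degenerate (all-equal) sample has a zero-width HPD and is its own
  mode.

## Problem sizes

The test suite and the acceptance script run the recovery experiments at
reduced replicate counts (8--20 trees per condition, 10--16 for the
heavier 400-tip and tempering experiments) with the full per-tree chain
settings, comparing grand means within three Monte-Carlo standard errors.
These sizes give standard errors a few times smaller than the expected
between-tree dispersion while keeping a complete run in the tens of
minutes on one core; the statistics themselves are computed exactly as
described above.

## Known limitations

* Extinction-rate posteriors are wide and skewed at low extinction
  fractions; the mean overestimates badly there and the mode should be
  read instead — this mirrors the behaviour of the underlying models, not
  an implementation artefact.
* Absolute marginal likelihoods from short ladders carry the
  first-interval bias discussed above; compare models, do not quote the
  absolute values.
* The meta-analysis model fixes two partitions per data set; more
  partitions require a different parameterisation.
* No reversible-jump over the number of shifts: competing shift counts
  are fixed models compared by Bayes factor.
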