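// Metropolis-Hastings chain for the single-tree diversification models.
//
// One "generation" performs a sequential sweep over the parameters, each
// updated by a reflected-normal proposal (symmetric, Hastings ratio 1) and
// accepted with probability min(1, [L'/L]^beta) under the flat priors whose
// bounds define the reflection interval.  With beta = 0 the chain samples
// the prior and the likelihood is evaluated only when a state is recorded.
// R's RNG is used throughout so results are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

double bd_loglik_core(const double* x, int m, double lambda, double mu,
                      double rho);
double pb_shift_core(const double* x, int m, const double* lam,
                     const double* sh, int n);
double spvar_core(const double* xdesc, int m, double l0, double m0, double k,
                  double z);

// fold a value into [lo, hi] by repeated boundary reflection
static inline double reflect_into(double v, double lo, double hi) {
  double w = hi - lo;
  if (!(w > 0.0)) return lo;
  double period = 2.0 * w;
  double y = v - lo;
  y -= std::floor(y / period) * period;  // now 0 <= y < 2w
  return (y <= w) ? lo + y : lo + (period - y);
}

// [[Rcpp::export(name = ".reflect_cpp")]]
double reflect_cpp(double v, double lo, double hi) {
  return reflect_into(v, lo, hi);
}

// model codes: 0 = pure-birth (lambda); 1 = birth-death (r, a);
// 2 = shift pure-birth (lambda_1..lambda_{n+1}, s_1..s_n);
// 3 = declining-speciation birth-death (lambda0, mu0, k)
// [[Rcpp::export(name = ".mcmc_chain_cpp")]]
List mcmc_chain_cpp(NumericVector x, int model, double rho, double z,
                    NumericVector init, NumericVector lower,
                    NumericVector upper, NumericVector scale, int ngen,
                    int sampfreq, int burnin, double beta, bool tune,
                    double target_acc) {
  int m = x.size();
  int np = init.size();
  std::vector<double> th(init.begin(), init.end());
  std::vector<double> lo(lower.begin(), lower.end());
  std::vector<double> hi(upper.begin(), upper.end());
  std::vector<double> sc(scale.begin(), scale.end());
  int nsh = (model == 2) ? (np - 1) / 2 : 0;
  int nlam = nsh + 1;
  const double* xx = REAL(x);

  auto loglik = [&](const std::vector<double>& t) -> double {
    switch (model) {
      case 0:
        return bd_loglik_core(xx, m, t[0], 0.0, rho);
      case 1: {
        double r = t[0], aa = t[1];
        if (!(r > 0.0) || aa < 0.0 || aa >= 1.0) return R_NegInf;
        double lam = r / (1.0 - aa);
        return bd_loglik_core(xx, m, lam, aa * lam, rho);
      }
      case 2:
        return pb_shift_core(xx, m, t.data(), t.data() + nlam, nsh);
      case 3:
        return spvar_core(xx, m, t[0], t[1], t[2], z);
    }
    return R_NegInf;
  };

  double cur = (beta > 0.0) ? loglik(th) : R_NegInf;
  int nsamp = (ngen - burnin) / sampfreq;
  NumericMatrix out(nsamp, np + 2);
  std::vector<long> acc(np, 0), tries(np, 0);
  std::vector<long> accb(np, 0), trib(np, 0);
  int batch = 0, row = 0;

  for (int g = 1; g <= ngen; ++g) {
    for (int p = 0; p < np; ++p) {
      double old = th[p];
      double prop = reflect_into(old + norm_rand() * sc[p], lo[p], hi[p]);
      th[p] = prop;
      bool ok = true;
      if (model == 2 && p >= nlam) {
        // shift times stay strictly ordered inside (0, root age)
        int si = p - nlam;
        if (!(prop > 0.0) || !(prop < xx[0])) ok = false;
        if (si > 0 && th[nlam + si - 1] >= prop) ok = false;
        if (si < nsh - 1 && prop >= th[nlam + si + 1]) ok = false;
      }
      bool accept = false;
      double lnew = cur;
      if (ok) {
        if (beta == 0.0) {
          accept = true;  // flat prior, symmetric proposal
        } else {
          lnew = loglik(th);
          if (std::isfinite(lnew)) {
            if (!std::isfinite(cur)) {
              accept = true;
            } else {
              double lr = beta * (lnew - cur);
              accept = (lr >= 0.0) || (unif_rand() < std::exp(lr));
            }
          }
        }
      }
      ++tries[p];
      ++trib[p];
      if (accept) {
        if (beta > 0.0) cur = lnew;
        ++acc[p];
        ++accb[p];
      } else {
        th[p] = old;
      }
    }
    if (tune && g <= burnin && g % 50 == 0) {
      ++batch;
      double gam = 1.0 / std::sqrt((double)batch);
      for (int p = 0; p < np; ++p) {
        double rate = (double)accb[p] / (double)trib[p];
        sc[p] *= std::exp(gam * (rate - target_acc));
        double w = hi[p] - lo[p];
        if (std::isfinite(w) && sc[p] > w) sc[p] = w;
        if (sc[p] < 1e-8) sc[p] = 1e-8;
        accb[p] = 0;
        trib[p] = 0;
      }
    }
    if (g > burnin && (g - burnin) % sampfreq == 0 && row < nsamp) {
      out(row, 0) = g;
      out(row, 1) = (beta == 0.0) ? loglik(th) : cur;
      for (int p = 0; p < np; ++p) out(row, 2 + p) = th[p];
      ++row;
    }
  }

  NumericVector arate(np), fscale(np);
  for (int p = 0; p < np; ++p) {
    arate[p] = tries[p] ? (double)acc[p] / (double)tries[p] : NA_REAL;
    fscale[p] = sc[p];
  }
  return List::create(_["samples"] = out, _["acceptance"] = arate,
                      _["scales"] = fscale);
}
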