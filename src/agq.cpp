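#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Random-intercept proportional-odds (cumulative logit) marginal
// log-likelihood via adaptive Gauss-Hermite quadrature.
//
// Model: P(Y_it <= k | x_it, u_i) = logistic(kappa_k - x_it'beta - u_i),
//        u_i ~ Normal(0, sigma^2).
// Each group's integral over u is centred and scaled at the posterior
// mode of the integrand (found by damped Newton; the per-group
// log-likelihood is concave in u), then evaluated with Gauss-Hermite
// nodes/weights supplied from R.

static inline double log_F(double x) {          // log logistic CDF
  if (x > 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

// log(F(a) - F(b)) for a > b, stable for extreme arguments
static inline double log_Fdiff(double a, double b) {
  if (!std::isfinite(b)) return log_F(a);          // b = -Inf
  if (!std::isfinite(a)) return log_F(-b);         // a = +Inf -> 1 - F(b)
  return log_F(a) + log_F(-b) + std::log1p(-std::exp(b - a));
}

static inline double Fl(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double fl(double x) {               // logistic density
  double p = Fl(x);
  return p * (1.0 - p);
}

// per-group log-likelihood at offset u, with first and second
// derivatives in u.  a_t = kappa_{y_t} - eta_t - u, b_t = kappa_{y_t-1} - ...
struct GroupDeriv { double val, d1, d2; };

static GroupDeriv group_ll(const std::vector<double>& lo,
                           const std::vector<double>& hi,
                           double u, bool derivs) {
  GroupDeriv g{0.0, 0.0, 0.0};
  for (size_t t = 0; t < lo.size(); ++t) {
    double a = hi[t] - u, b = lo[t] - u;
    double lp = log_Fdiff(a, b);
    g.val += lp;
    if (derivs) {
      double P = std::exp(lp);
      if (P < 1e-300) P = 1e-300;
      double fa = std::isfinite(a) ? fl(a) : 0.0;
      double fb = std::isfinite(b) ? fl(b) : 0.0;
      double d1 = (fb - fa) / P;                          // d log P / du
      double fpa = std::isfinite(a) ? fl(a) * (1.0 - 2.0 * Fl(a)) : 0.0;
      double fpb = std::isfinite(b) ? fl(b) * (1.0 - 2.0 * Fl(b)) : 0.0;
      double d2 = (fpa - fpb) / P - d1 * d1;              // d2 log P / du2
      g.d1 += d1;
      g.d2 += d2;
    }
  }
  return g;
}

// [[Rcpp::export]]
double agq_nll_cpp(NumericVector beta, NumericVector kappa, double sigma,
                   IntegerVector y, NumericMatrix X, IntegerVector grp,
                   int ngrp, NumericVector gh_x, NumericVector gh_w) {
  const int n = y.size(), p = X.ncol(), K = kappa.size() + 1, nq = gh_x.size();
  const double NEGINF = -std::numeric_limits<double>::infinity();
  const double POSINF = std::numeric_limits<double>::infinity();

  // linear predictor
  std::vector<double> eta(n, 0.0);
  for (int j = 0; j < p; ++j) {
    double bj = beta[j];
    for (int i = 0; i < n; ++i) eta[i] += bj * X(i, j);
  }

  // per-observation interval bounds kappa_{y-1} - eta, kappa_y - eta
  std::vector<std::vector<double>> lo(ngrp), hi(ngrp);
  for (int i = 0; i < n; ++i) {
    int yi = y[i];                                  // 1..K
    double l = (yi == 1) ? NEGINF : kappa[yi - 2] - eta[i];
    double h = (yi == K) ? POSINF : kappa[yi - 1] - eta[i];
    lo[grp[i]].push_back(l);
    hi[grp[i]].push_back(h);
  }

  double total = 0.0;
  const double sig2 = sigma * sigma;
  const bool degenerate = sigma < 1e-8;

  for (int gidx = 0; gidx < ngrp; ++gidx) {
    if (lo[gidx].empty()) continue;
    if (degenerate) {                               // u == 0 exactly
      total += group_ll(lo[gidx], hi[gidx], 0.0, false).val;
      continue;
    }
    // Newton for the mode of h(u) = ll(u) - u^2/(2 sig2)
    double u = 0.0;
    double h1 = 0.0, h2 = -1.0 / sig2;
    for (int it = 0; it < 50; ++it) {
      GroupDeriv g = group_ll(lo[gidx], hi[gidx], u, true);
      h1 = g.d1 - u / sig2;
      h2 = g.d2 - 1.0 / sig2;                       // strictly negative
      double step = -h1 / h2;
      if (std::fabs(step) > 5.0) step = (step > 0 ? 5.0 : -5.0);
      u += step;
      if (std::fabs(h1) < 1e-10 && std::fabs(step) < 1e-8) break;
    }
    { // refresh curvature at the mode
      GroupDeriv g = group_ll(lo[gidx], hi[gidx], u, true);
      h2 = g.d2 - 1.0 / sig2;
    }
    double s = 1.0 / std::sqrt(-h2);
    // log integral = log( sqrt(2) s sum_j w_j exp(z_j^2) f(u + sqrt(2) s z_j) )
    // with f(u) = exp(ll(u)) * dnorm(u; 0, sigma)
    double m = -POSINF;
    std::vector<double> expo(nq);
    for (int q = 0; q < nq; ++q) {
      double uq = u + M_SQRT2 * s * gh_x[q];
      double llq = group_ll(lo[gidx], hi[gidx], uq, false).val;
      double logf = llq - 0.5 * uq * uq / sig2 -
                    std::log(sigma) - 0.5 * std::log(2.0 * M_PI);
      expo[q] = std::log(gh_w[q]) + gh_x[q] * gh_x[q] + logf;
      if (expo[q] > m) m = expo[q];
    }
    double acc = 0.0;
    for (int q = 0; q < nq; ++q) acc += std::exp(expo[q] - m);
    total += m + std::log(acc) + 0.5 * std::log(2.0) + std::log(s);
  }
  return -total;
}
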