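#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log 1F1(beta; cc; g) for beta >= 0, cc > 0, g >= 0.
// All series terms are non-negative (Kummer-transformed form), so a streaming
// log-sum-exp is stable even at g ~ several hundred.
static double log_kummer(double beta, double cc, double g) {
  if (g <= 0.0 || beta <= 0.0) return 0.0;
  double logt = 0.0;          // log of term k (k = 0 term is 1)
  double m = 0.0, s = 1.0;    // running sum = exp(m) * s
  const double lg = std::log(g);
  for (int k = 0; k < 1000000; ++k) {
    double inc = std::log(beta + k) + lg - std::log(cc + k)
               - std::log1p((double)k);
    logt += inc;
    if (logt > m) {
      s = s * std::exp(m - logt) + 1.0;
      m = logt;
    } else {
      s += std::exp(logt - m);
    }
    // terms rise while the ratio exceeds 1, then decay monotonically:
    // safe to stop once past the peak and 45 nats below the maximum
    if (inc < 0.0 && logt < m - 45.0) break;
  }
  return m + std::log(s);
}

// Steady-state telegraph PMF over 0..n_max in d-normalized parameters.
// P(n) = [G(a+n)G(a+b)/(G(n+1)G(a+b+n)G(a))] g^n 1F1(a+n; a+b+n; -g)
// evaluated through the Kummer transform 1F1(a+n;a+b+n;-g) =
// e^{-g} 1F1(b; a+b+n; g), whose series has positive terms.
// [[Rcpp::export]]
NumericVector telegraph_pmf_cpp(double alpha, double beta, double gamma,
                                int n_max) {
  NumericVector p(n_max + 1);
  if (gamma == 0.0) { p[0] = 1.0; return p; }
  if (beta == 0.0) {               // gene always on: Poisson(gamma)
    for (int n = 0; n <= n_max; ++n)
      p[n] = std::exp(-gamma + n * std::log(gamma) - lgamma(n + 1.0));
    return p;
  }
  const double lga  = lgamma(alpha);
  const double lgab = lgamma(alpha + beta);
  const double lgg  = std::log(gamma);
  for (int n = 0; n <= n_max; ++n) {
    double cc = alpha + beta + n;
    double lp = lgamma(alpha + n) - lga + lgab - lgamma(cc)
              - lgamma(n + 1.0) + n * lgg - gamma
              + log_kummer(beta, cc, gamma);
    p[n] = std::exp(lp);
  }
  return p;
}

// Exact SSA for the telegraph model: promoter switching a/b, initiation c
// while active, first-order decay d. Each cell starts inactive with 0 mRNA
// and is evolved to t_end; the count at t_end is returned. Uses R's RNG.
// [[Rcpp::export]]
IntegerVector sim_counts_cpp(double a, double b, double c, double d,
                             int n_cells, double t_end) {
  IntegerVector out(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    int s = 0, n = 0;
    double t = 0.0;
    for (;;) {
      double r_sw = s ? b : a;
      double r_in = s ? c : 0.0;
      double r_de = d * n;
      double rtot = r_sw + r_in + r_de;
      if (rtot <= 0.0) break;
      t += R::exp_rand() / rtot;
      if (t > t_end) break;
      double u = R::unif_rand() * rtot;
      if (u < r_sw) s = 1 - s;
      else if (u < r_sw + r_in) ++n;
      else --n;
    }
    out[i] = n;
  }
  return out;
}

// Exact SSA for the promoter state + initiation events of one trace.
// Returns the times of state flips and of initiation events on [0, t_end].
// a may be zero (pulse preset), b may be zero (always-on preset).
// [[Rcpp::export]]
List sim_trace_cpp(double a, double b, double c, int start_state,
                   double t_end) {
  std::vector<double> flips, inits;
  int s = start_state;
  double t = 0.0;
  for (;;) {
    double r_sw = s ? b : a;
    double r_in = s ? c : 0.0;
    double rtot = r_sw + r_in;
    if (rtot <= 0.0) break;
    t += R::exp_rand() / rtot;
    if (t > t_end) break;
    double u = R::unif_rand() * rtot;
    if (u < r_sw) { s = 1 - s; flips.push_back(t); }
    else inits.push_back(t);
  }
  return List::create(_["flips"] = wrap(flips), _["inits"] = wrap(inits),
                      _["start_state"] = start_state);
}
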