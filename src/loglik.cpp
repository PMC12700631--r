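// Marginal-likelihood kernels: each target observation contributes a
// univariate integral mixing its response density over the Cauchy random
// effect.  Evaluated with an adaptive Gauss-Kronrod 15(7) rule on a
// substituted coordinate, with breakpoints seeded at the integrand's known
// concentration points so narrow Cauchy spikes are never missed.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// QUADPACK dqk15 abscissae/weights on [-1, 1]
static const double XGK[8] = {
  0.991455371120813, 0.949107912342759, 0.864864423359769,
  0.741531185599394, 0.586087235467691, 0.405845151377397,
  0.207784955007898, 0.0};
static const double WGK[8] = {
  0.022935322010529, 0.063092092629979, 0.104790010322250,
  0.140653259715525, 0.169004726639267, 0.190350578064785,
  0.204432940075298, 0.209482141084728};
static const double WG[4] = {
  0.129484966168870, 0.279705391489277, 0.381830050505119,
  0.417959183673469};

template <class F>
static void qk15(const F& f, double a, double b, double& res, double& err) {
  const double c = 0.5 * (a + b), h = 0.5 * (b - a);
  double fc = f(c);
  double rk = WGK[7] * fc, rg = WG[3] * fc;
  for (int j = 0; j < 7; ++j) {
    double f1 = f(c - h * XGK[j]), f2 = f(c + h * XGK[j]);
    rk += WGK[j] * (f1 + f2);
    if (j % 2 == 1) rg += WG[j / 2] * (f1 + f2);
  }
  res = rk * h;
  err = std::fabs((rk - rg) * h);
}

struct Seg { double a, b, r, e; };

// Globally adaptive bisection over an initial partition `pts` (sorted).
template <class F>
static double adapt_quad(const F& f, std::vector<double>& pts,
                         double atol, double rtol, int limit) {
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  std::vector<Seg> segs;
  segs.reserve(64);
  for (size_t i = 0; i + 1 < pts.size(); ++i) {
    Seg s;
    s.a = pts[i];
    s.b = pts[i + 1];
    qk15(f, s.a, s.b, s.r, s.e);
    segs.push_back(s);
  }
  while ((int)segs.size() < limit) {
    double tot = 0.0, etot = 0.0, worst_e = -1.0;
    size_t worst = 0;
    for (size_t i = 0; i < segs.size(); ++i) {
      tot += segs[i].r;
      etot += segs[i].e;
      if (segs[i].e > worst_e) { worst_e = segs[i].e; worst = i; }
    }
    if (etot <= std::max(atol, rtol * std::fabs(tot))) break;
    Seg s = segs[worst];
    double m = 0.5 * (s.a + s.b);
    if (m <= s.a || m >= s.b) break;  // machine-width interval
    Seg l, r;
    l.a = s.a; l.b = m;
    r.a = m;   r.b = s.b;
    qk15(f, l.a, l.b, l.r, l.e);
    qk15(f, r.a, r.b, r.r, r.e);
    segs[worst] = l;
    segs.push_back(r);
  }
  double tot = 0.0;
  for (size_t i = 0; i < segs.size(); ++i) tot += segs[i].r;
  return tot;
}

static inline double dnorm_std(double t) {
  return 0.3989422804014326779 * std::exp(-0.5 * t * t);
}

static inline double expit(double z) {
  if (z > 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// log integral N(y | beta f, sigma^2) Cauchy(beta | delta, gamma) dbeta.
// Substituting t = (beta - y/f) |f| / sigma turns it into a standard-normal
// expectation of the Cauchy density; the Gaussian weight underflows beyond
// |t| = 39, so the range is truncated there.  Breakpoints are seeded at the
// Cauchy peak (t*, half-width gamma |f| / sigma) and at the Gaussian core.
static double term_cont(double y, double f, double delta, double gamma,
                        double sigma, double atol, double rtol, int limit,
                        double bound) {
  const double m = y / f, a = sigma / std::fabs(f);
  const double g2 = gamma * gamma;
  const double cfac = gamma / M_PI;
  auto g = [&](double t) {
    double d = m + a * t - delta;
    return dnorm_std(t) * cfac / (d * d + g2);
  };
  const double tstar = (delta - m) / a;  // t at the Cauchy mode
  const double w = gamma / a;
  std::vector<double> pts;
  pts.push_back(-bound);
  pts.push_back(bound);
  double extra[4] = {0.0, -6.0, 6.0, tstar};
  for (int i = 0; i < 4; ++i)
    if (extra[i] > -bound && extra[i] < bound) pts.push_back(extra[i]);
  // geometric ladder outward from the Cauchy spike: its tail mass decays
  // only like 1/t, spanning many octaves when gamma |f| / sigma is tiny
  for (double h = 5.0 * w; h < 2.0 * bound; h *= 8.0) {
    if (tstar - h > -bound) pts.push_back(tstar - h);
    if (tstar + h < bound) pts.push_back(tstar + h);
    if (tstar - h <= -bound && tstar + h >= bound) break;
  }
  double I = adapt_quad(g, pts, atol, rtol, limit);
  if (!(I > 0.0)) return R_NegInf;
  return std::log(I) - std::log(std::fabs(f));
}

// log integral expit(beta f)^y (1-expit(beta f))^(1-y) Cauchy(beta) dbeta.
// Substituting beta = delta + gamma tan(u) integrates the Bernoulli factor
// against the Cauchy measure over u in (-pi/2, pi/2); breakpoints are seeded
// where the expit switches (|beta f| < ~40).
static double term_bin(int y, double f, double delta, double gamma,
                       double atol, double rtol, int limit) {
  if (f == 0.0) return -M_LN2;  // expit(0) = 1/2 regardless of beta
  const double c = (y == 1) ? f : -f;
  auto g = [&](double u) {
    double beta = delta + gamma * std::tan(u);
    return expit(c * beta) / M_PI;
  };
  const double hp = M_PI_2;
  std::vector<double> pts;
  pts.push_back(-hp);
  pts.push_back(hp);
  double bw = 40.0 / std::fabs(c);
  double extra[3] = {std::atan(-delta / gamma),
                     std::atan((-bw - delta) / gamma),
                     std::atan((bw - delta) / gamma)};
  pts.push_back(0.0);
  for (int i = 0; i < 3; ++i)
    if (extra[i] > -hp && extra[i] < hp) pts.push_back(extra[i]);
  double I = adapt_quad(g, pts, atol, rtol, limit);
  if (!(I > 0.0)) return R_NegInf;
  if (I > 1.0) I = 1.0;  // round-off guard: it is a probability
  return std::log(I);
}

// [[Rcpp::export(name = ".term_cont_cpp")]]
double term_cont_cpp(double y, double f, double delta, double gamma,
                     double sigma, double atol, double rtol,
                     double bound) {
  return term_cont(y, f, delta, gamma, sigma, atol, rtol, 512, bound);
}

// [[Rcpp::export(name = ".term_bin_cpp")]]
double term_bin_cpp(int y, double f, double delta, double gamma,
                    double atol, double rtol) {
  return term_bin(y, f, delta, gamma, atol, rtol, 512);
}

// [[Rcpp::export(name = ".loglik_cont_cpp")]]
double loglik_cont_cpp(NumericVector y, NumericVector f, double delta,
                       double gamma, double sigma, double atol, double rtol,
                       double bound) {
  const int n = y.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = term_cont(y[i], f[i], delta, gamma, sigma, atol, rtol, 512,
                         bound);
    if (!R_FINITE(t)) return R_NegInf;
    s += t;
  }
  return s;
}

// [[Rcpp::export(name = ".loglik_bin_cpp")]]
double loglik_bin_cpp(IntegerVector y, NumericVector f, double delta,
                      double gamma, double atol, double rtol) {
  const int n = y.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = term_bin(y[i], f[i], delta, gamma, atol, rtol, 512);
    if (!R_FINITE(t)) return R_NegInf;
    s += t;
  }
  return s;
}
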