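#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// KL(p_b || q) for the tilted pmf p_b(k) ∝ q(k) exp(-b d2_k), computed in
// log space. Writes p_b into `p` and returns the divergence in nats.
static double tilt_kl(const std::vector<double>& logq,
                      const std::vector<double>& d2,
                      double b, std::vector<double>& p,
                      double* var_d2 = nullptr) {
  const int m = (int)logq.size();
  double mx = -INFINITY;
  for (int k = 0; k < m; ++k) {
    p[k] = logq[k] - b * d2[k];
    if (p[k] > mx) mx = p[k];
  }
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    p[k] = std::exp(p[k] - mx);
    s += p[k];
  }
  // log p_k - log q_k = -b d2_k - logZ with logZ = log sum q exp(-b d2)
  const double logZ = std::log(s) + mx;
  double kl = 0.0, e1 = 0.0, e2 = 0.0;
  for (int k = 0; k < m; ++k) {
    p[k] /= s;
    if (p[k] > 0) {
      kl += p[k] * (-b * d2[k] - logZ);
      e1 += p[k] * d2[k];
      e2 += p[k] * d2[k] * d2[k];
    }
  }
  if (var_d2) *var_d2 = e2 - e1 * e1;
  return kl;
}

// Solve b >= 0 with KL(p_b||q) = C by bisection; fills pmf row.
// Returns b (Inf when saturated). KL is strictly increasing in b.
static double solve_one(const std::vector<double>& logq,
                        int n_idx, double C, double tol,
                        std::vector<double>& p, double* kl_out,
                        bool* saturated) {
  const int m = (int)logq.size();
  std::vector<double> d2(m);
  for (int k = 0; k < m; ++k) {
    double d = (double)(k - n_idx);
    d2[k] = d * d;
  }
  *saturated = false;
  if (C <= 0.0) {
    for (int k = 0; k < m; ++k) p[k] = std::exp(logq[k]);
    *kl_out = 0.0;
    return 0.0;
  }
  double kl_max = -logq[n_idx]; // sup over b of KL(p_b||q)
  if (C >= kl_max - 1e-12) {
    std::fill(p.begin(), p.end(), 0.0);
    p[n_idx] = 1.0;
    *kl_out = kl_max;
    *saturated = true;
    return R_PosInf;
  }
  // Tiny budgets: KL(b) ~ (b^2/2) Var_q[(n-k)^2], below the resolution of
  // the finite-tolerance solve; use the asymptotic multiplier directly so
  // the zero-capacity limit degrades smoothly onto q.
  if (C < 1e-10) {
    double e1 = 0.0, e2 = 0.0;
    for (int k = 0; k < m; ++k) {
      double qk = std::exp(logq[k]);
      e1 += qk * d2[k];
      e2 += qk * d2[k] * d2[k];
    }
    double v = e2 - e1 * e1;
    double b = (v > 0) ? std::sqrt(2.0 * C / v) : 0.0;
    *kl_out = tilt_kl(logq, d2, b, p);
    return b;
  }
  // Bracket, then safeguarded Newton on KL(b) = C: the divergence is
  // strictly increasing with derivative dKL/db = b * Var_{p_b}[(n-k)^2].
  double lo = 0.0, hi = 1.0;
  double kl_hi = tilt_kl(logq, d2, hi, p);
  int guard = 0;
  while (kl_hi < C && hi < 1e9 && guard++ < 64) {
    hi *= 4.0;
    kl_hi = tilt_kl(logq, d2, hi, p);
  }
  if (kl_hi < C) stop("solve_beta: failed to bracket multiplier below 1e9");
  double b = 0.5 * hi, kl, var;
  for (int it = 0; it < 200; ++it) {
    kl = tilt_kl(logq, d2, b, p, &var);
    if (std::fabs(kl - C) <= tol) break;
    if (kl < C) lo = b; else hi = b;
    double deriv = b * var;
    double step = (deriv > 0) ? (C - kl) / deriv : 0.0;
    double bn = b + step;
    if (!(bn > lo && bn < hi)) bn = 0.5 * (lo + hi);
    b = bn;
  }
  *kl_out = kl;
  return b;
}

// [[Rcpp::export]]
List tim_solve_beta_cpp(NumericVector q, int n, double C_target, double tol) {
  const int m = q.size();
  std::vector<double> logq(m), p(m);
  for (int k = 0; k < m; ++k) logq[k] = std::log(q[k]);
  double kl; bool sat;
  double b = solve_one(logq, n - 1, C_target, tol, p, &kl, &sat);
  NumericVector pmf(m);
  for (int k = 0; k < m; ++k) pmf[k] = p[k];
  return List::create(_["b"] = b, _["pmf"] = pmf, _["kl"] = kl,
                      _["saturated"] = sat);
}

// [[Rcpp::export]]
NumericMatrix tim_solve_batch_cpp(NumericVector q, IntegerVector n,
                                  NumericVector C, double tol) {
  const int m = q.size();
  const int rows = n.size();
  if (C.size() != rows) stop("n and C must have equal length");
  std::vector<double> logq(m), p(m);
  for (int k = 0; k < m; ++k) logq[k] = std::log(q[k]);
  NumericMatrix out(rows, m);
  double kl; bool sat;
  for (int i = 0; i < rows; ++i) {
    solve_one(logq, n[i] - 1, C[i], tol, p, &kl, &sat);
    for (int k = 0; k < m; ++k) out(i, k) = p[k];
  }
  return out;
}

// Discrete SEB pmf: quadrature over the representation r ~ N(log n, nu^2).
// For each grid point the integer posterior mean is rounded
// (half away from zero) and the trapezoid-weighted normal density mass is
// accumulated on that integer.
// [[Rcpp::export]]
NumericVector seb_discrete_pmf_cpp(NumericVector prior, double logn,
                                   double nu, int n_grid, double half_width) {
  const int m = prior.size();
  std::vector<double> logprior(m), logj(m);
  for (int j = 0; j < m; ++j) {
    logprior[j] = std::log(prior[j]);
    logj[j] = std::log((double)(j + 1));
  }
  NumericVector out(m);
  const double lo = logn - half_width * nu;
  const double hi = logn + half_width * nu;
  const double h = (hi - lo) / (n_grid - 1);
  const double inv2nu2 = 1.0 / (2.0 * nu * nu);
  double wsum = 0.0;
  std::vector<double> lw(m);
  for (int i = 0; i < n_grid; ++i) {
    double r = lo + h * i;
    // posterior over integers given representation r
    double mx = -INFINITY;
    for (int j = 0; j < m; ++j) {
      double d = r - logj[j];
      lw[j] = logprior[j] - d * d * inv2nu2;
      if (lw[j] > mx) mx = lw[j];
    }
    double s = 0.0, num = 0.0;
    for (int j = 0; j < m; ++j) {
      double w = std::exp(lw[j] - mx);
      s += w;
      num += w * (double)(j + 1);
    }
    double post_mean = num / s;
    int k = (int)std::floor(post_mean + 0.5);
    if (k < 1) k = 1;
    if (k > m) k = m;
    double z = (r - logn) / nu;
    double dens = std::exp(-0.5 * z * z);
    double w = dens * ((i == 0 || i == n_grid - 1) ? 0.5 : 1.0);
    out[k - 1] += w;
    wsum += w;
  }
  for (int j = 0; j < m; ++j) out[j] /= wsum;
  return out;
}
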