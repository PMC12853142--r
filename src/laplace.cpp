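// Laplace-approximation marginal -2 log-likelihood for the reduced PBPK
// structural model with diagonal log-normal random effects (on CL_int, V,
// ka) and combined proportional + additive residual error.
//
// The per-subject joint deviance is minimised over eta by a damped Newton
// iteration with finite-difference derivatives; the marginal contribution
// is J(eta_hat) + log|Omega| + log det H, where H is the Hessian of the
// negative log joint density (half the deviance Hessian).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double LOG2PI = 1.8378770664093454836;

struct Model {
  const int *obs_subject;
  const double *obs_dv;
  const int *contrib_obs;
  const double *contrib_amt;
  const double *contrib_tad;
  const double *contrib_ii;
  const int *contrib_ss;
  const double *clint_base, *qh, *clr, *vbase, *kabase;
  double fub, fafg;
  int use_cl, use_v, use_ka;  // eta layout flags
  double sig_prop, sig_add;
  const double *omega;  // variances, length q
  int q;
  // CSR offsets
  const int *obs_start;      // per subject, length n_sub + 1
  const int *contrib_start;  // per obs, length n_obs + 1
};

// one-compartment oral concentration contribution (ng/mL)
inline double conc_contrib(double amt, double tad, int ss, double ii,
                           double F, double V, double CL, double ka) {
  if (tad < 0.0) return 0.0;
  double ke = CL / V;
  if (std::fabs(ka - ke) < 1e-8 * ke) ka = ka * (1.0 + 1e-6);
  double coef = 1000.0 * F * amt * ka / (V * (ka - ke));
  if (ss) {
    return coef * (std::exp(-ke * tad) / (1.0 - std::exp(-ke * ii)) -
                   std::exp(-ka * tad) / (1.0 - std::exp(-ka * ii)));
  }
  return coef * (std::exp(-ke * tad) - std::exp(-ka * tad));
}

// per-subject deviance-scale objective J(eta)
double J_subject(const Model &m, int i, const double *eta) {
  int k = 0;
  double e_cl = m.use_cl ? eta[k++] : 0.0;
  double e_v = m.use_v ? eta[k++] : 0.0;
  double e_ka = m.use_ka ? eta[k++] : 0.0;

  double clint = m.clint_base[i] * std::exp(e_cl);
  double denom = m.qh[i] + m.fub * clint;
  double clh = m.qh[i] * m.fub * clint / denom;
  double fh = m.qh[i] / denom;
  double cl = clh + m.clr[i];
  double F = m.fafg * fh;
  double V = m.vbase[i] * std::exp(e_v);
  double ka = m.kabase[i] * std::exp(e_ka);

  double J = 0.0;
  for (int o = m.obs_start[i]; o < m.obs_start[i + 1]; ++o) {
    double f = 0.0;
    for (int c = m.contrib_start[o]; c < m.contrib_start[o + 1]; ++c) {
      f += conc_contrib(m.contrib_amt[c], m.contrib_tad[c], m.contrib_ss[c],
                        m.contrib_ii[c], F, V, cl, ka);
    }
    if (f < 0.0) f = 0.0;
    double g2 = m.sig_prop * m.sig_prop * f * f + m.sig_add * m.sig_add;
    double r = m.obs_dv[o] - f;
    J += r * r / g2 + std::log(g2) + LOG2PI;
  }
  for (int j = 0; j < m.q; ++j) J += eta[j] * eta[j] / m.omega[j];
  return J;
}

// finite-difference gradient and Hessian of J for subject i
void fd_derivs(const Model &m, int i, const double *eta, double *grad,
               double *hess /* q x q */) {
  const double h = 1e-4;
  int q = m.q;
  double e[3], f0 = J_subject(m, i, eta);
  for (int a = 0; a < q; ++a) {
    for (int j = 0; j < q; ++j) e[j] = eta[j];
    e[a] = eta[a] + h;
    double fp = J_subject(m, i, e);
    e[a] = eta[a] - h;
    double fm = J_subject(m, i, e);
    grad[a] = (fp - fm) / (2.0 * h);
    hess[a * q + a] = (fp - 2.0 * f0 + fm) / (h * h);
  }
  for (int a = 0; a < q; ++a) {
    for (int b = a + 1; b < q; ++b) {
      for (int j = 0; j < q; ++j) e[j] = eta[j];
      e[a] += h; e[b] += h;
      double fpp = J_subject(m, i, e);
      e[b] -= 2.0 * h;
      double fpm = J_subject(m, i, e);
      e[a] -= 2.0 * h;
      double fmm = J_subject(m, i, e);
      e[b] += 2.0 * h;
      double fmp = J_subject(m, i, e);
      double v = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
      hess[a * q + b] = v;
      hess[b * q + a] = v;
    }
  }
}

// solve (H + ridge I) d = -g for q <= 3; returns log det of H (no ridge)
// via detH output; returns false if solve fails.
bool solve_newton(const double *hess, const double *grad, int q,
                  double ridge, double *step, double *detH) {
  double A[9];
  for (int j = 0; j < q * q; ++j) A[j] = hess[j];
  for (int j = 0; j < q; ++j) A[j * q + j] += ridge;
  if (q == 1) {
    *detH = hess[0];
    if (A[0] <= 0.0) return false;
    step[0] = -grad[0] / A[0];
    return true;
  }
  if (q == 2) {
    *detH = hess[0] * hess[3] - hess[1] * hess[2];
    double det = A[0] * A[3] - A[1] * A[2];
    if (det <= 0.0 || A[0] <= 0.0) return false;
    step[0] = -(A[3] * grad[0] - A[1] * grad[1]) / det;
    step[1] = -(-A[2] * grad[0] + A[0] * grad[1]) / det;
    return true;
  }
  // q == 3: cofactor expansion
  double dH = hess[0] * (hess[4] * hess[8] - hess[5] * hess[7]) -
              hess[1] * (hess[3] * hess[8] - hess[5] * hess[6]) +
              hess[2] * (hess[3] * hess[7] - hess[4] * hess[6]);
  *detH = dH;
  double det = A[0] * (A[4] * A[8] - A[5] * A[7]) -
               A[1] * (A[3] * A[8] - A[5] * A[6]) +
               A[2] * (A[3] * A[7] - A[4] * A[6]);
  if (det <= 0.0) return false;
  double inv[9];
  inv[0] = (A[4] * A[8] - A[5] * A[7]) / det;
  inv[1] = (A[2] * A[7] - A[1] * A[8]) / det;
  inv[2] = (A[1] * A[5] - A[2] * A[4]) / det;
  inv[3] = (A[5] * A[6] - A[3] * A[8]) / det;
  inv[4] = (A[0] * A[8] - A[2] * A[6]) / det;
  inv[5] = (A[2] * A[3] - A[0] * A[5]) / det;
  inv[6] = (A[3] * A[7] - A[4] * A[6]) / det;
  inv[7] = (A[1] * A[6] - A[0] * A[7]) / det;
  inv[8] = (A[0] * A[4] - A[1] * A[3]) / det;
  for (int a = 0; a < 3; ++a) {
    step[a] = 0.0;
    for (int b = 0; b < 3; ++b) step[a] -= inv[a * 3 + b] * grad[b];
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
List ofv_laplace_cpp(IntegerVector obs_subject, NumericVector obs_dv,
                     IntegerVector contrib_obs, NumericVector contrib_amt,
                     NumericVector contrib_tad, NumericVector contrib_ii,
                     IntegerVector contrib_ss, NumericVector clint_base,
                     NumericVector qh, NumericVector clr, NumericVector vbase,
                     NumericVector kabase, double fub, double fafg,
                     LogicalVector eta_flags, NumericVector omega,
                     double sig_prop, double sig_add,
                     NumericMatrix eta_start) {
  int n_obs = obs_dv.size();
  int n_sub = clint_base.size();
  int q = omega.size();

  // CSR offsets (inputs must be sorted/grouped)
  std::vector<int> obs_start(n_sub + 1, 0);
  for (int o = 0; o < n_obs; ++o) obs_start[obs_subject[o] + 1]++;
  for (int i = 0; i < n_sub; ++i) obs_start[i + 1] += obs_start[i];
  std::vector<int> contrib_start(n_obs + 1, 0);
  for (int c = 0; c < contrib_obs.size(); ++c)
    contrib_start[contrib_obs[c] + 1]++;
  for (int o = 0; o < n_obs; ++o) contrib_start[o + 1] += contrib_start[o];

  Model m;
  m.obs_subject = INTEGER(obs_subject);
  m.obs_dv = REAL(obs_dv);
  m.contrib_obs = INTEGER(contrib_obs);
  m.contrib_amt = REAL(contrib_amt);
  m.contrib_tad = REAL(contrib_tad);
  m.contrib_ii = REAL(contrib_ii);
  m.contrib_ss = INTEGER(contrib_ss);
  m.clint_base = REAL(clint_base);
  m.qh = REAL(qh);
  m.clr = REAL(clr);
  m.vbase = REAL(vbase);
  m.kabase = REAL(kabase);
  m.fub = fub;
  m.fafg = fafg;
  m.use_cl = eta_flags[0];
  m.use_v = eta_flags[1];
  m.use_ka = eta_flags[2];
  m.sig_prop = sig_prop;
  m.sig_add = sig_add;
  m.omega = REAL(omega);
  m.q = q;
  m.obs_start = obs_start.data();
  m.contrib_start = contrib_start.data();

  NumericMatrix eta_hat(n_sub, std::max(q, 1));
  NumericVector ofv_i(n_sub);
  double log_det_omega = 0.0;
  for (int j = 0; j < q; ++j) log_det_omega += std::log(omega[j]);

  double total = 0.0;
  int n_fail = 0;
  for (int i = 0; i < n_sub; ++i) {
    if (q == 0 || obs_start[i + 1] == obs_start[i]) {
      // no random effects, or no observations: eta = 0 (prior mode)
      double eta0[3] = {0.0, 0.0, 0.0};
      double Ji = J_subject(m, i, eta0);
      if (q > 0 && obs_start[i + 1] == obs_start[i]) {
        // empty subject contributes nothing beyond constants; keep 0
        Ji = 0.0;
      }
      ofv_i[i] = Ji;
      total += Ji;
      continue;
    }
    double eta[3] = {0.0, 0.0, 0.0};
    for (int j = 0; j < q; ++j) eta[j] = eta_start(i, j);
    double J = J_subject(m, i, eta);
    double grad[3], hess[9], step[3], detH;
    bool ok = true;
    for (int it = 0; it < 50; ++it) {
      fd_derivs(m, i, eta, grad, hess);
      double gnorm = 0.0;
      for (int j = 0; j < q; ++j) gnorm += grad[j] * grad[j];
      if (std::sqrt(gnorm) < 1e-9) break;
      double ridge = 0.0;
      while (!solve_newton(hess, grad, q, ridge, step, &detH)) {
        ridge = (ridge == 0.0) ? 1e-4 : ridge * 10.0;
        if (ridge > 1e8) { ok = false; break; }
      }
      if (!ok) break;
      // damped step
      double lam = 1.0, Jnew = 0.0;
      double trial[3];
      bool improved = false;
      for (int ls = 0; ls < 30; ++ls) {
        for (int j = 0; j < q; ++j) trial[j] = eta[j] + lam * step[j];
        Jnew = J_subject(m, i, trial);
        if (Jnew <= J + 1e-12) { improved = true; break; }
        lam *= 0.5;
      }
      if (!improved) break;
      double delta = J - Jnew;
      for (int j = 0; j < q; ++j) eta[j] = trial[j];
      J = Jnew;
      if (delta < 1e-11) break;
    }
    fd_derivs(m, i, eta, grad, hess);
    solve_newton(hess, grad, q, 0.0, step, &detH);
    // Hessian of the negative log joint is half the deviance Hessian
    double detH_half = detH / std::pow(2.0, q);
    if (!(detH_half > 0.0)) { detH_half = 1e-10; n_fail++; ok = false; }
    double Ji = J + log_det_omega + std::log(detH_half);
    ofv_i[i] = Ji;
    total += Ji;
    for (int j = 0; j < q; ++j) eta_hat(i, j) = eta[j];
  }

  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                      _["eta"] = eta_hat, _["n_inner_fail"] = n_fail);
}
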