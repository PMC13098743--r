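#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Semi-infinite time-domain diffuse reflectance (extrapolated boundary,
// two image sources). Units: t in ps, v in mm/ps, lengths in mm, mua/musp
// in 1/mm. Amplitude is arbitrary (fits estimate scale as a nuisance).
static void td_curve(const double* t, int n, double mua, double musp,
                     double rho, double v, double z0, double zb,
                     double* out) {
  const double D  = 1.0 / (3.0 * musp);
  const double zp = z0 + 2.0 * zb;
  const double c0 = 0.5 * std::pow(4.0 * M_PI * D * v, -1.5);
  const double rho2 = rho * rho;
  for (int i = 0; i < n; ++i) {
    const double ti = t[i];
    if (ti <= 0.0) { out[i] = 0.0; continue; }
    const double q = 4.0 * D * v * ti;
    const double e = -mua * v * ti - rho2 / q;
    // exp(e) underflows harmlessly to 0 for very early/late times
    const double bracket = z0 * std::exp(-z0 * z0 / q) + zp * std::exp(-zp * zp / q);
    out[i] = c0 * std::pow(ti, -2.5) * std::exp(e) * bracket;
    if (!std::isfinite(out[i]) || out[i] < 0.0) out[i] = 0.0;
  }
}

// [[Rcpp::export(name = ".cpp_td_reflectance")]]
NumericVector cpp_td_reflectance(NumericVector t_ps, double mua, double musp,
                                 double rho, double v, double z0, double zb) {
  NumericVector out(t_ps.size());
  td_curve(t_ps.begin(), t_ps.size(), mua, musp, rho, v, z0, zb, out.begin());
  return out;
}

// Causal discrete convolution truncated to the model length.
static void conv_causal(const double* m, int n, const double* irf, int k,
                        double* out) {
  for (int i = 0; i < n; ++i) out[i] = 0.0;
  for (int j = 0; j < k; ++j) {
    const double w = irf[j];
    if (w == 0.0) continue;
    for (int i = j; i < n; ++i) out[i] += w * m[i - j];
  }
}

// [[Rcpp::export(name = ".cpp_conv_causal")]]
NumericVector cpp_conv_causal(NumericVector model, NumericVector irf) {
  NumericVector out(model.size());
  conv_causal(model.begin(), model.size(), irf.begin(), irf.size(), out.begin());
  return out;
}

// Normalized field autocorrelation g1 for the semi-infinite correlation
// diffusion model with Brownian dynamics (msd = 6 * BFI * tau).
// bfi in mm^2/s, tau in s, k0 in 1/mm.
static void g1_curve(const double* tau, int n, double mua, double musp,
                     double k0, double bfi, double rho, double z0, double zb,
                     double* out) {
  const double r1 = std::sqrt(rho * rho + z0 * z0);
  const double zp = z0 + 2.0 * zb;
  const double r2 = std::sqrt(rho * rho + zp * zp);
  const double K0 = std::sqrt(3.0 * mua * musp);
  const double g0 = std::exp(-K0 * r1) / r1 - std::exp(-K0 * r2) / r2;
  for (int i = 0; i < n; ++i) {
    const double K = std::sqrt(3.0 * mua * musp +
                               6.0 * musp * musp * k0 * k0 * bfi * tau[i]);
    const double g = std::exp(-K * r1) / r1 - std::exp(-K * r2) / r2;
    out[i] = g / g0;
    if (!std::isfinite(out[i]) || out[i] < 0.0) out[i] = 0.0;
  }
}

// [[Rcpp::export(name = ".cpp_dcs_g1")]]
NumericVector cpp_dcs_g1(NumericVector tau, double mua, double musp, double k0,
                         double bfi_mm2s, double rho, double z0, double zb) {
  NumericVector out(tau.size());
  g1_curve(tau.begin(), tau.size(), mua, musp, k0, bfi_mm2s, rho, z0, zb,
           out.begin());
  return out;
}

// ---- small dense solver for the LM normal equations (p <= 4) -------------

static bool solve_sym(double A[4][4], double b[4], int p, double x[4]) {
  double M[4][5];
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) M[i][j] = A[i][j];
    M[i][p] = b[i];
  }
  for (int c = 0; c < p; ++c) {
    int piv = c;
    for (int r = c + 1; r < p; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (std::fabs(M[piv][c]) < 1e-300) return false;
    if (piv != c)
      for (int j = c; j <= p; ++j) std::swap(M[c][j], M[piv][j]);
    for (int r = c + 1; r < p; ++r) {
      const double f = M[r][c] / M[c][c];
      for (int j = c; j <= p; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int r = p - 1; r >= 0; --r) {
    double s = M[r][p];
    for (int j = r + 1; j < p; ++j) s -= M[r][j] * x[j];
    x[r] = s / M[r][r];
  }
  for (int i = 0; i < p; ++i)
    if (!std::isfinite(x[i])) return false;
  return true;
}

// Generic Levenberg-Marquardt over p parameters given a residual functor.
// Returns true when converged. Residual function fills r (length m) and
// returns false for invalid parameter values.
template <typename F>
static bool lm_fit(F resid, double* theta, int p, int m, int max_iter,
                   double tol, int* iter_out, double* cost_out) {
  std::vector<double> r(m), rt(m), J(m * p);
  double th[4], trial[4];
  for (int i = 0; i < p; ++i) th[i] = theta[i];
  if (!resid(th, r.data())) return false;
  double cost = 0.0;
  for (int i = 0; i < m; ++i) cost += r[i] * r[i];
  double lambda = 1e-3;
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // forward-difference jacobian
    for (int j = 0; j < p; ++j) {
      const double h = 1e-6 * std::max(1.0, std::fabs(th[j]));
      for (int i = 0; i < p; ++i) trial[i] = th[i];
      trial[j] += h;
      if (!resid(trial, rt.data())) {
        for (int i = 0; i < m; ++i) J[i * p + j] = 0.0;
        continue;
      }
      for (int i = 0; i < m; ++i) J[i * p + j] = (rt[i] - r[i]) / h;
    }
    double JtJ[4][4], Jtr[4];
    for (int a = 0; a < p; ++a) {
      Jtr[a] = 0.0;
      for (int b = 0; b < p; ++b) JtJ[a][b] = 0.0;
    }
    for (int i = 0; i < m; ++i)
      for (int a = 0; a < p; ++a) {
        Jtr[a] += J[i * p + a] * r[i];
        for (int b = a; b < p; ++b) JtJ[a][b] += J[i * p + a] * J[i * p + b];
      }
    for (int a = 0; a < p; ++a)
      for (int b = 0; b < a; ++b) JtJ[a][b] = JtJ[b][a];

    double gmax = 0.0;
    for (int a = 0; a < p; ++a) gmax = std::max(gmax, std::fabs(Jtr[a]));
    if (gmax < 1e-12 * (1.0 + cost)) { converged = true; break; }

    bool stepped = false;
    for (int inner = 0; inner < 25; ++inner) {
      double A[4][4], bb[4], delta[4];
      for (int a = 0; a < p; ++a) {
        bb[a] = -Jtr[a];
        for (int b = 0; b < p; ++b) A[a][b] = JtJ[a][b];
        A[a][a] += lambda * std::max(JtJ[a][a], 1e-12);
      }
      if (!solve_sym(A, bb, p, delta)) { lambda *= 10.0; continue; }
      for (int a = 0; a < p; ++a) trial[a] = th[a] + delta[a];
      if (!resid(trial, rt.data())) { lambda *= 10.0; continue; }
      double cost_t = 0.0;
      for (int i = 0; i < m; ++i) cost_t += rt[i] * rt[i];
      if (cost_t < cost) {
        double dn = 0.0;
        for (int a = 0; a < p; ++a) dn = std::max(dn, std::fabs(delta[a]));
        const double dc = cost - cost_t;
        for (int a = 0; a < p; ++a) th[a] = trial[a];
        std::swap(r, rt);
        cost = cost_t;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        if (dc < tol * (cost + 1e-300) && dn < 1e-9) converged = true;
        break;
      }
      lambda *= 5.0;
    }
    if (!stepped) { converged = true; break; }  // no improving step found
    if (converged) break;
  }
  for (int i = 0; i < p; ++i) theta[i] = th[i];
  *iter_out = it;
  *cost_out = cost;
  return converged;
}

// Shift a curve later in time by s bins (fractional, linear interpolation).
static void shift_curve(const double* m, int n, double s, double* out) {
  for (int i = 0; i < n; ++i) {
    const double x = i - s;
    if (x < 0.0 || x > n - 1) { out[i] = 0.0; continue; }
    const int k = (int)std::floor(x);
    const double f = x - k;
    out[i] = (k + 1 < n) ? (1.0 - f) * m[k] + f * m[k + 1] : m[k];
  }
}

// DTOF fit: Poisson-weighted least squares over (log mua, log musp[, shift])
// with the amplitude profiled analytically. Window indices are 0-based,
// inclusive.
// [[Rcpp::export(name = ".cpp_fit_dtof")]]
List cpp_fit_dtof(NumericVector counts, NumericVector irf, NumericVector t_ps,
                  double bin_ps, double rho, double v, double z0_scale,
                  double zb_factor, int win_lo, int win_hi, double mua0,
                  double musp0, double shift0_ps, bool fit_shift,
                  int max_iter) {
  const int n = counts.size();
  const int m = win_hi - win_lo + 1;
  // restrict the convolution to the IRF's significant support; bins below
  // 1e-10 of the IRF maximum carry no measurable mass
  double irf_max = 0.0;
  for (int j = 0; j < irf.size(); ++j)
    irf_max = std::max(irf_max, irf[j]);
  std::vector<int> irf_idx;
  std::vector<double> irf_w;
  for (int j = 0; j < irf.size(); ++j)
    if (irf[j] > 1e-10 * irf_max) { irf_idx.push_back(j); irf_w.push_back(irf[j]); }
  std::vector<double> w(m), y(m);
  for (int i = 0; i < m; ++i) {
    y[i] = counts[win_lo + i];
    w[i] = 1.0 / std::sqrt(std::max(y[i], 1.0));
  }
  // the model is only needed up to the end of the fit window (plus room
  // for the shift interpolation)
  const int n_eff = std::min(n, win_hi + 60);
  std::vector<double> model(n_eff), conv(n_eff), shifted(n_eff);
  double amp_out = NA_REAL;

  auto resid = [&](const double* th, double* r) -> bool {
    const double mua = std::exp(th[0]);
    const double musp = std::exp(th[1]);
    if (!(mua > 1e-6 && mua < 1.0 && musp > 1e-3 && musp < 50.0)) return false;
    const double z0 = z0_scale / musp;
    const double zb = zb_factor / musp;  // zb = 2*D*(1+Reff)/(1-Reff), D=1/(3musp)
    td_curve(t_ps.begin(), n_eff, mua, musp, rho, v, z0, zb, model.data());
    std::fill(conv.begin(), conv.end(), 0.0);
    for (size_t q = 0; q < irf_idx.size(); ++q) {
      const int j = irf_idx[q];
      const double wq = irf_w[q];
      for (int i = j; i < n_eff; ++i) conv[i] += wq * model[i - j];
    }
    const double* mm = conv.data();
    if (fit_shift) {
      const double s = th[2] / bin_ps;
      if (std::fabs(s) > 50.0) return false;  // shift limited to +-50 bins
      shift_curve(conv.data(), n_eff, s, shifted.data());
      mm = shifted.data();
    }
    // profile the amplitude under the weighted metric
    double num = 0.0, den = 0.0;
    for (int i = 0; i < m; ++i) {
      const double mi = mm[win_lo + i];
      num += w[i] * w[i] * y[i] * mi;
      den += w[i] * w[i] * mi * mi;
    }
    if (!(den > 0.0) || !std::isfinite(num)) return false;
    const double A = num / den;
    if (!(A > 0.0)) return false;
    amp_out = A;
    for (int i = 0; i < m; ++i) r[i] = w[i] * (y[i] - A * mm[win_lo + i]);
    return true;
  };

  const int p = fit_shift ? 3 : 2;
  double theta[4] = {std::log(mua0), std::log(musp0), shift0_ps, 0.0};
  int iter = 0;
  double cost = NA_REAL;
  const bool ok = lm_fit(resid, theta, p, m, max_iter, 1e-10, &iter, &cost);
  // refresh profiled amplitude at the solution
  std::vector<double> rfin(m);
  const bool valid = resid(theta, rfin.data());
  return List::create(
      _["mua"] = std::exp(theta[0]), _["musp"] = std::exp(theta[1]),
      _["shift_ps"] = fit_shift ? theta[2] : 0.0, _["amplitude"] = amp_out,
      _["converged"] = ok && valid, _["iterations"] = iter,
      _["cost"] = cost, _["n_fit"] = m);
}

// g2 fit: least squares over (log BFI, beta) against 1 + beta * g1^2.
// [[Rcpp::export(name = ".cpp_fit_g2")]]
List cpp_fit_g2(NumericVector tau, NumericVector g2, double mua, double musp,
                double k0, double rho, double z0, double zb, double bfi0_mm2s,
                double beta0, int max_iter) {
  const int m = tau.size();
  std::vector<double> g1v(m);

  auto resid = [&](const double* th, double* r) -> bool {
    const double bfi = std::exp(th[0]);
    const double beta = th[1];
    if (!(bfi > 1e-12 && bfi < 1e3) || !(beta > 1e-4 && beta < 1.5))
      return false;
    g1_curve(tau.begin(), m, mua, musp, k0, bfi, rho, z0, zb, g1v.data());
    for (int i = 0; i < m; ++i)
      r[i] = g2[i] - (1.0 + beta * g1v[i] * g1v[i]);
    return true;
  };

  double theta[4] = {std::log(bfi0_mm2s), beta0, 0.0, 0.0};
  int iter = 0;
  double cost = NA_REAL;
  const bool ok = lm_fit(resid, theta, 2, m, max_iter, 1e-14, &iter, &cost);
  return List::create(
      _["bfi_mm2s"] = std::exp(theta[0]), _["beta"] = theta[1],
      _["converged"] = ok, _["iterations"] = iter, _["cost"] = cost,
      _["n_fit"] = m);
}
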