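// Event-driven adaptive RKF45 core for the hydro-osmotic lumen chain.
//
// State within one topology segment: y = (L_1..L_n, N_1..N_n); lumen
// centers are fixed and bridge lengths are recomputed from geometry at
// every evaluation, so total chain length is conserved identically.
// Integration halts at the first threshold crossing (collapse L <= L_min
// or collision ell <= ell_min), localized by bisection; the chain rewrite
// is applied at the R level and integration is restarted.
//
// The bridge fluxes evaluated here mirror the analytic solution of the R
// solve_bridge(); the two implementations are cross-checked in the tests.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct ModelPars {
  double mu, nu, eps, xiv, xis, tau_ratio, Lsys;
  int model;            // 0 = full hydro-osmotic, 1 = hydraulic mean-field
  double Th, Tp;        // hydraulic-chain scales (model 1)
  double ell0bar;       // bridge-length unit for model 1 (resistance scale)
  std::vector<double> x, ja_lum, ja_br;
};

struct Fluxes { double JvL, JvR, JsL, JsR; };

// fluxes of a lumen-lumen bridge, stable in tanh/coth form
static inline Fluxes bridge_fluxes(double cL, double pL, double cR, double pR,
                                   double ell, double xiv, double xis,
                                   double ja) {
  const double h = ell / 2.0;
  const double cm0 = 0.5 * (cL + cR) - ja;
  const double cd  = 0.5 * (cR - cL);
  const double pm  = 0.5 * (pL + pR);
  const double pd  = 0.5 * (pR - pL);
  const double Ts = std::tanh(h / xis);
  const double Tv = std::tanh(h / xiv);
  Fluxes f;
  f.JsL = xis * (cm0 * Ts - cd / Ts);
  f.JsR = xis * (cm0 * Ts + cd / Ts);
  if (std::fabs(xiv - xis) >= 1e-6 * xis) {
    const double r = xis * xis / (xis * xis - xiv * xiv);
    const double pm0 = pm - ja - r * cm0;
    const double pd0 = pd - r * cd;
    const double common = r * xiv * xiv / xis;
    f.JvL = common * (cm0 * Ts - cd / Ts) + xiv * (pm0 * Tv - pd0 / Tv);
    f.JvR = common * (cm0 * Ts + cd / Ts) + xiv * (pm0 * Tv + pd0 / Tv);
  } else {
    // resonant particular solution x*sinh, x*cosh
    const double xi = xis;
    const double AsinH  = -cm0 * Ts / (2.0 * xi);
    const double AhcosH = -cm0 * h / (2.0 * xi * xi);
    const double BcosH  = -cd / Ts / (2.0 * xi);
    const double BhsinH = -cd * h / (2.0 * xi * xi);
    const double pm0 = pm - ja + cm0 * h * Ts / (2.0 * xi);
    const double pd0 = pd + cd * h / (Ts * 2.0 * xi);
    const double dp_odd  = AsinH + AhcosH + pm0 * Tv / xiv;
    const double dp_even = BcosH + BhsinH + pd0 / (Tv * xiv);
    f.JvL = -xiv * xiv * (-dp_odd + dp_even);
    f.JvR =  xiv * xiv * ( dp_odd + dp_even);
  }
  return f;
}

// fluxes at the lumen end of a sealed-wall bridge (method of images:
// symmetric doubled bridge, h = ell)
static inline Fluxes wall_fluxes(double c, double p, double ell,
                                 double xiv, double xis, double ja) {
  const double cm0 = c - ja;
  const double Ts = std::tanh(ell / xis);
  const double Tv = std::tanh(ell / xiv);
  Fluxes f;
  f.JsL = xis * cm0 * Ts;
  f.JsR = f.JsL;
  if (std::fabs(xiv - xis) >= 1e-6 * xis) {
    const double r = xis * xis / (xis * xis - xiv * xiv);
    const double pm0 = p - ja - r * cm0;
    f.JvL = r * xiv * xiv / xis * cm0 * Ts + xiv * pm0 * Tv;
  } else {
    const double xi = xis;
    const double AsinH  = -cm0 * Ts / (2.0 * xi);
    const double AhcosH = -cm0 * ell / (2.0 * xi * xi);
    const double pm0 = p - ja + cm0 * ell * Ts / (2.0 * xi);
    f.JvL = xiv * xiv * (AsinH + AhcosH + pm0 * Tv / xiv);
  }
  f.JvR = f.JvL;
  return f;
}

static inline void get_ells(const std::vector<double>& x, const double* L,
                            int n, double Lsys, double* ell) {
  ell[0] = x[0] - L[0];
  for (int j = 1; j < n; ++j) ell[j] = x[j] - x[j - 1] - L[j] - L[j - 1];
  ell[n] = Lsys - x[n - 1] - L[n - 1];
}

// returns false if the state is unusable (negative sizes/lengths, NaN)
static bool rhs(const ModelPars& P, const double* y, double* dy) {
  const int n = (int)P.x.size();
  const double* L = y;
  const double* N = y + n;
  std::vector<double> ell(n + 1);
  get_ells(P.x, L, n, P.Lsys, ell.data());
  for (int i = 0; i < n; ++i)
    if (!(L[i] > 0.0) || !std::isfinite(L[i])) return false;
  for (int j = 0; j <= n; ++j)
    if (!(ell[j] > 0.0)) return false;

  if (P.model == 1) {
    // hydraulic chain: bridge length (in ell0 units) acts as
    // resistance; sealed ends exchange nothing
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      if (i > 0)
        s += P.ell0bar / (ell[i] * L[i]) * (1.0 / L[i - 1] - 1.0 / L[i]);
      if (i < n - 1)
        s += P.ell0bar / (ell[i + 1] * L[i]) * (1.0 / L[i + 1] - 1.0 / L[i]);
      dy[i] = s / P.Th + (std::isfinite(P.Tp) ? 1.0 / P.Tp : 0.0);
      dy[n + i] = 0.0;
    }
    return true;
  }

  std::vector<double> dC(n), dP(n), Jv(n, 0.0), Js(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!(N[i] > 0.0) || !std::isfinite(N[i])) return false;
    dC[i] = P.mu * N[i] / (L[i] * L[i]) - 1.0;
    dP[i] = P.eps / L[i];
  }
  for (int j = 0; j <= n; ++j) {
    const int il = j - 1, ir = j;
    if (il < 0) {
      Fluxes f = wall_fluxes(dC[0], dP[0], ell[0], P.xiv, P.xis, P.ja_br[0]);
      Jv[0] += f.JvR; Js[0] += f.JsR;
    } else if (ir >= n) {
      Fluxes f = wall_fluxes(dC[n - 1], dP[n - 1], ell[n], P.xiv, P.xis,
                             P.ja_br[n]);
      Jv[n - 1] += f.JvL; Js[n - 1] += f.JsL;
    } else {
      Fluxes f = bridge_fluxes(dC[il], dP[il], dC[ir], dP[ir], ell[j],
                               P.xiv, P.xis, P.ja_br[j]);
      Jv[il] += f.JvL; Js[il] += f.JsL;
      Jv[ir] += f.JvR; Js[ir] += f.JsR;
    }
  }
  for (int i = 0; i < n; ++i) {
    dy[i] = P.mu * P.nu * (dC[i] - P.eps / L[i]) -
      P.mu / (2.0 * L[i]) * Jv[i];
    dy[n + i] = (2.0 * P.nu * L[i] * (-dC[i] + P.ja_lum[i]) - Js[i]) /
      P.tau_ratio;
    if (!std::isfinite(dy[i]) || !std::isfinite(dy[n + i])) return false;
  }
  return true;
}

// classic Fehlberg 4(5) tableau; propagates the 5th-order solution
static bool rkf45_step(const ModelPars& P, const std::vector<double>& y,
                       double h, std::vector<double>& ynew, double& errnorm,
                       double rtol, double atol,
                       std::vector<std::vector<double> >& k,
                       const double* k1) {
  const int m = (int)y.size();
  static const double a21 = 1.0 / 4.0;
  static const double a31 = 3.0 / 32.0, a32 = 9.0 / 32.0;
  static const double a41 = 1932.0 / 2197.0, a42 = -7200.0 / 2197.0,
    a43 = 7296.0 / 2197.0;
  static const double a51 = 439.0 / 216.0, a52 = -8.0, a53 = 3680.0 / 513.0,
    a54 = -845.0 / 4104.0;
  static const double a61 = -8.0 / 27.0, a62 = 2.0, a63 = -3544.0 / 2565.0,
    a64 = 1859.0 / 4104.0, a65 = -11.0 / 40.0;
  static const double b51 = 16.0 / 135.0, b53 = 6656.0 / 12825.0,
    b54 = 28561.0 / 56430.0, b55 = -9.0 / 50.0, b56 = 2.0 / 55.0;
  static const double e1 = 16.0 / 135.0 - 25.0 / 216.0,
    e3 = 6656.0 / 12825.0 - 1408.0 / 2565.0,
    e4 = 28561.0 / 56430.0 - 2197.0 / 4104.0,
    e5 = -9.0 / 50.0 + 1.0 / 5.0, e6 = 2.0 / 55.0;

  std::vector<double> tmp(m);
  for (int i = 0; i < m; ++i) k[0][i] = k1[i];
  for (int i = 0; i < m; ++i) tmp[i] = y[i] + h * a21 * k[0][i];
  if (!rhs(P, tmp.data(), k[1].data())) return false;
  for (int i = 0; i < m; ++i)
    tmp[i] = y[i] + h * (a31 * k[0][i] + a32 * k[1][i]);
  if (!rhs(P, tmp.data(), k[2].data())) return false;
  for (int i = 0; i < m; ++i)
    tmp[i] = y[i] + h * (a41 * k[0][i] + a42 * k[1][i] + a43 * k[2][i]);
  if (!rhs(P, tmp.data(), k[3].data())) return false;
  for (int i = 0; i < m; ++i)
    tmp[i] = y[i] + h * (a51 * k[0][i] + a52 * k[1][i] + a53 * k[2][i] +
                         a54 * k[3][i]);
  if (!rhs(P, tmp.data(), k[4].data())) return false;
  for (int i = 0; i < m; ++i)
    tmp[i] = y[i] + h * (a61 * k[0][i] + a62 * k[1][i] + a63 * k[2][i] +
                         a64 * k[3][i] + a65 * k[4][i]);
  if (!rhs(P, tmp.data(), k[5].data())) return false;

  errnorm = 0.0;
  for (int i = 0; i < m; ++i) {
    ynew[i] = y[i] + h * (b51 * k[0][i] + b53 * k[2][i] + b54 * k[3][i] +
                          b55 * k[4][i] + b56 * k[5][i]);
    const double ei = h * (e1 * k[0][i] + e3 * k[2][i] + e4 * k[3][i] +
                           e5 * k[4][i] + e6 * k[5][i]);
    const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(ynew[i]));
    errnorm += (ei / sc) * (ei / sc);
  }
  errnorm = std::sqrt(errnorm / m);
  return true;
}

static bool crossed(const ModelPars& P, const std::vector<double>& y,
                    double Lmin, double ellmin) {
  const int n = (int)P.x.size();
  for (int i = 0; i < n; ++i) if (y[i] <= Lmin) return true;
  std::vector<double> ell(n + 1);
  get_ells(P.x, y.data(), n, P.Lsys, ell.data());
  for (int j = 0; j <= n; ++j) if (ell[j] <= ellmin) return true;
  return false;
}

// [[Rcpp::export]]
List chain_rhs_cpp(NumericVector L, NumericVector N, NumericVector x,
                   NumericVector ja_lum, NumericVector ja_br,
                   double mu, double nu, double eps, double xiv, double xis,
                   double tau_ratio, double Lsys) {
  const int n = L.size();
  ModelPars P;
  P.mu = mu; P.nu = nu; P.eps = eps; P.xiv = xiv; P.xis = xis;
  P.tau_ratio = tau_ratio; P.Lsys = Lsys; P.model = 0;
  P.x.assign(x.begin(), x.end());
  P.ja_lum.assign(ja_lum.begin(), ja_lum.end());
  P.ja_br.assign(ja_br.begin(), ja_br.end());
  std::vector<double> y(2 * n), dy(2 * n);
  for (int i = 0; i < n; ++i) { y[i] = L[i]; y[n + i] = N[i]; }
  if (!rhs(P, y.data(), dy.data()))
    stop("invalid state in chain_rhs_cpp");
  return List::create(_["dL"] = NumericVector(dy.begin(), dy.begin() + n),
                      _["dN"] = NumericVector(dy.begin() + n, dy.end()));
}

// Integrate one topology segment. Returns at t_end, at the first localized
// threshold crossing, or with an error status.
// status: 0 = reached t_end, 1 = event, 2 = step-size underflow,
//         3 = max steps exceeded, 4 = invalid initial state
// [[Rcpp::export]]
List integrate_segment_cpp(NumericVector L, NumericVector N, NumericVector x,
                           NumericVector ja_lum, NumericVector ja_br,
                           List pars, double t0, double t_end,
                           double rtol, double atol, double h0,
                           double Lmin, double ellmin,
                           NumericVector snap_times, bool record_all,
                           double max_steps) {
  const int n = L.size();
  ModelPars P;
  P.mu = as<double>(pars["mu"]); P.nu = as<double>(pars["nu"]);
  P.eps = as<double>(pars["eps"]); P.xiv = as<double>(pars["xiv"]);
  P.xis = as<double>(pars["xis"]);
  P.tau_ratio = as<double>(pars["tau_ratio"]);
  P.Lsys = as<double>(pars["Lsys"]);
  P.model = as<int>(pars["model"]);
  P.Th = as<double>(pars["Th"]); P.Tp = as<double>(pars["Tp"]);
  P.ell0bar = as<double>(pars["ell0bar"]);
  P.x.assign(x.begin(), x.end());
  P.ja_lum.assign(ja_lum.begin(), ja_lum.end());
  P.ja_br.assign(ja_br.begin(), ja_br.end());

  const int m = 2 * n;
  std::vector<double> y(m), ynew(m), k1(m);
  for (int i = 0; i < n; ++i) { y[i] = L[i]; y[n + i] = N[i]; }
  std::vector<std::vector<double> > k(6, std::vector<double>(m));

  double t = t0, h = h0;
  long nacc = 0, nrej = 0;
  int status = 0;
  int isnap = 0;
  const int nsnap = snap_times.size();
  std::vector<double> snap_t; std::vector<int> snap_idx;
  std::vector<double> snap_state;
  std::vector<double> rec_t; std::vector<double> rec_state;

  if (!rhs(P, y.data(), k1.data()))
    return List::create(_["status"] = 4, _["t"] = t,
                        _["L"] = NumericVector(y.begin(), y.begin() + n),
                        _["N"] = NumericVector(y.begin() + n, y.end()));
  if (record_all) {
    rec_t.push_back(t);
    rec_state.insert(rec_state.end(), y.begin(), y.end());
  }

  double errnorm;
  while (t < t_end) {
    if (nacc + nrej > (long)max_steps) { status = 3; break; }
    if (h > t_end - t) h = t_end - t;
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) { status = 2; break; }
    bool ok = rkf45_step(P, y, h, ynew, errnorm, rtol, atol, k, k1.data());
    if (!ok || errnorm > 1.0) {
      ++nrej;
      h *= ok ? std::max(0.1, 0.9 * std::pow(errnorm, -0.25)) : 0.5;
      continue;
    }
    // accepted; check thresholds on the new state
    if (crossed(P, ynew, Lmin, ellmin)) {
      // bisect the crossing time with single RKF45 steps from y
      double lo = 0.0, hi = 1.0;
      std::vector<double> ytrial(m), yev(ynew);
      for (int it = 0; it < 80; ++it) {
        if ((hi - lo) * h <= 1e-6 * std::max(1e-12, t + hi * h)) break;
        const double mid = 0.5 * (lo + hi);
        double e2;
        if (!rkf45_step(P, y, mid * h, ytrial, e2, rtol, atol, k, k1.data()))
          { hi = mid; continue; }
        if (crossed(P, ytrial, Lmin, ellmin)) { hi = mid; yev = ytrial; }
        else lo = mid;
      }
      t += hi * h;
      y = yev;
      status = 1;
      break;
    }
    t += h;
    y = ynew;
    ++nacc;
    if (!rhs(P, y.data(), k1.data())) { status = 2; break; } // FSAL-style reuse
    while (isnap < nsnap && t >= snap_times[isnap]) {
      snap_t.push_back(t); snap_idx.push_back(isnap);
      snap_state.insert(snap_state.end(), y.begin(), y.end());
      ++isnap;
    }
    if (record_all) {
      rec_t.push_back(t);
      rec_state.insert(rec_state.end(), y.begin(), y.end());
    }
    h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(
      std::max(errnorm, 1e-16), -0.2)));
  }

  // event identification at the returned state
  int ev_kind = 0, ev_index = -1;
  if (status == 1) {
    for (int i = 0; i < n; ++i)
      if (y[i] <= Lmin) { ev_kind = 1; ev_index = i; break; }
    if (ev_kind == 0) {
      std::vector<double> ell(n + 1);
      get_ells(P.x, y.data(), n, P.Lsys, ell.data());
      for (int j = 0; j <= n; ++j)
        if (ell[j] <= ellmin) { ev_kind = 2; ev_index = j; break; }
    }
  }

  NumericMatrix snaps(snap_t.size(), m);
  for (size_t r = 0; r < snap_t.size(); ++r)
    for (int cidx = 0; cidx < m; ++cidx)
      snaps(r, cidx) = snap_state[r * m + cidx];
  NumericMatrix recs(record_all ? rec_t.size() : 0, record_all ? m : 0);
  if (record_all)
    for (size_t r = 0; r < rec_t.size(); ++r)
      for (int cidx = 0; cidx < m; ++cidx)
        recs(r, cidx) = rec_state[r * m + cidx];

  return List::create(
    _["status"] = status, _["t"] = t, _["h"] = h,
    _["L"] = NumericVector(y.begin(), y.begin() + n),
    _["N"] = NumericVector(y.begin() + n, y.end()),
    _["ev_kind"] = ev_kind, _["ev_index"] = ev_index + 1,
    _["n_accepted"] = (double)nacc, _["n_rejected"] = (double)nrej,
    _["snap_t"] = wrap(snap_t), _["snap_idx"] = wrap(snap_idx),
    _["snaps"] = snaps, _["rec_t"] = wrap(rec_t), _["recs"] = recs);
}
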