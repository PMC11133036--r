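// First-passage-time density of the Wiener diffusion model between two
// absorbing boundaries, with inter-trial variability in drift (normal),
// starting point (uniform) and non-decision time (uniform).
//
// The within-trial diffusion coefficient is fixed at s = 1; all parameters
// are expressed on that scale.
//
// Density kernel f(t* | 0, 1, w) of the zero-drift, unit-boundary process
// at scaled time t* = t / a^2 is evaluated by whichever of the two series
// representations (large-time / small-time) needs fewer terms for a given
// absolute tolerance.  Truncation counts come from explicit tail bounds:
// a geometric-ratio envelope for the large-time series and a Gaussian-tail
// integral envelope for the small-time series.
//
// The gradient of the log-density is the exact derivative of the same
// series-plus-quadrature computation (manual reverse-mode differentiation
// of the computational graph), so it is consistent with the returned
// log-density values to the accuracy of the series truncation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>

using namespace Rcpp;

static const double PI_ = 3.141592653589793238462643383280;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

// count of series evaluations clamped at zero (kernel gone negative by
// truncation error near the support boundary)
static long clamp_counter = 0;

// ---------------------------------------------------------------------------
// Gauss-Legendre nodes/weights on [-1, 1], cached per order.
// ---------------------------------------------------------------------------

struct GLRule { std::vector<double> x, w; };

static GLRule gl_compute(int n) {
  GLRule r;
  r.x.resize(n); r.w.resize(n);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(PI_ * (i + 0.75) / (n + 0.5));
    double z1 = 2.0, pp = 0.0;
    while (std::fabs(z - z1) > 1e-15) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z;
      z = z1 - p1 / pp;
    }
    r.x[i] = -z;
    r.x[n - 1 - i] = z;
    r.w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    r.w[n - 1 - i] = r.w[i];
  }
  return r;
}

static const GLRule& gl_rule(int n) {
  static std::map<int, GLRule> cache;
  auto it = cache.find(n);
  if (it == cache.end()) it = cache.emplace(n, gl_compute(n)).first;
  return it->second;
}

// ---------------------------------------------------------------------------
// Series truncation bounds (tests in log space: no exp in the hot loop)
// ---------------------------------------------------------------------------

// Smallest K so that the large-time tail
//   sum_{k>K} k pi exp(-k^2 pi^2 t*/2) |sin(k pi w)|
// is below tol: terms decay super-geometrically once k >= 1/(pi sqrt(t*)),
// and the tail is bounded by b_{K+1} / (1 - r) with r an upper bound on
// the term ratio.
static int k_large(double tstar, double tol) {
  const double c = PI_ * PI_ * tstar / 2.0;
  const double ltol = std::log(tol);
  int K = std::max(1, (int)std::ceil(1.0 / (PI_ * std::sqrt(tstar))));
  for (; K < 100000; ++K) {
    double lb = std::log((K + 1.0) * PI_) - c * (K + 1.0) * (K + 1.0);
    double lr = -c * (2.0 * K + 3.0) + std::log((K + 2.0) / (K + 1.0));
    if (lr < -0.6931472) {            // r < 1/2  =>  1/(1-r) < 2
      if (lb + 0.6931472 <= ltol) break;
    } else if (lr < 0.0) {
      if (lb - std::log1p(-std::exp(lr)) <= ltol) break;
    }
  }
  return K;
}

// Symmetric truncation k in [-K, K] of the small-time series so the
// absolute tail is below tol.  For q >= sqrt(t*), g(q) = q exp(-q^2/2t*)
// decreases, and the lattice sum with spacing 2 obeys
//   sum_{j>=0} g(q0 + 2j) <= g(q0) + (t*/2) exp(-q0^2 / 2 t*).
static int k_small(double tstar, double w, double tol) {
  const double lpref = -0.5 * std::log(2.0 * PI_ * tstar * tstar * tstar);
  const double sq = std::sqrt(tstar);
  const double ltol = std::log(tol);
  int K;
  for (K = 0; K < 100000; ++K) {
    double qp = 2.0 * (K + 1.0) + w;   // first omitted term, positive side
    double qm = 2.0 * (K + 1.0) - w;   // first omitted term, negative side
    if (qm < sq) continue;             // not yet in decreasing regime
    // tail <= 2 * pref * (qp + t*/2) * exp(-qm^2 / 2 t*)
    double lt = 0.6931472 + lpref + std::log(qp + tstar / 2.0) -
      qm * qm / (2.0 * tstar);
    if (lt <= ltol) break;
  }
  return K;
}

static double f_large_K(double tstar, double w, int K) {
  double s = 0.0;
  const double c = PI_ * PI_ * tstar / 2.0;
  for (int k = 1; k <= K; ++k)
    s += k * PI_ * std::exp(-c * (double)k * k) * std::sin(k * PI_ * w);
  return s;
}

static double f_small_K(double tstar, double w, int K) {
  const double pref = 1.0 / std::sqrt(2.0 * PI_ * tstar * tstar * tstar);
  double s = 0.0;
  for (int k = -K; k <= K; ++k) {
    double q = w + 2.0 * k;
    s += q * std::exp(-q * q / (2.0 * tstar));
  }
  return pref * s;
}

// kernel value only, automatic expansion choice; clamped at 0
static double f_kernel(double tstar, double w, double tol) {
  int Kl = k_large(tstar, tol);
  int Ks = k_small(tstar, w, tol);
  double v;
  if (2 * Ks + 1 < Kl) v = f_small_K(tstar, w, Ks);
  else                 v = f_large_K(tstar, w, Kl);
  if (v < 0.0) { clamp_counter++; v = 0.0; }
  return v;
}

// kernel with partial derivatives w.r.t. t* and w (same truncation rule,
// two extra terms of margin for the polynomial factors of the derivatives)
struct FVal { double f, ft, fw; };

static FVal f_all(double tstar, double w, double tol) {
  FVal r = {0.0, 0.0, 0.0};
  int Kl = k_large(tstar, tol);
  int Ks = k_small(tstar, w, tol);
  if (2 * Ks + 1 < Kl) {
    int K = Ks + 2;
    const double pref = 1.0 / std::sqrt(2.0 * PI_ * tstar * tstar * tstar);
    for (int k = -K; k <= K; ++k) {
      double q = w + 2.0 * k;
      double e = std::exp(-q * q / (2.0 * tstar));
      r.f  += q * e;
      r.ft += q * e * (q * q / (2.0 * tstar * tstar) - 1.5 / tstar);
      r.fw += (1.0 - q * q / tstar) * e;
    }
    r.f *= pref; r.ft *= pref; r.fw *= pref;
  } else {
    int K = Kl + 2;
    const double c = PI_ * PI_ * tstar / 2.0;
    for (int k = 1; k <= K; ++k) {
      double kp = k * PI_;
      double e = std::exp(-c * (double)k * k);
      double si = std::sin(kp * w), co = std::cos(kp * w);
      r.f  += kp * e * si;
      r.ft += -kp * e * si * (kp * kp / 2.0);
      r.fw += kp * kp * e * co;
    }
  }
  if (r.f < 0.0) { clamp_counter++; r.f = 0.0; }
  return r;
}

// ---------------------------------------------------------------------------
// Four-parameter density and the drift-variability factor
// ---------------------------------------------------------------------------

// log p3(t | a, v, w) = -2 log a - a v w - v^2 t / 2 + log f(t/a^2 | 0,1,w)
static double log_p3(double t, double a, double v, double w, double tol) {
  if (t <= 0.0) return NEG_INF;
  double f = f_kernel(t / (a * a), w, tol);
  if (f <= 0.0) return NEG_INF;
  return -2.0 * std::log(a) - a * v * w - v * v * t / 2.0 + std::log(f);
}

// log M(t; a, v, omega, sv): multiplying p3(t|a,v,omega) by M gives the
// normal mixture of p3 over trial drift nu ~ N(v, sv^2) in closed form.
static double log_M(double t, double a, double v, double omega, double sv) {
  if (sv <= 0.0) return 0.0;
  double s2t = sv * sv * t;
  double one = 1.0 + s2t;
  double ao = a * omega;
  return -0.5 * std::log(one) + a * v * omega + v * v * t / 2.0 +
    (sv * sv * ao * ao - 2.0 * a * v * omega - v * v * t) / (2.0 * one);
}

// Combined integrand exponent g = log(M * p3) at trial level.  The
// +-(a v omega + v^2 t / 2) terms cancel between M and p3, leaving
//   g = -2 log a + log f(t/a^2, omega) - log(O)/2 + Q/(2 O)
// with S = sv^2, O = 1 + S t, Q = S a^2 omega^2 - 2 a v omega - v^2 t.
struct GVal { double g, da, dv, dom, dt, dsv; };

static GVal g_from_f(double t, double a, double v, double omega, double sv,
                     const FVal& F) {
  GVal r;
  double S = sv * sv, O = 1.0 + S * t;
  double ao = a * omega;
  double Q = S * ao * ao - 2.0 * a * v * omega - v * v * t;
  double ts = t / (a * a);
  if (F.f <= 0.0) { r.g = NEG_INF; r.da = r.dv = r.dom = r.dt = r.dsv = 0.0; return r; }
  double lf = std::log(F.f);
  double rt = F.ft / F.f, rw = F.fw / F.f;
  r.g = -2.0 * std::log(a) + lf - 0.5 * std::log(O) + Q / (2.0 * O);
  r.da = -2.0 / a + rt * (-2.0 * t / (a * a * a)) +
    (2.0 * S * a * omega * omega - 2.0 * v * omega) / (2.0 * O);
  r.dv = -(ao + v * t) / O;
  r.dom = rw + (S * a * ao - a * v) / O;
  r.dt = rt / (a * a) - S / (2.0 * O) + (-v * v * O - Q * S) / (2.0 * O * O);
  // d/dS, then chain to sv
  double dS = -t / (2.0 * O) + (ao * ao * O - Q * t) / (2.0 * O * O);
  r.dsv = 2.0 * sv * dS;
  return r;
}

// ---------------------------------------------------------------------------
// Seven-parameter log-density: quadrature over omega and tau0
// ---------------------------------------------------------------------------

// single evaluation at fixed quadrature order n (value only)
static double w7_lpdf_order(double y, double a, double v, double w,
                            double t0, double sv, double sw, double st0,
                            double tol, int n) {
  if (y <= t0) return NEG_INF;

  // tau0 range [t0, min(y, t0 + st0)]: integrand is zero for tau0 >= y but
  // the 1/st0 normalizer keeps the full range's measure (mass below t0+st0
  // that exceeds y is correctly lost)
  int nt = 1;
  std::vector<double> tau0s(1, t0), lw_t(1, 0.0);
  if (st0 > 0.0) {
    double hi = std::min(y, t0 + st0);
    double width = hi - t0;
    if (width <= 0.0) return NEG_INF;
    // clipped upper limit (y < t0 + st0): the integrand develops a sharp
    // vanishing layer towards tau0 -> y; double the node count there
    int nt_use = (y < t0 + st0) ? 2 * n : n;
    const GLRule& g = gl_rule(nt_use);
    nt = nt_use;
    tau0s.assign(nt, 0.0); lw_t.assign(nt, 0.0);
    double mid = (t0 + hi) / 2.0, half = width / 2.0;
    for (int i = 0; i < nt; ++i) {
      tau0s[i] = mid + half * g.x[i];
      lw_t[i] = std::log(g.w[i] * half) - std::log(st0);
    }
  }

  int nw = 1;
  std::vector<double> omegas(1, w), lw_o(1, 0.0);
  if (sw > 0.0) {
    const GLRule& g = gl_rule(n);
    int nw_use = n;
    nw = nw_use;
    omegas.assign(nw, 0.0); lw_o.assign(nw, 0.0);
    double half = sw / 2.0;
    for (int j = 0; j < nw; ++j) {
      omegas[j] = w + half * g.x[j];
      lw_o[j] = std::log(g.w[j] / 2.0);   // (sw/2) jacobian cancels 1/sw
    }
  }

  double mx = NEG_INF;
  std::vector<double> terms(nt * nw);
  for (int i = 0; i < nt; ++i) {
    double t = y - tau0s[i];
    for (int j = 0; j < nw; ++j) {
      double L = lw_t[i] + lw_o[j] +
        log_M(t, a, v, omegas[j], sv) + log_p3(t, a, v, omegas[j], tol);
      terms[i * nw + j] = L;
      if (L > mx) mx = L;
    }
  }
  if (mx == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (double L : terms) s += std::exp(L - mx);
  return mx + std::log(s);
}

// full evaluation with optional order-doubling refinement; the response
// mirroring (-v, 1 - w for the lower boundary) happens here
static double w7_lpdf_one(double y, int resp, double a, double v, double w,
                          double t0, double sv, double sw, double st0,
                          double tol, int n0, bool refine) {
  // the series kernel models the boundary opposite to w's reference point;
  // with w measured from the lower boundary, upper responses use (-v, 1-w)
  if (resp != 0) { v = -v; w = 1.0 - w; }
  if (sw <= 0.0 && st0 <= 0.0) {
    if (y <= t0) return NEG_INF;
    double t = y - t0;
    return log_M(t, a, v, w, sv) + log_p3(t, a, v, w, tol);
  }
  double L1 = w7_lpdf_order(y, a, v, w, t0, sv, sw, st0, tol, n0);
  if (!refine) return L1;
  int n = n0;
  for (int pass = 0; pass < 2; ++pass) {
    n *= 2;
    double L2 = w7_lpdf_order(y, a, v, w, t0, sv, sw, st0, tol, n);
    double d1 = (L1 == NEG_INF) ? 0.0 : std::exp(L1);
    double d2 = (L2 == NEG_INF) ? 0.0 : std::exp(L2);
    if (std::fabs(d1 - d2) < tol) return L2;
    L1 = L2;
  }
  return L1;
}

// ---------------------------------------------------------------------------
// Fused log-density + exact gradient of the quadrature computation.
// Gradient is w.r.t. (a, v, w, t0, sv, sw, st0) of the *upper-boundary*
// parameterization; mirroring for resp = 0 flips the signs of the v and w
// components (sw is symmetric under the mirror).
// ---------------------------------------------------------------------------

struct LGrad { double L; double g[7]; bool ok; };

static LGrad w7_lgrad_one(double y, int resp, double a, double v, double w,
                          double t0, double sv, double sw, double st0,
                          double tol, int n) {
  LGrad out; out.L = NEG_INF; out.ok = false;
  for (int k = 0; k < 7; ++k) out.g[k] = 0.0;
  bool mirror = (resp != 0);   // upper responses use (-v, 1-w), see above
  if (mirror) { v = -v; w = 1.0 - w; }
  if (y <= t0) return out;

  // tau0 nodes; node position/weight sensitivities to t0 and st0 depend on
  // whether the upper limit is clipped at y
  int nt = 1;
  std::vector<double> tau0s(1, t0), lw_t(1, 0.0);
  std::vector<double> dtau_dt0(1, 1.0), dtau_dst0(1, 0.0);
  double dlwt_dt0 = 0.0, dlwt_dst0 = 0.0;   // same for all i within a branch
  if (st0 > 0.0) {
    double hi = t0 + st0;
    bool clipped = (y < hi);
    if (clipped) hi = y;
    double width = hi - t0;
    if (width <= 0.0) return out;
    int nt_use = clipped ? 2 * n : n;   // sharp layer: double node count
    const GLRule& g = gl_rule(nt_use);
    nt = nt_use;
    tau0s.assign(nt, 0.0); lw_t.assign(nt, 0.0);
    dtau_dt0.assign(nt, 0.0); dtau_dst0.assign(nt, 0.0);
    double mid = (t0 + hi) / 2.0, half = width / 2.0;
    for (int i = 0; i < nt; ++i) {
      tau0s[i] = mid + half * g.x[i];
      lw_t[i] = std::log(g.w[i] * half) - std::log(st0);
      if (clipped) {
        dtau_dt0[i] = (1.0 - g.x[i]) / 2.0;   // mid' = 1/2, half' = -1/2
        dtau_dst0[i] = 0.0;
      } else {
        dtau_dt0[i] = 1.0;
        dtau_dst0[i] = (1.0 + g.x[i]) / 2.0;  // mid' = 1/2, half' = 1/2
      }
    }
    // log weight = log(gw * half) - log(st0)
    dlwt_dt0  = clipped ? (-0.5 / (y - t0) * 1.0) * 1.0 : 0.0;  // d log half/dt0 = -1/(2 half) -> with half=(y-t0)/2: -1/(y-t0)
    if (clipped) dlwt_dt0 = -1.0 / (y - t0);
    dlwt_dst0 = clipped ? (-1.0 / st0) : 0.0;
    // unclipped: half = st0/2 -> d log(half)/dst0 = 1/st0, minus d log(st0) = -1/st0 -> 0
  }

  int nw = 1;
  std::vector<double> omegas(1, w), lw_o(1, 0.0);
  std::vector<double> dom_dsw(1, 0.0);
  if (sw > 0.0) {
    const GLRule& g = gl_rule(n);
    int nw_use = n;
    nw = nw_use;
    omegas.assign(nw, 0.0); lw_o.assign(nw, 0.0); dom_dsw.assign(nw, 0.0);
    double half = sw / 2.0;
    for (int j = 0; j < nw; ++j) {
      omegas[j] = w + half * g.x[j];
      lw_o[j] = std::log(g.w[j] / 2.0);
      dom_dsw[j] = g.x[j] / 2.0;
    }
  }

  int ntot = nt * nw;
  std::vector<double> L(ntot);
  std::vector<GVal> gv(ntot);
  double mx = NEG_INF;
  // per tau0 node, the series-truncation decision and (for the large-time
  // branch) the exponential term table are shared across all omega nodes
  double wmax = omegas[0];
  for (int j = 1; j < nw; ++j) if (omegas[j] > wmax) wmax = omegas[j];
  std::vector<double> ek, kpk;
  for (int i = 0; i < nt; ++i) {
    double t = y - tau0s[i];
    double ts = t / (a * a);
    int Kl = k_large(ts, tol);
    int Ks = k_small(ts, wmax, tol);
    bool use_small = (2 * Ks + 1 < Kl);
    int K = (use_small ? Ks : Kl) + 2;
    if (!use_small) {
      const double c = PI_ * PI_ * ts / 2.0;
      ek.resize(K + 1); kpk.resize(K + 1);
      for (int k = 1; k <= K; ++k) {
        kpk[k] = k * PI_;
        ek[k] = std::exp(-c * (double)k * k);
      }
    }
    for (int j = 0; j < nw; ++j) {
      double om = omegas[j];
      FVal F = {0.0, 0.0, 0.0};
      if (use_small) {
        const double pref = 1.0 / std::sqrt(2.0 * PI_ * ts * ts * ts);
        for (int k = -K; k <= K; ++k) {
          double q = om + 2.0 * k;
          double e = std::exp(-q * q / (2.0 * ts));
          F.f  += q * e;
          F.ft += q * e * (q * q / (2.0 * ts * ts) - 1.5 / ts);
          F.fw += (1.0 - q * q / ts) * e;
        }
        F.f *= pref; F.ft *= pref; F.fw *= pref;
      } else {
        for (int k = 1; k <= K; ++k) {
          double si = std::sin(kpk[k] * om), co = std::cos(kpk[k] * om);
          double b = kpk[k] * ek[k];
          F.f  += b * si;
          F.ft += -b * si * (kpk[k] * kpk[k] / 2.0);
          F.fw += kpk[k] * kpk[k] * ek[k] * co;
        }
      }
      if (F.f < 0.0) { clamp_counter++; F.f = 0.0; }
      GVal gg = g_from_f(t, a, v, om, sv, F);
      int idx = i * nw + j;
      gv[idx] = gg;
      L[idx] = (gg.g == NEG_INF) ? NEG_INF : lw_t[i] + lw_o[j] + gg.g;
      if (L[idx] > mx) mx = L[idx];
    }
  }
  if (mx == NEG_INF) return out;

  double den = 0.0, num[7] = {0, 0, 0, 0, 0, 0, 0};
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < nw; ++j) {
      int idx = i * nw + j;
      if (L[idx] == NEG_INF) continue;
      double wgt = std::exp(L[idx] - mx);
      den += wgt;
      const GVal& gg = gv[idx];
      double dtau0_contrib = -gg.dt;   // t = y - tau0
      num[0] += wgt * gg.da;                                       // a
      num[1] += wgt * gg.dv;                                       // v
      num[2] += wgt * gg.dom;                                      // w
      num[3] += wgt * (dtau0_contrib * dtau_dt0[i] + dlwt_dt0);    // t0
      num[4] += wgt * gg.dsv;                                      // sv
      num[5] += wgt * gg.dom * dom_dsw[j];                         // sw
      num[6] += wgt * (dtau0_contrib * dtau_dst0[i] + dlwt_dst0);  // st0
    }
  }
  out.L = mx + std::log(den);
  for (int k = 0; k < 7; ++k) out.g[k] = num[k] / den;
  if (mirror) { out.g[1] = -out.g[1]; out.g[2] = -out.g[2]; }
  out.ok = true;
  return out;
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".fl_cpp")]]
double fl_cpp(double tstar, double w, double tol) {
  return f_large_K(tstar, w, k_large(tstar, tol));
}

// [[Rcpp::export(name = ".fs_cpp")]]
double fs_cpp(double tstar, double w, double tol) {
  return f_small_K(tstar, w, k_small(tstar, w, tol));
}

// [[Rcpp::export(name = ".fl_terms_cpp")]]
double fl_terms_cpp(double tstar, double w, int K) { return f_large_K(tstar, w, K); }

// [[Rcpp::export(name = ".fs_terms_cpp")]]
double fs_terms_cpp(double tstar, double w, int K) { return f_small_K(tstar, w, K); }

// [[Rcpp::export(name = ".choose_expansion_cpp")]]
List choose_expansion_cpp(double tstar, double w, double tol) {
  int Kl = k_large(tstar, tol);
  int Ks = k_small(tstar, w, tol);
  bool small = (2 * Ks + 1 < Kl);
  return List::create(_["method"] = small ? "small" : "large",
                      _["terms"] = small ? 2 * Ks + 1 : Kl,
                      _["K_small"] = Ks, _["K_large"] = Kl);
}

// [[Rcpp::export(name = ".logp3_cpp")]]
NumericVector logp3_cpp(NumericVector t, double a, double v, double w, double tol) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = log_p3(t[i], a, v, w, tol);
  return out;
}

// p3 with per-element (v, w): used by Monte-Carlo mixture oracles
// [[Rcpp::export(name = ".logp3_mix_cpp")]]
NumericVector logp3_mix_cpp(NumericVector t, double a, NumericVector v,
                            NumericVector w, double tol) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = log_p3(t[i], a, v[i], w[i], tol);
  return out;
}

// [[Rcpp::export(name = ".logM_cpp")]]
double logM_cpp(double t, double a, double v, double omega, double sv) {
  return log_M(t, a, v, omega, sv);
}

// [[Rcpp::export(name = ".w7_lpdf_cpp")]]
NumericVector w7_lpdf_cpp(NumericVector y, IntegerVector resp,
                          double a, double v, double w, double t0,
                          double sv, double sw, double st0,
                          double tol, int n0, bool refine) {
  int n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = w7_lpdf_one(y[i], resp[i], a, v, w, t0, sv, sw, st0, tol, n0, refine);
  return out;
}

// total log-likelihood of a dataset; params is n_cond x 7 matrix with rows
// (a, v, w, t0, sv, sw, st0) per condition, cond is 1-based condition index
// [[Rcpp::export(name = ".w7_loglik_cpp")]]
double w7_loglik_cpp(NumericVector y, IntegerVector resp, IntegerVector cond,
                     NumericMatrix params, double tol, int n0, bool refine) {
  int n = y.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    int c = cond[i] - 1;
    double L = w7_lpdf_one(y[i], resp[i], params(c, 0), params(c, 1),
                           params(c, 2), params(c, 3), params(c, 4),
                           params(c, 5), params(c, 6), tol, n0, refine);
    if (L == NEG_INF) return NEG_INF;
    s += L;
  }
  return s;
}

// single-trial gradient (exact derivative of the fixed-order computation)
// [[Rcpp::export(name = ".w7_grad_cpp")]]
NumericVector w7_grad_cpp(double y, int resp, double a, double v, double w,
                          double t0, double sv, double sw, double st0,
                          double tol, int n) {
  LGrad r = w7_lgrad_one(y, resp, a, v, w, t0, sv, sw, st0, tol, n);
  NumericVector out(8);
  out[0] = r.L;
  for (int k = 0; k < 7; ++k) out[k + 1] = r.g[k];
  out.attr("ok") = r.ok;
  return out;
}

// loglik and per-condition summed gradient: returns list(loglik, grad)
// with grad an n_cond x 7 matrix; loglik = -Inf (ok = FALSE) if any trial
// has zero density
// [[Rcpp::export(name = ".w7_loglik_grad_cpp")]]
List w7_loglik_grad_cpp(NumericVector y, IntegerVector resp,
                        IntegerVector cond, NumericMatrix params,
                        double tol, int n0) {
  int n = y.size(), ncond = params.nrow();
  NumericMatrix grad(ncond, 7);
  double s = 0.0;
  bool ok = true;
  for (int i = 0; i < n && ok; ++i) {
    int c = cond[i] - 1;
    LGrad r = w7_lgrad_one(y[i], resp[i], params(c, 0), params(c, 1),
                           params(c, 2), params(c, 3), params(c, 4),
                           params(c, 5), params(c, 6), tol, n0);
    if (!r.ok) { ok = false; s = NEG_INF; break; }
    s += r.L;
    for (int k = 0; k < 7; ++k) grad(c, k) += r.g[k];
  }
  return List::create(_["loglik"] = s, _["grad"] = grad, _["ok"] = ok);
}

// [[Rcpp::export(name = ".clamp_count_cpp")]]
double clamp_count_cpp() { return (double)clamp_counter; }

// ---------------------------------------------------------------------------
// First-passage sampler: Euler-Maruyama with Brownian-bridge boundary-
// crossing correction.  At each step the probability that the bridge
// between consecutive interior points crossed either boundary is evaluated
// exactly, removing the leading O(sqrt(dt)) discretization bias of naive
// Euler.  Crossing times get a uniform within-step jitter (removes the
// +dt/2 bias of reporting step ends and the dt-grid ties).
// Uses R's RNG so set.seed() governs reproducibility.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sim_fpt_cpp")]]
List sim_fpt_cpp(NumericVector a, NumericVector nu, NumericVector omega,
                 double dt) {
  int n = a.size();
  NumericVector t_out(n);
  IntegerVector r_out(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double A = a[i], x = omega[i] * A;
    double drift_dt = nu[i] * dt;
    double time = 0.0;
    int resp = -1;
    long maxsteps = (long)(2000.0 / dt);   // 2000 s guard
    for (long s = 0; s < maxsteps; ++s) {
      double xn = x + drift_dt + sdt * norm_rand();
      time += dt;
      if (xn >= A) { resp = 1; break; }
      if (xn <= 0.0) { resp = 0; break; }
      double pu = std::exp(-2.0 * (A - x) * (A - xn) / dt);
      double pl = std::exp(-2.0 * x * xn / dt);
      double u = unif_rand();
      if (u < pu) { resp = 1; break; }
      if (u < pu + pl) { resp = 0; break; }
      x = xn;
    }
    if (resp < 0) { resp = (x > A / 2.0) ? 1 : 0; }  // guard, never expected
    t_out[i] = time - dt * unif_rand();
    r_out[i] = resp;
  }
  return List::create(_["t"] = t_out, _["response"] = r_out);
}
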