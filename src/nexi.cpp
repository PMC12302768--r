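// Core numerics for the two-compartment anisotropic Karger model:
//  - analytic narrow-pulse kernel (NEXI) with parameter gradients
//  - finite-pulse kernel (SMEX) as a matrix-exponential product over the
//    trapezoidal PGSE waveform, with step-doubling to a fixed tolerance
//  - exact Rice-distribution mean (scaled-Bessel closed form)
//  - batched forward model for rotational invariants S0/S2 used by both
//    solvers (optionally with the Rician-mean correction on S0)
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinhc(double h) {
  // sinh(h)/h, stable at h -> 0
  if (h < 1e-4) {
    double h2 = h * h;
    return 1.0 + h2 / 6.0 + h2 * h2 / 120.0;
  }
  return std::sinh(h) / h;
}

// Narrow-pulse Karger kernel K(b, eps, t) and (optionally) its gradient
// with respect to (f, Dn, De, rn).  Uses the eigenvalue form
//   K = f1' exp(-a1) + f2' exp(-a2),
//   a_{1,2} = abar +/- h,  abar = (x + y + u + v)/2,
//   h = sqrt((x - y + u - v)^2 + 4 u v)/2,
// with x = b Dn eps^2, y = b De, u = t rn, v = t re, re = rn f/(1-f),
// and amplitudes fixed by f1' + f2' = 1 and f1' a1 + f2' a2 = b * Dbar,
// Dbar = f Dn eps^2 + (1 - f) De.  The discriminant carries t^2 rn re
// (dimensionally consistent form).
static double karger_K(double b, double t, double eps2,
                       double f, double Dn, double De, double rn,
                       double *grad) {
  double omf = 1.0 - f;
  if (omf < 1e-12) omf = 1e-12;
  double re = rn * f / omf;

  double x = b * Dn * eps2;
  double y = b * De;
  double u = t * rn;
  double v = t * re;

  double abar = 0.5 * (x + y + u + v);
  double w = x - y + u - v;
  double h = 0.5 * std::sqrt(w * w + 4.0 * u * v);
  double m = f * x + omf * y;  // = b * Dbar

  double K;
  double c = 0.0, g = 0.0, eab = 0.0;
  double A1 = 0.0, A2 = 0.0, e1 = 0.0, e2 = 0.0;
  bool small_h = (h < 1e-5);
  if (small_h) {
    c = std::cosh(h);
    g = sinhc(h);
    eab = std::exp(-abar);
    K = eab * (c + (abar - m) * g);
  } else {
    // two-exponential form; both exponents are >= 0 so no overflow
    double r = (abar - m) / h;
    A2 = 0.5 * (1.0 + r);  // weight of exp(-a2), a2 = abar - h (slow decay)
    A1 = 0.5 * (1.0 - r);
    e2 = std::exp(-(abar - h));
    e1 = std::exp(-(abar + h));
    K = A2 * e2 + A1 * e1;
  }

  if (grad) {
    // partials of (x, y, u, v, m) w.r.t. (f, Dn, De, rn)
    double dx[4] = {0.0, b * eps2, 0.0, 0.0};
    double dy[4] = {0.0, 0.0, b, 0.0};
    double du[4] = {0.0, 0.0, 0.0, t};
    double dv[4] = {t * rn / (omf * omf), 0.0, 0.0, t * f / omf};
    double dm[4] = {x - y, f * b * eps2, omf * b, 0.0};

    double hs = (h > 1e-12) ? h : 1e-12;
    for (int k = 0; k < 4; ++k) {
      double dabar = 0.5 * (dx[k] + dy[k] + du[k] + dv[k]);
      double dw = dx[k] - dy[k] + du[k] - dv[k];
      double dh = (w * dw + 2.0 * (u * dv[k] + v * du[k])) / (4.0 * hs);
      if (small_h) {
        double s = std::sinh(h);
        // d/dh of sinh(h)/h
        double dgdh = (h < 1e-4) ? (h / 3.0 + h * h * h / 30.0)
                                 : (c * h - s) / (h * h);
        grad[k] = eab * (-dabar * (c + (abar - m) * g)
                         + s * dh + (dabar - dm[k]) * g
                         + (abar - m) * dgdh * dh);
      } else {
        double r = (abar - m) / h;
        double dr = (dabar - dm[k]) / h - r * dh / h;
        double dA2 = 0.5 * dr;
        double da2 = dabar - dh;
        double da1 = dabar + dh;
        grad[k] = dA2 * e2 - A2 * e2 * da2 - dA2 * e1 - A1 * e1 * da1;
      }
    }
  }
  return K;
}

// [[Rcpp::export]]
NumericVector cpp_nexi_kernel(NumericVector b, NumericVector eps,
                              NumericVector t, NumericVector f,
                              NumericVector Dn, NumericVector De,
                              NumericVector rn) {
  int n = b.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = karger_K(b[i], t[i], eps[i] * eps[i], f[i], Dn[i], De[i], rn[i],
                      nullptr);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rice-distribution mean and its derivative in the location parameter.
// E|nu + complex N(0, sigma)| = sigma sqrt(pi/2) *
//   [ (1 + tt) I0~(tt/2) + tt I1~(tt/2) ],  tt = nu^2 / (2 sigma^2),
// where I~ are exponentially scaled modified Bessel functions.
static const double SQRT_HALF_PI = 1.2533141373155003;

static inline double rice_mean_1(double nu, double sigma) {
  if (sigma <= 0.0) return nu;
  if (nu <= 0.0) return sigma * SQRT_HALF_PI;
  double ratio = nu / sigma;
  if (ratio > 1e4) return nu + sigma * sigma / (2.0 * nu);
  double tt = 0.5 * ratio * ratio;
  double i0 = R::bessel_i(tt / 2.0, 0.0, 2.0);
  double i1 = R::bessel_i(tt / 2.0, 1.0, 2.0);
  return sigma * SQRT_HALF_PI * ((1.0 + tt) * i0 + tt * i1);
}

static inline double rice_mean_dnu_1(double nu, double sigma) {
  if (sigma <= 0.0) return 1.0;
  if (nu <= 0.0) return 0.0;
  double ratio = nu / sigma;
  if (ratio > 1e4) return 1.0 - sigma * sigma / (2.0 * nu * nu);
  double tt = 0.5 * ratio * ratio;
  double i0 = R::bessel_i(tt / 2.0, 0.0, 2.0);
  double i1 = R::bessel_i(tt / 2.0, 1.0, 2.0);
  return SQRT_HALF_PI * ratio * 0.5 * (i0 + i1);
}

// [[Rcpp::export]]
NumericVector cpp_rice_mean(NumericVector nu, NumericVector sigma) {
  int n = nu.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rice_mean_1(nu[i], sigma[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rice_mean_dnu(NumericVector nu, NumericVector sigma) {
  int n = nu.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rice_mean_dnu_1(nu[i], sigma[i]);
  return out;
}

// ---------------------------------------------------------------------------
// SMEX: finite-pulse kernel by propagating the coupled magnetizations
//   d/dt [Mn; Me] = -( R + q^2(t) diag(Dn eps^2, De) ) [Mn; Me]
// through the trapezoidal PGSE waveform.  Piecewise 2x2 matrix exponentials
// with the midpoint q^2 on each substep; the inter-pulse plateau (constant q)
// is one exact step.  Substeps are doubled until |Delta K| < tol.

struct Seg { double t0, t1; int kind; };
// kind: 0 ramp-up-1, 1 flat-1, 2 ramp-down-1, 3 plateau,
//       4 ramp-up-2, 5 flat-2, 6 ramp-down-2

// normalized q(tau)/qmax on the waveform (FWHM duration delta, ramp r,
// leading-edge separation t between the two pulses)
static inline double qnorm_at(double tau, double t, double delta, double r) {
  if (r <= 0.0) r = 1e-12;
  if (tau <= 0.0) return 0.0;
  if (tau < r) return tau * tau / (2.0 * r * delta);
  if (tau < delta) return (tau - 0.5 * r) / delta;
  if (tau < delta + r) {
    double z = delta + r - tau;
    return 1.0 - z * z / (2.0 * r * delta);
  }
  if (tau < t) return 1.0;
  double u = tau - t;
  if (u < r) return 1.0 - u * u / (2.0 * r * delta);
  if (u < delta) return 1.0 - (u - 0.5 * r) / delta;
  if (u < delta + r) {
    double z = delta + r - u;
    return z * z / (2.0 * r * delta);
  }
  return 0.0;
}

static inline void expm_step(double q2, double h, double Dneps2, double De,
                             double rn, double re, double v[2]) {
  // v <- expm(-A h) v with A = [[q2*Dneps2 + rn, -re], [-rn, q2*De + re]]
  double m11 = -(q2 * Dneps2 + rn) * h;
  double m12 = re * h;
  double m21 = rn * h;
  double m22 = -(q2 * De + re) * h;
  double tm = 0.5 * (m11 + m22);
  double d = 0.5 * (m11 - m22);
  double s2 = d * d + m12 * m21;  // >= 0 (m12*m21 = rn*re*h^2 >= 0)
  double s = std::sqrt(s2 > 0.0 ? s2 : 0.0);
  double ch = std::cosh(s);
  double sh = sinhc(s);
  double et = std::exp(tm);
  double e11 = et * (ch + d * sh);
  double e12 = et * m12 * sh;
  double e21 = et * m21 * sh;
  double e22 = et * (ch - d * sh);
  double v0 = e11 * v[0] + e12 * v[1];
  double v1 = e21 * v[0] + e22 * v[1];
  v[0] = v0;
  v[1] = v1;
}

// exact average of q^2/qmax^2 over [a, b] within one polynomial piece of the
// waveform (q^2 is piecewise quartic; 5-node Gauss-Legendre is exact)
static inline double q2norm_avg(double a, double b, double t, double delta,
                                double r) {
  static const double gx[5] = {-0.9061798459386640, -0.5384693101056831, 0.0,
                               0.5384693101056831, 0.9061798459386640};
  static const double gw[5] = {0.2369268850561891, 0.4786286704993665,
                               0.5688888888888889, 0.4786286704993665,
                               0.2369268850561891};
  double hw = 0.5 * (b - a), cm = 0.5 * (b + a), acc = 0.0;
  for (int j = 0; j < 5; ++j) {
    double qn = qnorm_at(cm + hw * gx[j], t, delta, r);
    acc += 0.5 * gw[j] * qn * qn;
  }
  return acc;
}

// Exponential-midpoint propagation with the exact substep average of q^2:
// when the compartments are decoupled (rn = 0) the matrices commute and the
// product of exponentials of exact integrals is exact for any step count.
static double smex_once(double qmax2, double t, double delta, double r,
                        double Dneps2, double De, double f, double rn,
                        double re, int msub) {
  double v[2] = {f, 1.0 - f};
  Seg segs[7] = {
    {0.0, r, 0},          {r, delta, 1},        {delta, delta + r, 2},
    {delta + r, t, 3},    {t, t + r, 4},        {t + r, t + delta, 5},
    {t + delta, t + delta + r, 6}};
  for (int si = 0; si < 7; ++si) {
    double a = segs[si].t0, bEnd = segs[si].t1;
    if (bEnd <= a) continue;
    if (segs[si].kind == 3) {
      // constant q: exact in one step
      expm_step(qmax2, bEnd - a, Dneps2, De, rn, re, v);
    } else {
      int mloc = msub;
      double h = (bEnd - a) / mloc;
      for (int j = 0; j < mloc; ++j) {
        double q2bar = q2norm_avg(a + j * h, a + (j + 1) * h, t, delta, r);
        expm_step(qmax2 * q2bar, h, Dneps2, De, rn, re, v);
      }
    }
  }
  return v[0] + v[1];
}

static double smex_K(double b, double t, double delta, double r, double eps2,
                     double f, double Dn, double De, double rn,
                     double bunit, double tol, bool *ok) {
  // bunit = b-value of the unit-qmax waveform: b = qmax^2 * bunit
  double omf = 1.0 - f;
  if (omf < 1e-12) omf = 1e-12;
  double re = rn * f / omf;
  double qmax2 = (b > 0.0) ? b / bunit : 0.0;
  double Dneps2 = Dn * eps2;
  int msub = 4;
  double Kprev = smex_once(qmax2, t, delta, r, Dneps2, De, f, rn, re, msub);
  for (int it = 0; it < 12; ++it) {
    msub *= 2;
    double K = smex_once(qmax2, t, delta, r, Dneps2, De, f, rn, re, msub);
    if (std::fabs(K - Kprev) < tol) {
      if (ok) *ok = true;
      return K;
    }
    Kprev = K;
  }
  if (ok) *ok = false;
  return Kprev;
}

// b-value of the unit-qmax trapezoidal waveform, i.e. int_0^{T} (q/qmax)^2 dt,
// evaluated exactly by 5-node Gauss-Legendre per polynomial piece
static double bunit_waveform(double t, double delta, double r) {
  static const double gx[5] = {-0.9061798459386640, -0.5384693101056831, 0.0,
                               0.5384693101056831, 0.9061798459386640};
  static const double gw[5] = {0.2369268850561891, 0.4786286704993665,
                               0.5688888888888889, 0.4786286704993665,
                               0.2369268850561891};
  double edges[8] = {0.0,       r,         delta,     delta + r,
                     t,         t + r,     t + delta, t + delta + r};
  double acc = 0.0;
  for (int si = 0; si < 7; ++si) {
    double a = edges[si], bEnd = edges[si + 1];
    if (bEnd <= a) continue;
    double hw = 0.5 * (bEnd - a), cm = 0.5 * (bEnd + a);
    for (int j = 0; j < 5; ++j) {
      double qn = qnorm_at(cm + hw * gx[j], t, delta, r);
      acc += hw * gw[j] * qn * qn;
    }
  }
  return acc;
}

// [[Rcpp::export]]
double cpp_bunit_waveform(double t, double delta, double ramp) {
  return bunit_waveform(t, delta, ramp);
}

// [[Rcpp::export]]
List cpp_smex_kernel(NumericVector b, NumericVector t, NumericVector delta,
                     NumericVector ramp, NumericVector eps, NumericVector f,
                     NumericVector Dn, NumericVector De, NumericVector rn,
                     double tol) {
  int n = b.size();
  NumericVector out(n);
  LogicalVector conv(n);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    double bu = bunit_waveform(t[i], delta[i], ramp[i]);
    out[i] = smex_K(b[i], t[i], delta[i], ramp[i], eps[i] * eps[i], f[i],
                    Dn[i], De[i], rn[i], bu, tol, &ok);
    conv[i] = ok;
  }
  return List::create(_["K"] = out, _["converged"] = conv);
}

// SMEX Legendre projections K0 (and K2) for a batch of parameter sets over a
// set of (b, t) shells sharing one (delta, ramp) pulse shape.
// [[Rcpp::export]]
List cpp_smex_invariants(NumericMatrix params,
                         NumericVector b, NumericVector t, double delta,
                         double ramp, NumericVector nodes,
                         NumericVector weights, double tol) {
  int V = params.nrow(), S = b.size(), Q = nodes.size();
  NumericMatrix K0(V, S), K2(V, S);
  // bunit depends only on (t, delta, ramp): cache per shell
  std::vector<double> bu(S);
  for (int s = 0; s < S; ++s) bu[s] = bunit_waveform(t[s], delta, ramp);
  for (int v = 0; v < V; ++v) {
    double f = params(v, 0), Dn = params(v, 1), De = params(v, 2),
           rn = params(v, 3);
    for (int s = 0; s < S; ++s) {
      double k0 = 0.0, k2 = 0.0;
      for (int q = 0; q < Q; ++q) {
        double e = nodes[q], e2 = e * e;
        bool ok = true;
        double K = smex_K(b[s], t[s], delta, ramp, e2, f, Dn, De, rn, bu[s],
                          tol, &ok);
        double P2 = 0.5 * (3.0 * e2 - 1.0);
        k0 += weights[q] * K;
        k2 += weights[q] * K * P2;
      }
      K0(v, s) = k0;
      K2(v, s) = k2;
    }
  }
  return List::create(_["K0"] = K0, _["K2"] = K2);
}

// ---------------------------------------------------------------------------
// Batched NEXI forward model of rotational invariants with gradients.
// params: V x 5 (f, Dn, De, rn, p2); shells: b, t of length S.
// Returns S0 (V x S), optionally S2 and gradient arrays (V x S x 5).
// With rician = true the l = 0 prediction is the directional average of the
// Rice mean applied to the per-direction model signal
//   S(dir) = K0 + 5 p2 K2 P2(u),  u = |cos| uniform on [0, 1],
// evaluated with the same quadrature nodes.
// [[Rcpp::export]]
List cpp_nexi_forward(NumericMatrix params, NumericVector b, NumericVector t,
                      NumericVector nodes, NumericVector weights, int lmax,
                      bool rician, NumericVector sigma, bool grad) {
  int V = params.nrow(), S = b.size(), Q = nodes.size();
  bool want2 = (lmax >= 2);
  NumericMatrix S0(V, S), S2(want2 ? V : 0, want2 ? S : 0);
  NumericVector dS0, dS2;
  if (grad) {
    dS0 = NumericVector(Dimension(V, S, 5));
    if (want2) dS2 = NumericVector(Dimension(V, S, 5));
  }
  std::vector<double> P2n(Q);
  for (int q = 0; q < Q; ++q) P2n[q] = 0.5 * (3.0 * nodes[q] * nodes[q] - 1.0);

  std::vector<double> Kq(Q), dKq(grad ? 4 * Q : 0);
  double gbuf[4];

  for (int v = 0; v < V; ++v) {
    double f = params(v, 0), Dn = params(v, 1), De = params(v, 2),
           rn = params(v, 3), p2 = (params.ncol() > 4) ? params(v, 4) : 0.0;
    double sg = (sigma.size() == V) ? sigma[v] : (sigma.size() ? sigma[0] : 0.0);
    for (int s = 0; s < S; ++s) {
      double K0 = 0.0, K2s = 0.0;
      double dK0[4] = {0, 0, 0, 0}, dK2[4] = {0, 0, 0, 0};
      for (int q = 0; q < Q; ++q) {
        double e2 = nodes[q] * nodes[q];
        double K = karger_K(b[s], t[s], e2, f, Dn, De, rn,
                            grad ? gbuf : nullptr);
        Kq[q] = K;
        K0 += weights[q] * K;
        K2s += weights[q] * K * P2n[q];
        if (grad) {
          for (int k = 0; k < 4; ++k) {
            dKq[4 * q + k] = gbuf[k];
            dK0[k] += weights[q] * gbuf[k];
            dK2[k] += weights[q] * gbuf[k] * P2n[q];
          }
        }
      }
      double sgn2 = (K2s >= 0.0) ? 1.0 : -1.0;

      if (!rician) {
        S0(v, s) = K0;
        if (grad)
          for (int k = 0; k < 4; ++k) dS0[v + V * s + V * S * k] = dK0[k];
      } else if (!want2) {
        S0(v, s) = rice_mean_1(K0, sg);
        if (grad) {
          double dr = rice_mean_dnu_1(K0, sg);
          for (int k = 0; k < 4; ++k) dS0[v + V * s + V * S * k] = dr * dK0[k];
        }
      } else {
        // directional average of the Rice mean over the l <= 2 series
        double acc = 0.0, dacc[5] = {0, 0, 0, 0, 0};
        for (int q = 0; q < Q; ++q) {
          double Sdir = K0 + 5.0 * p2 * K2s * P2n[q];
          if (Sdir < 0.0) Sdir = 0.0;
          acc += weights[q] * rice_mean_1(Sdir, sg);
          if (grad) {
            double dr = rice_mean_dnu_1(Sdir, sg);
            for (int k = 0; k < 4; ++k)
              dacc[k] += weights[q] * dr * (dK0[k] + 5.0 * p2 * P2n[q] * dK2[k]);
            dacc[4] += weights[q] * dr * 5.0 * K2s * P2n[q];
          }
        }
        S0(v, s) = acc;
        if (grad)
          for (int k = 0; k < 5; ++k) dS0[v + V * s + V * S * k] = dacc[k];
      }

      if (want2) {
        S2(v, s) = p2 * std::fabs(K2s);
        if (grad) {
          for (int k = 0; k < 4; ++k)
            dS2[v + V * s + V * S * k] = p2 * sgn2 * dK2[k];
          dS2[v + V * s + V * S * 4] = std::fabs(K2s);
        }
      }
    }
  }
  List out = List::create(_["S0"] = S0);
  if (want2) out["S2"] = S2;
  if (grad) {
    out["dS0"] = dS0;
    if (want2) out["dS2"] = dS2;
  }
  // signed K2 is needed by callers that build directional series
  return out;
}

// Signed Legendre projections K0/K2 of the NEXI kernel (no gradients).
// [[Rcpp::export]]
List cpp_nexi_invariants(NumericMatrix params, NumericVector b,
                         NumericVector t, NumericVector nodes,
                         NumericVector weights) {
  int V = params.nrow(), S = b.size(), Q = nodes.size();
  NumericMatrix K0(V, S), K2(V, S);
  for (int v = 0; v < V; ++v) {
    double f = params(v, 0), Dn = params(v, 1), De = params(v, 2),
           rn = params(v, 3);
    for (int s = 0; s < S; ++s) {
      double k0 = 0.0, k2 = 0.0;
      for (int q = 0; q < Q; ++q) {
        double e2 = nodes[q] * nodes[q];
        double K = karger_K(b[s], t[s], e2, f, Dn, De, rn, nullptr);
        k0 += weights[q] * K;
        k2 += weights[q] * K * 0.5 * (3.0 * e2 - 1.0);
      }
      K0(v, s) = k0;
      K2(v, s) = k2;
    }
  }
  return List::create(_["K0"] = K0, _["K2"] = K2);
}
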