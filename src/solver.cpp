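// Core numerics: sequential scalar integration of the power-law cascade,
// cell-specific deactivation-rate closure, and Gaussian-kernel MMD.
//
// The reaction network is triangular (PI3K -> pRAF -> MEK -> ERK -> RSK,
// PI3K -> AKT, {AKT,RSK} -> GSK3B, {RSK,AKT} -> S6), so each species is a
// scalar ODE driven by already-integrated upstream trajectories evaluated
// through cubic-Hermite dense output.  The primary integrator is an
// adaptive Cash-Karp RK45; species that defeat it (extreme kinetic orders
// blow the local rate scale up by many orders of magnitude) are redone
// with an L-stable TR-BDF2 scheme whose implicit stages are solved by
// bracketed Newton/bisection -- the stage residual is strictly monotone in
// the unknown, so the solve cannot fail.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// canonical parameter order, must match modelParameterNames()
enum Par {
  I1, TAU1, D1, I2, TAU2, D2,
  KR, GR, GC1, HR, GAMMAR, RTOT,
  KP, GP, HP, GAMMAP,
  K1, G1, H1, K2, G2, H2, K3, G3, H3, K4, G4, H4,
  K5, G5, K12, G12, H5, K6, G6, K13, G13, H6, NPAR
};

inline double powp(double x, double g) {
  // non-negative base guard: transient overshoot below zero must not NaN
  return x <= 0.0 ? 0.0 : std::pow(x, g);
}

// aggregated pathway input: 1 before the delay, then a decaying exponential
inline double inputSignal(double t, double I, double tau, double d) {
  if (t < tau) return 1.0;
  return 1.0 + (I - 1.0) * std::exp(-d * (t - tau));
}

// ---- dense output ---------------------------------------------------------

struct Dense {
  std::vector<double> t, x, f;
  void clear() {
    t.clear(); x.clear(); f.clear();
    t.reserve(128); x.reserve(128); f.reserve(128);
  }
  void push(double ti, double xi, double fi) {
    t.push_back(ti); x.push_back(xi); f.push_back(fi);
  }
  // cubic Hermite evaluation; flat outside the stored range
  double eval(double tq) const {
    const size_t n = t.size();
    if (n == 0) return 0.0;
    if (tq <= t.front()) return x.front();
    if (tq >= t.back()) return x.back();
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (t[mid] <= tq) lo = mid; else hi = mid;
    }
    const double h = t[hi] - t[lo];
    if (h <= 0.0) return x[lo];
    const double s = (tq - t[lo]) / h;
    // when the stored slopes disagree wildly with the secant (stiff
    // transients resolved by an L-stable step), the cubic oscillates;
    // fall back to linear interpolation there
    const double dx = x[hi] - x[lo];
    const double scale = std::fabs(dx) +
                         1e-4 * (std::fabs(x[lo]) + std::fabs(x[hi])) + 1e-30;
    if (std::fabs(h * f[lo]) > 50.0 * scale ||
        std::fabs(h * f[hi]) > 50.0 * scale) {
      return std::max(x[lo] + s * dx, 0.0);
    }
    const double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
    const double h10 = s * (1 - s) * (1 - s);
    const double h01 = s * s * (3 - 2 * s);
    const double h11 = s * s * (s - 1);
    double v = h00 * x[lo] + h10 * h * f[lo] + h01 * x[hi] + h11 * h * f[hi];
    return std::max(v, 0.0);
  }
};

// ---- scalar right-hand sides ----------------------------------------------

// dx/dt = prod(t) * (cap - x) - gamma * x^h   (cap = +Inf handled separately)
struct SpeciesRHS {
  // production coefficient A(t); for the no-capacity form, total production
  bool hasCap;
  double cap, gamma, h;
  // production callback data: up to two upstream interpolants with
  // coefficient/exponent, or direct input signals
  int kind;  // 0: PI3K, 1: pRAF, 2: one-branch cell species, 3: two-branch
  const double *th;
  const Dense *up1, *up2;
  double c1, g1e, c2, g2e;  // production terms c * up^g

  double prodCoef(double t) const {
    switch (kind) {
    case 0:  // PI3K: kP * u2(t)^gP   (production, not a coefficient on cap-x)
      return th[KP] * std::pow(inputSignal(t, th[I2], th[TAU2], th[D2]), th[GP]);
    case 1:  // pRAF: kR * u1^gR * PI3K(t)^gc1
      return th[KR] *
             std::pow(inputSignal(t, th[I1], th[TAU1], th[D1]), th[GR]) *
             powp(up1->eval(t), th[GC1]);
    case 2:
      return c1 * powp(up1->eval(t), g1e);
    default:
      return c1 * powp(up1->eval(t), g1e) + c2 * powp(up2->eval(t), g2e);
    }
  }
  double operator()(double t, double x) const {
    const double a = prodCoef(t);
    const double dec = gamma * powp(x, h);
    return hasCap ? a * (cap - x) - dec : a - dec;
  }
  // upper bound on f(t, x) used to bracket implicit stages
  double prodMax(double t) const {
    const double a = prodCoef(t);
    return hasCap ? a * cap : a;
  }
};

// ---- adaptive Cash-Karp RK45 ----------------------------------------------

bool integrateCK45(const SpeciesRHS &f, double t0, double t1, double x0,
                   double rtol, double atol, int maxSteps, Dense &out) {
  static const double a2 = 0.2, a3 = 0.3, a4 = 0.6, a5 = 1.0, a6 = 0.875;
  static const double b21 = 0.2;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
  static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                      b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                      d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                      d6 = c6 - 0.25;

  double t = t0, x = x0;
  double fx = f(t, x);
  if (!std::isfinite(fx)) return false;
  out.push(t, x, fx);
  if (t1 <= t0) return true;
  double hstep = (t1 - t0) / 16.0;
  const double hmin = (t1 - t0) * 1e-10;
  int steps = 0;
  while (t < t1) {
    if (++steps > maxSteps) return false;
    if (t + hstep > t1) hstep = t1 - t;
    const double k1 = fx;
    const double k2 = f(t + a2 * hstep, x + hstep * b21 * k1);
    const double k3 = f(t + a3 * hstep, x + hstep * (b31 * k1 + b32 * k2));
    const double k4 = f(t + a4 * hstep, x + hstep * (b41 * k1 + b42 * k2 + b43 * k3));
    const double k5 = f(t + a5 * hstep,
                        x + hstep * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4));
    const double k6 = f(t + a6 * hstep,
                        x + hstep * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 +
                                     b65 * k5));
    const double xnew = x + hstep * (c1 * k1 + c3 * k3 + c4 * k4 + c6 * k6);
    const double errAbs = std::fabs(
        hstep * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6));
    const double sc = atol + rtol * std::max(std::fabs(x), std::fabs(xnew));
    const double err = errAbs / sc;
    if (!std::isfinite(err)) {
      hstep *= 0.25;
      if (hstep < hmin) return false;
      continue;
    }
    if (err <= 1.0) {
      t += hstep;
      x = std::max(xnew, 0.0);
      fx = f(t, x);
      out.push(t, x, fx);
      double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      hstep *= std::min(5.0, std::max(0.2, fac));
    } else {
      hstep *= std::max(0.2, 0.9 * std::pow(err, -0.25));
      if (hstep < hmin) return false;
    }
  }
  return true;
}

// ---- TR-BDF2 with bracketed implicit solves -------------------------------

// solve F(x) = x - cst - s * f(t, x) = 0; F strictly increasing in x.
// The production coefficient is frozen at the stage time, so each Newton
// iteration costs one pow; the bracket [lo, hi] makes the solve safe.
double implicitStage(const SpeciesRHS &f, double t, double cst, double s) {
  const double A = std::max(f.prodCoef(t), 0.0);
  const bool cap = f.hasCap;
  auto fx = [&](double x) {
    return (cap ? A * (f.cap - x) : A) - f.gamma * powp(x, f.h);
  };
  double lo = 0.0;
  double hi = cst + s * (cap ? A * f.cap : A);
  if (hi <= lo) hi = std::max(cst, 1e-300);
  double x = std::min(std::max(cst, 0.5 * hi), hi);
  for (int it = 0; it < 100; ++it) {
    const double F = x - cst - s * fx(x);
    if (F > 0.0) hi = x; else lo = x;
    const double dF =
        1.0 + s * ((cap ? A : 0.0) + f.gamma * f.h * powp(x, f.h - 1.0));
    double xn = x - F / dF;
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
    if (std::fabs(xn - x) <= 1e-12 * (1.0 + std::fabs(xn))) return xn;
    x = xn;
  }
  return x;
}

// one TR-BDF2 step from (t, xn) with step h; gamma = 2 - sqrt(2)
double trbdf2Step(const SpeciesRHS &f, double t, double xn, double h) {
  const double g = 2.0 - std::sqrt(2.0);
  const double fn = f(t, xn);
  // stage 1: trapezoid to t + g*h
  const double s1 = 0.5 * g * h;
  const double x1 = implicitStage(f, t + g * h, xn + s1 * fn, s1);
  // stage 2: BDF2-like to t + h
  const double w = 1.0 / (g * (2.0 - g));
  const double cst = w * x1 - (1.0 - g) * (1.0 - g) * w * xn;
  const double s2 = (1.0 - g) / (2.0 - g) * h;
  return implicitStage(f, t + h, cst, s2);
}

bool integrateTRBDF2(const SpeciesRHS &f, double t0, double t1, double x0,
                     double rtol, double atol, int maxSteps, Dense &out) {
  double t = t0, x = x0;
  out.push(t, x, f(t, x));
  if (t1 <= t0) return true;
  double hstep = (t1 - t0) / 64.0;
  const double hmin = (t1 - t0) * 1e-12;
  int steps = 0;
  while (t < t1) {
    if (++steps > maxSteps) return false;
    if (t + hstep > t1) hstep = t1 - t;
    // boundary-layer onset (e.g. an input jump under an astronomically
    // fast rate): the local rate dwarfs every state scale, the layer is
    // physically instantaneous, and TR-BDF2's trapezoid stage would be
    // catapulted by its explicit half.  One L-stable backward-Euler step
    // lands on the slow manifold and is accepted as the layer's limit.
    const double fn0 = f(t, x);
    const double big =
        100.0 * (std::fabs(x) + (f.hasCap ? f.cap : std::fabs(x)) + 1.0);
    if (std::isfinite(fn0) && std::fabs(fn0) * hstep > big) {
      const double xl = implicitStage(f, t + hstep, x, hstep);
      if (!std::isfinite(xl)) return false;
      t += hstep;
      x = std::max(xl, 0.0);
      out.push(t, x, f(t, x));
      continue;
    }
    // error control by step doubling (scheme is 2nd order: error ~ diff/3)
    const double xFull = trbdf2Step(f, t, x, hstep);
    const double xHalf1 = trbdf2Step(f, t, x, 0.5 * hstep);
    const double xHalf = trbdf2Step(f, t + 0.5 * hstep, xHalf1, 0.5 * hstep);
    const double sc = atol + rtol * std::max(std::fabs(x), std::fabs(xHalf));
    const double err = std::fabs(xFull - xHalf) / (3.0 * sc);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += hstep;
      x = std::max(xHalf, 0.0);
      out.push(t, x, f(t, x));
      double fac = err > 0.0 ? 0.9 * std::pow(err, -1.0 / 3.0) : 4.0;
      hstep *= std::min(4.0, std::max(0.2, fac));
    } else {
      hstep *= std::max(0.1, 0.9 * std::pow(err, -0.5));
      if (hstep < hmin) return false;
    }
  }
  return true;
}

// integrate one species across input-delay breakpoints; explicit first,
// implicit (L-stable) fallback on failure.  `usedFallback` reports whether
// the implicit path was needed, so ensemble callers can route subsequent
// cells of a stiff species straight to it.
bool integrateSpecies(const SpeciesRHS &f, double x0, double tmax,
                      const std::vector<double> &breaks, double rtol,
                      double atol, Dense &out, bool preferImplicit = false,
                      bool *usedFallback = nullptr) {
  out.clear();
  double t = 0.0, x = x0;
  std::vector<double> ends;
  for (double b : breaks) if (b > 0.0 && b < tmax) ends.push_back(b);
  ends.push_back(tmax);
  std::sort(ends.begin(), ends.end());
  for (double te : ends) {
    if (te <= t) continue;
    Dense seg;
    bool ok = !preferImplicit &&
              integrateCK45(f, t, te, x, rtol, atol, 250, seg);
    if (!ok) {
      seg.clear();
      ok = integrateTRBDF2(f, t, te, x, rtol, atol, 5000, seg);
      if (!ok) {
        // extreme parameter corners: accuracy matters far less than
        // robustness there, so retry once with relaxed tolerances
        seg.clear();
        ok = integrateTRBDF2(f, t, te, x, 100.0 * rtol, 100.0 * atol,
                             20000, seg);
      }
      if (usedFallback) *usedFallback = true;
    }
    if (!ok) return false;
    // append, skipping the duplicated segment start
    size_t from = out.t.empty() ? 0 : 1;
    for (size_t i = from; i < seg.t.size(); ++i) {
      out.push(seg.t[i], seg.x[i], seg.f[i]);
    }
    t = te;
    x = out.x.back();
  }
  return true;
}

// ---- model assembly --------------------------------------------------------

struct SharedTraj {
  Dense xp, xr;
};

bool simulateShared(const double *th, double xR0, double xP0, double tmax,
                    double rtol, SharedTraj &sh) {
  std::vector<double> brk = {th[TAU1], th[TAU2]};
  SpeciesRHS fP;
  fP.hasCap = false; fP.cap = 0.0; fP.gamma = th[GAMMAP]; fP.h = th[HP];
  fP.kind = 0; fP.th = th; fP.up1 = fP.up2 = nullptr;
  if (!integrateSpecies(fP, xP0, tmax, brk, rtol, 1e-9 * std::max(xP0, 1.0),
                        sh.xp)) {
    return false;
  }
  SpeciesRHS fR;
  fR.hasCap = true; fR.cap = th[RTOT]; fR.gamma = th[GAMMAR]; fR.h = th[HR];
  fR.kind = 1; fR.th = th; fR.up1 = &sh.xp; fR.up2 = nullptr;
  return integrateSpecies(fR, xR0, tmax, brk, rtol,
                          1e-9 * std::max(th[RTOT], 1.0), sh.xr);
}

// derive the six cell-specific deactivation rates from the steady-state
// closure at baseline input (u = 1)
void deriveGammaRow(const double *th, double xR0, double xP0,
                    const double *T, const double *x0, double *g) {
  g[0] = th[K1] * std::pow(xR0, th[G1]) * (T[0] - x0[0]) / std::pow(x0[0], th[H1]);
  g[1] = th[K2] * std::pow(x0[0], th[G2]) * (T[1] - x0[1]) / std::pow(x0[1], th[H2]);
  g[2] = th[K3] * std::pow(x0[1], th[G3]) * (T[2] - x0[2]) / std::pow(x0[2], th[H3]);
  g[3] = th[K4] * std::pow(xP0, th[G4]) * (T[3] - x0[3]) / std::pow(x0[3], th[H4]);
  g[4] = (th[K5] * std::pow(x0[3], th[G5]) + th[K12] * std::pow(x0[2], th[G12])) *
         (T[4] - x0[4]) / std::pow(x0[4], th[H5]);
  g[5] = (th[K6] * std::pow(x0[2], th[G6]) + th[K13] * std::pow(x0[3], th[G13])) *
         (T[5] - x0[5]) / std::pow(x0[5], th[H6]);
}

// integrate the six measured species of one cell; writes states at the
// requested output times (times <= 0 return the baseline)
bool simulateCell(const double *th, const SharedTraj &sh,
                  const double *T, const double *x0, const double *g,
                  const std::vector<double> &times, double tmax, double rtol,
                  double *outStates /* 6 x ntimes, species-major rows */,
                  int *stiffHint = nullptr /* per-species fallback counts */,
                  int cellIndex = 0) {
  std::vector<double> brk = {th[TAU1], th[TAU2]};
  Dense tr[6];
  SpeciesRHS f;
  f.th = th; f.hasCap = true;
  struct Wire { int kind; int up1; int up2; double c1p, g1p, c2p, g2p; };
  // upstream wiring: -1 = pRAF dense, -2 = PI3K dense, >=0 = own species
  const Wire wire[6] = {
    {2, -1, 0, th[K1], th[G1], 0, 0},       // MEK <- pRAF
    {2, 0, 0, th[K2], th[G2], 0, 0},        // ERK <- MEK
    {2, 1, 0, th[K3], th[G3], 0, 0},        // RSK <- ERK
    {2, -2, 0, th[K4], th[G4], 0, 0},       // AKT <- PI3K
    {3, 3, 2, th[K5], th[G5], th[K12], th[G12]},  // GSK <- AKT + RSK
    {3, 2, 3, th[K6], th[G6], th[K13], th[G13]},  // S6  <- RSK + AKT
  };
  for (int s = 0; s < 6; ++s) {
    const Wire &w = wire[s];
    f.kind = w.kind;
    f.cap = T[s]; f.gamma = g[s]; f.h = (s == 0 ? th[H1] : s == 1 ? th[H2] :
                                         s == 2 ? th[H3] : s == 3 ? th[H4] :
                                         s == 4 ? th[H5] : th[H6]);
    f.c1 = w.c1p; f.g1e = w.g1p; f.c2 = w.c2p; f.g2e = w.g2p;
    f.up1 = w.up1 == -1 ? &sh.xr : (w.up1 == -2 ? &sh.xp : &tr[w.up1]);
    f.up2 = w.up2 >= 0 ? &tr[w.up2] : nullptr;
    // once a third of the cells needed the implicit path for this species,
    // send the rest straight there
    bool prefer = stiffHint && 3 * stiffHint[s] > cellIndex;
    bool fell = false;
    if (!integrateSpecies(f, x0[s], tmax, brk, rtol,
                          1e-9 * std::max(T[s], 1.0), tr[s], prefer, &fell)) {
      return false;
    }
    if (stiffHint && fell) ++stiffHint[s];
  }
  const size_t nt = times.size();
  for (size_t k = 0; k < nt; ++k) {
    for (int s = 0; s < 6; ++s) {
      outStates[s + 6 * k] = times[k] <= 0.0 ? x0[s] : tr[s].eval(times[k]);
    }
  }
  return true;
}

}  // namespace

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_derive_gamma(NumericVector theta, double xR0, double xP0,
                               NumericMatrix totals, NumericMatrix baseline) {
  const int n = totals.nrow();
  NumericMatrix out(n, 6);
  std::vector<double> th(theta.begin(), theta.end());
  double T[6], x0[6], g[6];
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 6; ++s) { T[s] = totals(i, s); x0[s] = baseline(i, s); }
    deriveGammaRow(th.data(), xR0, xP0, T, x0, g);
    for (int s = 0; s < 6; ++s) out(i, s) = g[s];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_ensemble(NumericVector theta, double xR0, double xP0,
                           NumericMatrix totals, NumericMatrix baseline,
                           NumericMatrix gammaMat, NumericVector times,
                           double rtol) {
  const int n = totals.nrow();
  const int nt = times.size();
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> tv(times.begin(), times.end());
  double tmax = 1.0;
  for (double t : tv) tmax = std::max(tmax, t);

  SharedTraj sh;
  if (!simulateShared(th.data(), xR0, xP0, tmax, rtol, sh)) {
    stop("integration of the shared unmeasured species failed");
  }
  NumericVector states(Dimension(n, 6, nt));
  std::vector<int> failed;
  double T[6], x0[6], g[6];
  int stiffHint[6] = {0, 0, 0, 0, 0, 0};
  std::vector<double> cellOut(6 * nt);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 6; ++s) {
      T[s] = totals(i, s); x0[s] = baseline(i, s); g[s] = gammaMat(i, s);
    }
    if (simulateCell(th.data(), sh, T, x0, g, tv, tmax, rtol, cellOut.data(),
                     stiffHint, i)) {
      for (int k = 0; k < nt; ++k) {
        for (int s = 0; s < 6; ++s) states[i + n * s + n * 6 * k] = cellOut[s + 6 * k];
      }
    } else {
      failed.push_back(i + 1);
      for (int k = 0; k < nt; ++k) {
        for (int s = 0; s < 6; ++s) states[i + n * s + n * 6 * k] = NA_REAL;
      }
    }
  }
  NumericMatrix shared(nt, 2);
  for (int k = 0; k < nt; ++k) {
    shared(k, 0) = tv[k] <= 0.0 ? xR0 : sh.xr.eval(tv[k]);
    shared(k, 1) = tv[k] <= 0.0 ? xP0 : sh.xp.eval(tv[k]);
  }
  return List::create(_["states"] = states, _["shared"] = shared,
                      _["failed"] = wrap(failed));
}

// ---- MMD ------------------------------------------------------------------

namespace {

// batched Gaussian-kernel sums: squared distances via one GEMM, then a
// vectorised exponential

// sum over all pairs (i in A, j in B) of exp(-||a_i - b_j||^2 / 2 sigma^2)
double ksumCrossAll(const arma::mat &A, const arma::mat &B, double sigma) {
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  arma::vec na = arma::sum(arma::square(A), 1);
  arma::vec nb = arma::sum(arma::square(B), 1);
  arma::mat D = A * B.t();
  D.each_col() -= 0.5 * na;
  D.each_row() -= 0.5 * nb.t();
  // D_ij = a.b - (|a|^2 + |b|^2)/2 = -||a-b||^2 / 2
  return arma::accu(arma::exp(D * (2.0 * inv2s2)));
}

// mean kernel within A; biased includes the unit diagonal
double kmeanSelf(const arma::mat &A, double sigma, bool biased) {
  const int n = A.n_rows;
  const double tot = ksumCrossAll(A, A, sigma);  // includes diagonal of n
  if (biased) return tot / (double(n) * n);
  return (tot - n) / (double(n) * (n - 1));
}

double kmeanCross(const arma::mat &A, const arma::mat &B, double sigma) {
  return ksumCrossAll(A, B, sigma) / (double(A.n_rows) * B.n_rows);
}

}  // namespace

// [[Rcpp::export]]
double cpp_mmd2(arma::mat A, arma::mat B, double sigma, bool biased) {
  return kmeanSelf(A, sigma, biased) + kmeanSelf(B, sigma, biased) -
         2.0 * kmeanCross(A, B, sigma);
}

// [[Rcpp::export]]
double cpp_kmean_self(arma::mat A, double sigma, bool biased) {
  return kmeanSelf(A, sigma, biased);
}

// Full distribution-matching cost: derive gammas, simulate the ensemble at
// the data's time points, and sum weighted biased MMD^2 on log2-transformed
// phospho channels.  dataSelf holds the precomputed within-data kernel
// means.  Returns +Inf when more than failTol of cells fail to integrate.
// [[Rcpp::export]]
double cpp_ensemble_cost(NumericVector theta, double xR0, double xP0,
                         NumericMatrix totals, NumericMatrix baseline,
                         List dataMats, NumericVector dataSelf,
                         NumericVector times, NumericVector weights,
                         double sigma, double log2offset, double rtol,
                         double failTol, NumericMatrix noiseFactors) {
  const int n = totals.nrow();
  const int nt = times.size();
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> tv(times.begin(), times.end());
  double tmax = 1.0;
  for (double t : tv) tmax = std::max(tmax, t);

  SharedTraj sh;
  if (!simulateShared(th.data(), xR0, xP0, tmax, rtol, sh)) return R_PosInf;

  arma::mat sim(n, 6 * nt);
  std::vector<int> ok;
  ok.reserve(n);
  const int maxFail = (int)std::floor(failTol * n);
  int nFail = 0;
  double T[6], x0[6], g[6];
  int stiffHint[6] = {0, 0, 0, 0, 0, 0};
  std::vector<double> cellOut(6 * nt);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 6; ++s) { T[s] = totals(i, s); x0[s] = baseline(i, s); }
    deriveGammaRow(th.data(), xR0, xP0, T, x0, g);
    bool good = true;
    for (int s = 0; s < 6 && good; ++s) good = std::isfinite(g[s]) && g[s] > 0;
    if (good) {
      good = simulateCell(th.data(), sh, T, x0, g, tv, tmax, rtol,
                          cellOut.data(), stiffHint, i);
    }
    if (!good) {
      if (++nFail > maxFail) return R_PosInf;  // fail fast on bad regions
      continue;
    }
    const int r = ok.size();
    ok.push_back(i);
    // frozen multiplicative measurement-noise factors keep the cost a
    // deterministic function of theta while matching the data's noise model
    const bool noisy = noiseFactors.nrow() == n;
    for (int k = 0; k < nt; ++k) {
      for (int s = 0; s < 6; ++s) {
        double x = cellOut[s + 6 * k];
        if (noisy) x *= noiseFactors(i, s + 6 * k);
        sim(r, s + 6 * k) = std::log2(x + log2offset);
      }
    }
  }
  const int nOK = ok.size();
  if (nOK < 2 || (n - nOK) > failTol * n) return R_PosInf;

  double F = 0.0;
  for (int k = 0; k < nt; ++k) {
    if (weights[k] == 0.0) continue;
    arma::mat S = sim.submat(0, 6 * k, nOK - 1, 6 * k + 5);
    const arma::mat &D = as<arma::mat>(dataMats[k]);
    const double v = kmeanSelf(S, sigma, true) + dataSelf[k] -
                     2.0 * kmeanCross(S, D, sigma);
    F += weights[k] * v;
  }
  return std::isfinite(F) ? F : R_PosInf;
}
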