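#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Adams-Bashforth-Moulton predictor-corrector for Caputo fractional systems.
// Weights follow the Diethelm-Ford-Freed discretization of the Volterra
// integral form; per-step history sums are O(min(n, L)) with an optional
// frozen-weight short-memory tail so the classical q = 1 limit stays exact
// under truncation.

struct AbmWeights {
  double q, hq_corr, hq_pred;       // h^q/Gamma(q+2), h^q/q/Gamma(q)
  std::vector<double> P;            // s^q
  std::vector<double> Q;            // s^(q+1)
  AbmWeights(double q_, double h, int nmax) : q(q_) {
    hq_corr = std::pow(h, q) / std::tgamma(q + 2.0);
    hq_pred = std::pow(h, q) / q / std::tgamma(q);
    P.resize(nmax + 3); Q.resize(nmax + 3);
    for (int s = 0; s < (int)P.size(); ++s) {
      P[s] = std::pow((double)s, q);
      Q[s] = std::pow((double)s, q + 1.0);
    }
  }
  // corrector weight for 1 <= j <= n, s = n - j
  inline double a(int s) const { return Q[s + 2] + Q[s] - 2.0 * Q[s + 1]; }
  // corrector weight for j = 0 at step n
  inline double a0(int n) const { return Q[n] - (n - q) * P[n + 1]; }
  // predictor weight, s = n - j
  inline double b(int s) const { return P[s + 1] - P[s]; }
};

// Right-hand side of the socially buffered stress-response model with
// periodic environmental forcing A(t) = A0 + rho * sin(omega t).
struct StressField {
  double k1, k2, k3, k4, k5, k6, k7, k8, k9, A0, S0, beta, B, rho, omega;
  StressField(NumericVector p) {
    k1 = p["k1"]; k2 = p["k2"]; k3 = p["k3"]; k4 = p["k4"]; k5 = p["k5"];
    k6 = p["k6"]; k7 = p["k7"]; k8 = p["k8"]; k9 = p["k9"];
    A0 = p["A0"]; S0 = p["S0"]; beta = p["beta"]; B = p["B"];
    rho = p["rho"]; omega = p["omega"];
  }
  inline void operator()(double t, const double* y, double* f) const {
    double A = A0 + rho * std::sin(omega * t);
    f[0] = k1 * A + (k2 * B - k6) * y[0] + k3 * y[1] - k4 * y[0] * y[2]
           - k5 * y[0] * y[0];
    f[1] = k6 * y[0] - k7 * y[1];
    f[2] = k8 * (S0 - y[2]) * y[1] - beta * k4 * y[0] * y[2] - k9 * y[2];
  }
  inline void jac(const double* y, double* J) const { // row-major 3x3
    J[0] = k2 * B - k6 - k4 * y[2] - 2.0 * k5 * y[0]; J[1] = k3; J[2] = -k4 * y[0];
    J[3] = k6; J[4] = -k7; J[5] = 0.0;
    J[6] = -beta * k4 * y[2]; J[7] = k8 * (S0 - y[2]);
    J[8] = -k8 * y[1] - beta * k4 * y[0] - k9;
  }
};

// Generic ABM driver over an m-dimensional field with per-component orders.
// hist: m x (n+1) storage of f evaluations. L = 0 means full memory.
template <typename Field>
static List abm_drive(const Field& field, int m, NumericVector q,
                      double h, int nsteps, NumericVector y0, int L,
                      double blow, int citer, double t0 = 0.0) {
  std::vector<AbmWeights> W;
  for (int i = 0; i < m; ++i) W.emplace_back(q[i], h, nsteps);
  NumericMatrix out(nsteps + 1, m);
  std::vector<std::vector<double>> F(m, std::vector<double>(nsteps + 1));
  std::vector<double> tailA(m, 0.0), tailB(m, 0.0); // frozen-weight tails
  std::vector<double> y(m), f(m), yp(m);
  for (int i = 0; i < m; ++i) { y[i] = y0[i]; out(0, i) = y0[i]; }
  field(t0, y.data(), f.data());
  for (int i = 0; i < m; ++i) F[i][0] = f[i];
  bool diverged = false;
  int nfin = nsteps;
  for (int n = 0; n < nsteps; ++n) {
    double tn1 = t0 + (n + 1) * h;
    int j0 = (L > 0 && n + 1 > L) ? (n + 1 - L) : 0;
    // predictor
    for (int i = 0; i < m; ++i) {
      const AbmWeights& w = W[i];
      double s_pred = 0.0;
      for (int j = j0; j <= n; ++j) s_pred += w.b(n - j) * F[i][j];
      if (j0 > 0) s_pred += tailB[i] * w.b(L); // frozen tail (excl. handled below)
      yp[i] = y0[i] + w.hq_pred * s_pred;
    }
    field(tn1, yp.data(), f.data());
    for (int ci = 0; ci < citer; ++ci) {
      for (int i = 0; i < m; ++i) {
        const AbmWeights& w = W[i];
        double s_corr = f[i]; // j = n+1 weight is 1
        int jlo = std::max(j0, 1);
        for (int j = jlo; j <= n; ++j) s_corr += w.a(n - j) * F[i][j];
        if (j0 > 0) s_corr += tailA[i] * w.a(L) + w.a0(n) * F[i][0];
        else s_corr += w.a0(n) * F[i][0];
        y[i] = y0[i] + w.hq_corr * s_corr;
      }
      if (ci + 1 < citer) field(tn1, y.data(), f.data());
    }
    // divergence check
    bool bad = false;
    for (int i = 0; i < m; ++i)
      if (!std::isfinite(y[i]) || std::fabs(y[i]) > blow) bad = true;
    if (bad) { diverged = true; nfin = n; break; }
    field(tn1, y.data(), f.data());
    for (int i = 0; i < m; ++i) { F[i][n + 1] = f[i]; out(n + 1, i) = y[i]; }
    if (L > 0 && n + 1 >= L) { // index n+1-L leaves the window next step
      int jx = n + 1 - L;
      if (jx >= 1)
        for (int i = 0; i < m; ++i) { tailA[i] += F[i][jx]; tailB[i] += F[i][jx]; }
    }
  }
  return List::create(_["states"] = out, _["diverged"] = diverged,
                      _["n_finite"] = nfin);
}

// [[Rcpp::export]]
List abm_stress_cpp(NumericVector pars, NumericVector q, double h, int nsteps,
                    NumericVector y0, int L, double blow, int citer,
                    double t0) {
  StressField field(pars);
  return abm_drive(field, 3, q, h, nsteps, y0, L, blow, citer, t0);
}

// Linear field y' = A y (tests / benchmarks).
struct LinField {
  NumericMatrix A; int m;
  LinField(NumericMatrix A_) : A(A_), m(A_.nrow()) {}
  inline void operator()(double, const double* y, double* f) const {
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int j = 0; j < m; ++j) s += A(i, j) * y[j];
      f[i] = s;
    }
  }
};

// [[Rcpp::export]]
List abm_linear_cpp(NumericMatrix A, NumericVector q, double h, int nsteps,
                    NumericVector y0, int L, double blow, int citer,
                    double t0) {
  LinField field(A);
  return abm_drive(field, A.nrow(), q, h, nsteps, y0, L, blow, citer, t0);
}

// ---- Benettin-Wolf: state + orthonormal tangent frame ----------------------
// The state subsystem carries its (optionally truncated) fractional history
// for the whole run; the tangent subsystem restarts its memory at every
// Gram-Schmidt renormalization, which keeps the orthonormalized frame a
// legitimate initial condition for the next leg.

template <typename Field>
static List benettin_drive(const Field& field, NumericVector q, double h,
                           int nsteps, NumericVector y0, int L, double blow,
                           int renorm_every) {
  const int m = 3, mt = 9;
  std::vector<AbmWeights> W;
  for (int i = 0; i < m; ++i) W.emplace_back(q[i], h, nsteps);
  // tangent weights: reuse state orders (q repeated per column)
  std::vector<AbmWeights> WT;
  for (int c = 0; c < 3; ++c)
    for (int i = 0; i < m; ++i) WT.emplace_back(q[i], h, renorm_every + 1);
  std::vector<std::vector<double>> F(m, std::vector<double>(nsteps + 1));
  std::vector<std::vector<double>> FT(mt, std::vector<double>(renorm_every + 2));
  std::vector<double> tailA(m, 0.0), tailB(m, 0.0);
  std::vector<double> y(m), f(m), yp(m), J(9), ft(mt), Tp(mt);
  std::vector<double> T(mt), T0(mt);          // current tangent, leg anchor
  for (int i = 0; i < m; ++i) y[i] = y0[i];
  for (int i = 0; i < mt; ++i) T[i] = (i % 4 == 0) ? 1.0 : 0.0; // identity cols
  for (int i = 0; i < mt; ++i) T0[i] = T[i];
  field(0.0, y.data(), f.data());
  for (int i = 0; i < m; ++i) F[i][0] = f[i];
  field.jac(y.data(), J.data());
  auto jtimes = [&](const double* Tv, double* out) {
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += J[3 * r + k] * Tv[3 * c + k];
        out[3 * c + r] = s;
      }
  };
  jtimes(T.data(), ft.data());
  for (int i = 0; i < mt; ++i) FT[i][0] = ft[i];
  int nleg = 0; // steps since last renorm
  int nrenorm = nsteps / renorm_every;
  NumericMatrix lognorms(nrenorm, 3);
  NumericVector rtimes(nrenorm);
  int ri = 0;
  bool diverged = false;
  for (int n = 0; n < nsteps && ri < nrenorm; ++n) {
    double tn1 = (n + 1) * h;
    int j0 = (L > 0 && n + 1 > L) ? (n + 1 - L) : 0;
    // --- state predictor/corrector (PECE) ---
    for (int i = 0; i < m; ++i) {
      const AbmWeights& w = W[i];
      double sp = 0.0;
      for (int j = j0; j <= n; ++j) sp += w.b(n - j) * F[i][j];
      if (j0 > 0) sp += tailB[i] * w.b(L);
      yp[i] = y0[i] + w.hq_pred * sp;
    }
    field(tn1, yp.data(), f.data());
    for (int i = 0; i < m; ++i) {
      const AbmWeights& w = W[i];
      double sc = f[i];
      int jlo = std::max(j0, 1);
      for (int j = jlo; j <= n; ++j) sc += w.a(n - j) * F[i][j];
      if (j0 > 0) sc += tailA[i] * w.a(L) + w.a0(n) * F[i][0];
      else sc += w.a0(n) * F[i][0];
      y[i] = y0[i] + w.hq_corr * sc;
    }
    // --- tangent predictor/corrector on the leg-local clock ---
    int nl = nleg;
    for (int i = 0; i < mt; ++i) {
      const AbmWeights& w = WT[i];
      double sp = 0.0;
      for (int j = 0; j <= nl; ++j) sp += w.b(nl - j) * FT[i][j];
      Tp[i] = T0[i] + w.hq_pred * sp;
    }
    field.jac(y.data(), J.data()); // Jacobian at corrected new state
    jtimes(Tp.data(), ft.data());
    for (int i = 0; i < mt; ++i) {
      const AbmWeights& w = WT[i];
      double sc = ft[i];
      for (int j = 1; j <= nl; ++j) sc += w.a(nl - j) * FT[i][j];
      sc += w.a0(nl) * FT[i][0];
      T[i] = T0[i] + w.hq_corr * sc;
    }
    bool bad = false;
    for (int i = 0; i < m; ++i)
      if (!std::isfinite(y[i]) || std::fabs(y[i]) > blow) bad = true;
    if (bad) { diverged = true; break; }
    field(tn1, y.data(), f.data());
    for (int i = 0; i < m; ++i) F[i][n + 1] = f[i];
    jtimes(T.data(), ft.data());
    for (int i = 0; i < mt; ++i) FT[i][nleg + 1] = ft[i];
    if (L > 0 && n + 1 >= L) {
      int jx = n + 1 - L;
      if (jx >= 1)
        for (int i = 0; i < m; ++i) { tailA[i] += F[i][jx]; tailB[i] += F[i][jx]; }
    }
    ++nleg;
    if (nleg == renorm_every) {
      // modified Gram-Schmidt on columns of T
      for (int c = 0; c < 3; ++c) {
        double* vc = &T[3 * c];
        for (int cp = 0; cp < c; ++cp) {
          const double* vp = &T[3 * cp];
          double dot = vc[0] * vp[0] + vc[1] * vp[1] + vc[2] * vp[2];
          for (int k = 0; k < 3; ++k) vc[k] -= dot * vp[k];
        }
        double nrm = std::sqrt(vc[0] * vc[0] + vc[1] * vc[1] + vc[2] * vc[2]);
        lognorms(ri, c) = std::log(nrm);
        for (int k = 0; k < 3; ++k) vc[k] /= nrm;
      }
      rtimes[ri] = tn1;
      ++ri;
      // restart tangent memory from the orthonormal frame
      for (int i = 0; i < mt; ++i) T0[i] = T[i];
      jtimes(T.data(), ft.data());
      for (int i = 0; i < mt; ++i) FT[i][0] = ft[i];
      nleg = 0;
    }
  }
  return List::create(_["lognorms"] = lognorms, _["times"] = rtimes,
                      _["n_events"] = ri, _["diverged"] = diverged);
}

// [[Rcpp::export]]
List benettin_stress_cpp(NumericVector pars, NumericVector q, double h,
                         int nsteps, NumericVector y0, int L, double blow,
                         int renorm_every) {
  StressField field(pars);
  return benettin_drive(field, q, h, nsteps, y0, L, blow, renorm_every);
}

struct LinField3 {
  NumericMatrix A;
  LinField3(NumericMatrix A_) : A(A_) {}
  inline void operator()(double, const double* y, double* f) const {
    for (int i = 0; i < 3; ++i) {
      double s = 0.0;
      for (int j = 0; j < 3; ++j) s += A(i, j) * y[j];
      f[i] = s;
    }
  }
  inline void jac(const double*, double* J) const {
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) J[3 * r + c] = A(r, c);
  }
};

// [[Rcpp::export]]
List benettin_linear_cpp(NumericMatrix A, NumericVector q, double h,
                         int nsteps, NumericVector y0, int L, double blow,
                         int renorm_every) {
  LinField3 field(A);
  return benettin_drive(field, q, h, nsteps, y0, L, blow, renorm_every);
}

// Combined 12-dim system: state (3) + tangent columns (9), one fresh Caputo
// IVP. Used by the leg-restart Benettin-Wolf mode, where every
// renormalization starts a new initial-value problem from the current state
// and orthonormalized frame (the memory of the whole system restarts).
struct StressTangentField {
  StressField base;
  StressTangentField(NumericVector p) : base(p) {}
  inline void operator()(double t, const double* y, double* f) const {
    base(t, y, f);
    double J[9];
    base.jac(y, J);
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += J[3 * r + k] * y[3 + 3 * c + k];
        f[3 + 3 * c + r] = s;
      }
  }
};

// [[Rcpp::export]]
List abm_stress_tangent_cpp(NumericVector pars, NumericVector q, double h,
                            int nsteps, NumericVector y0, int L, double blow,
                            int citer, double t0) {
  StressTangentField field(pars);
  // shift time origin for the forcing term: wrap as lambda-like adapter
  struct Shifted {
    const StressTangentField& f; double t0;
    Shifted(const StressTangentField& f_, double t0_) : f(f_), t0(t0_) {}
    inline void operator()(double t, const double* y, double* out) const {
      f(t + t0, y, out);
    }
  } sf(field, t0);
  return abm_drive(sf, 12, q, h, nsteps, y0, L, blow, citer);
}
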