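#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Saturating-mutualism Lotka-Volterra dynamics for a two-guild community,
// integrated with an adaptive embedded Dormand-Prince 5(4) scheme.
// Species whose abundance falls below ext_frac * initial are declared extinct
// and clamped to zero for the remainder of the run; integration stops when the
// largest per-capita growth rate among extant species drops below conv_tol
// (equilibrium reached) or at t_max.

struct Model {
  const NumericMatrix &betaP, &betaA, &gammaP, &gammaA;
  const NumericVector &alphaP, &alphaA;
  double hP, hA;
  int SP, SA;
  std::vector<bool> extinct;

  Model(const NumericMatrix &bP, const NumericMatrix &bA,
        const NumericMatrix &gP, const NumericMatrix &gA,
        const NumericVector &aP, const NumericVector &aA,
        double hP_, double hA_)
    : betaP(bP), betaA(bA), gammaP(gP), gammaA(gA),
      alphaP(aP), alphaA(aA), hP(hP_), hA(hA_),
      SP(bP.nrow()), SA(bA.nrow()), extinct(SP + SA, false) {}

  // per-capita growth rates into `per`, dy/dt into `dy`
  void rhs(const std::vector<double> &y, std::vector<double> &dy,
           std::vector<double> &per) {
    for (int i = 0; i < SP; ++i) {
      if (extinct[i]) { per[i] = 0.0; dy[i] = 0.0; continue; }
      double comp = 0.0, in = 0.0;
      for (int j = 0; j < SP; ++j) comp += betaP(i, j) * y[j];
      for (int k = 0; k < SA; ++k) in += gammaP(i, k) * y[SP + k];
      double mut = (hP > 0.0) ? in / (1.0 + hP * in) : in;
      per[i] = alphaP[i] - comp + mut;
      dy[i] = y[i] * per[i];
    }
    for (int k = 0; k < SA; ++k) {
      int idx = SP + k;
      if (extinct[idx]) { per[idx] = 0.0; dy[idx] = 0.0; continue; }
      double comp = 0.0, in = 0.0;
      for (int l = 0; l < SA; ++l) comp += betaA(k, l) * y[SP + l];
      for (int j = 0; j < SP; ++j) in += gammaA(k, j) * y[j];
      double mut = (hA > 0.0) ? in / (1.0 + hA * in) : in;
      per[idx] = alphaA[k] - comp + mut;
      dy[idx] = y[idx] * per[idx];
    }
  }
};

// [[Rcpp::export(name = ".integrate_community_cpp")]]
List integrate_community_cpp(NumericMatrix betaP, NumericMatrix betaA,
                             NumericMatrix gammaP, NumericMatrix gammaA,
                             NumericVector alphaP, NumericVector alphaA,
                             double hP, double hA, NumericVector n0,
                             double ext_frac = 1e-8, double conv_tol = 1e-6,
                             double t_max = 1e4, double rtol = 1e-8,
                             double atol = 1e-10, int max_steps = 2000000,
                             bool stop_on_extinction = false) {
  const int S = n0.size();
  Model mod(betaP, betaA, gammaP, gammaA, alphaP, alphaA, hP, hA);
  if (S != mod.SP + mod.SA) stop("state length does not match the matrices");

  // Dormand-Prince 5(4) tableau
  static const double
    a21 = 1.0/5,
    a31 = 3.0/40, a32 = 9.0/40,
    a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9,
    a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
    a54 = -212.0/729,
    a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
    a64 = 49.0/176, a65 = -5103.0/18656,
    b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
    b5 = -2187.0/6784, b6 = 11.0/84,
    e1 = 71.0/57600, e3 = -71.0/16695, e4 = 71.0/1920,
    e5 = -17253.0/339200, e6 = 22.0/525, e7 = -1.0/40;

  std::vector<double> y(n0.begin(), n0.end()), thr(S), ynew(S), per(S), ytmp(S);
  std::vector<std::vector<double>> k(7, std::vector<double>(S));
  for (int i = 0; i < S; ++i) {
    if (y[i] < 0) stop("initial abundances must be non-negative");
    thr[i] = ext_frac * y[i];
    if (y[i] == 0.0) mod.extinct[i] = true;
  }

  double t = 0.0, h = 1e-3;
  int steps = 0, clamped = 0;
  bool converged = false;
  mod.rhs(y, k[0], per);   // FSAL seed

  while (t < t_max && steps < max_steps) {
    if (h > t_max - t) h = t_max - t;

    for (int i = 0; i < S; ++i) ytmp[i] = y[i] + h * a21 * k[0][i];
    mod.rhs(ytmp, k[1], per);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a31 * k[0][i] + a32 * k[1][i]);
    mod.rhs(ytmp, k[2], per);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a41 * k[0][i] + a42 * k[1][i] + a43 * k[2][i]);
    mod.rhs(ytmp, k[3], per);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a51 * k[0][i] + a52 * k[1][i] + a53 * k[2][i] +
                            a54 * k[3][i]);
    mod.rhs(ytmp, k[4], per);
    for (int i = 0; i < S; ++i)
      ytmp[i] = y[i] + h * (a61 * k[0][i] + a62 * k[1][i] + a63 * k[2][i] +
                            a64 * k[3][i] + a65 * k[4][i]);
    mod.rhs(ytmp, k[5], per);
    for (int i = 0; i < S; ++i)
      ynew[i] = y[i] + h * (b1 * k[0][i] + b3 * k[2][i] + b4 * k[3][i] +
                            b5 * k[4][i] + b6 * k[5][i]);
    mod.rhs(ynew, k[6], per);

    double err = 0.0;
    for (int i = 0; i < S; ++i) {
      double ei = h * (e1 * k[0][i] + e3 * k[2][i] + e4 * k[3][i] +
                       e5 * k[4][i] + e6 * k[5][i] + e7 * k[6][i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      err += (ei / sc) * (ei / sc);
    }
    err = std::sqrt(err / S);
    ++steps;

    if (err <= 1.0) {                 // accept
      t += h;
      bool newly_extinct = false;
      for (int i = 0; i < S; ++i) {
        double v = ynew[i];
        if (!mod.extinct[i]) {
          if (v < 0.0) { ++clamped; v = 0.0; }
          if (v <= thr[i]) { v = 0.0; mod.extinct[i] = true; newly_extinct = true; }
        } else v = 0.0;
        y[i] = v;
      }
      if (newly_extinct) {
        if (stop_on_extinction) { converged = false; break; }
        mod.rhs(y, k[6], per);                   // refresh rates after clamp
      }
      k[0] = k[6];                               // FSAL: k7 is f(y)

      double worst = 0.0;
      for (int i = 0; i < S; ++i)
        if (!mod.extinct[i]) worst = std::max(worst, std::fabs(per[i]));
      if (worst < conv_tol) { converged = true; break; }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    h *= std::min(5.0, std::max(0.2, fac));
    if (h < 1e-14) stop("step size underflow in community integration");
  }

  LogicalVector extinct(S);
  NumericVector yout(S);
  for (int i = 0; i < S; ++i) { extinct[i] = mod.extinct[i]; yout[i] = y[i]; }
  return List::create(_["n"] = yout, _["extinct"] = extinct, _["t"] = t,
                      _["converged"] = converged, _["steps"] = steps,
                      _["clamped"] = clamped);
}
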