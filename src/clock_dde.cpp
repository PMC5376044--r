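// Method-of-steps integration of the five-gene delayed clock network.
//
// State order: 0 Bmal1, 1 Rev-erba, 2 Per2, 3 Cry1, 4 Dbp.
// Each equation reads dx/dt = d_x * (M_x(t) - x) where M_x is a product of
// E-box / D-box / RRE modulation factors evaluated on delayed species.
// Because every coupling is delayed (tau >= 4*dt enforced on the R side,
// or tau == 0 for the ODE limit), RK4 stage evaluations only ever look up
// history that is already on the grid; delayed values are interpolated with
// a 4-point cubic Lagrange stencil on the uniform grid.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct ClockPars {
  double d[5], tau[5];
  // theta layout (19): ar1, gr3, fE, fD,
  //   bR,aPR,aCR, bP,aPP,aCP, bC,aPC,aCC, bD,aPD,aCD, sR,sP,sC
  double ar1, gr3, fE, fD;
  double eb[4][3];   // rows: RevErba, Per2, Cry1, Dbp; cols: b, aP, aC
  double s[3];       // D-box strengths: RevErba, Per2, Cry1
  // site counts: rre on Bmal1, rre on Cry1, ebox on R/P/C/D, dbox on R/P/C
  int n_rre_B, n_rre_C, n_eb[4], n_db[3];
};

inline double rre_f(double x, double a, int n) {
  return std::pow(1.0 + a * x, -n);
}
inline double act_f(double xhat, double f, int n) {
  return std::pow((1.0 + f * xhat) / (1.0 + xhat), n);
}
inline double ebox_f(double B, double P, double C, const double* p,
                     double f, int n) {
  double Bh = p[0] * B / (1.0 + p[1] * P + p[2] * C);
  return act_f(Bh, f, n);
}

// cubic Lagrange interpolation of column j at fractional row u;
// rows 0..kmax are valid, u <= kmax guaranteed by the caller
double interp_col(const std::vector<double>& col, double u, int kmax,
                  double hist0) {
  if (u <= 0.0) return hist0;
  int i1 = (int)std::floor(u);
  if (i1 >= kmax) return col[kmax];
  double fr = u - i1;
  if (fr == 0.0) return col[i1];
  int i0 = i1 - 1, i2 = i1 + 1, i3 = i1 + 2;
  if (i0 < 0 || i3 > kmax) {   // linear fallback at the stencil edges
    return col[i1] * (1.0 - fr) + col[i2] * fr;
  }
  // Lagrange weights for nodes -1, 0, 1, 2 at offset fr
  double w0 = -fr * (fr - 1.0) * (fr - 2.0) / 6.0;
  double w1 = (fr + 1.0) * (fr - 1.0) * (fr - 2.0) / 2.0;
  double w2 = -(fr + 1.0) * fr * (fr - 2.0) / 2.0;
  double w3 = (fr + 1.0) * fr * (fr - 1.0) / 6.0;
  return w0 * col[i0] + w1 * col[i1] + w2 * col[i2] + w3 * col[i3];
}

// production terms M_x given delayed species lag[5]
void modulation(const double* lag, const ClockPars& P, double* M) {
  double B = lag[0], R = lag[1], Pp = lag[2], C = lag[3], D = lag[4];
  M[0] = rre_f(R, P.ar1, P.n_rre_B);
  M[1] = ebox_f(B, Pp, C, P.eb[0], P.fE, P.n_eb[0]) *
         act_f(P.s[0] * D, P.fD, P.n_db[0]);
  M[2] = ebox_f(B, Pp, C, P.eb[1], P.fE, P.n_eb[1]) *
         act_f(P.s[1] * D, P.fD, P.n_db[1]);
  M[3] = ebox_f(B, Pp, C, P.eb[2], P.fE, P.n_eb[2]) *
         act_f(P.s[2] * D, P.fD, P.n_db[2]) *
         rre_f(R, P.gr3, P.n_rre_C);
  M[4] = ebox_f(B, Pp, C, P.eb[3], P.fE, P.n_eb[3]);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix simulate_clock_cpp(NumericVector d, NumericVector tau,
                                 NumericVector theta, IntegerVector sites,
                                 NumericVector history0, double t_end,
                                 double dt) {
  if (d.size() != 5 || tau.size() != 5 || history0.size() != 5)
    stop("d, tau and history0 must have length 5");
  if (theta.size() != 19) stop("theta must have length 19");
  if (sites.size() != 9) stop("sites must have length 9");

  ClockPars P;
  for (int j = 0; j < 5; ++j) { P.d[j] = d[j]; P.tau[j] = tau[j]; }
  P.ar1 = theta[0]; P.gr3 = theta[1]; P.fE = theta[2]; P.fD = theta[3];
  for (int g = 0; g < 4; ++g)
    for (int c = 0; c < 3; ++c) P.eb[g][c] = theta[4 + 3 * g + c];
  for (int g = 0; g < 3; ++g) P.s[g] = theta[16 + g];
  P.n_rre_B = sites[0]; P.n_rre_C = sites[1];
  for (int g = 0; g < 4; ++g) P.n_eb[g] = sites[2 + g];
  for (int g = 0; g < 3; ++g) P.n_db[g] = sites[6 + g];

  int n = (int)std::llround(t_end / dt);
  std::vector<std::vector<double> > X(5, std::vector<double>(n + 1));
  for (int j = 0; j < 5; ++j) X[j][0] = history0[j];

  double y[5], ys[5], k1[5], k2[5], k3[5], k4[5], lag[5], M[5];
  for (int j = 0; j < 5; ++j) y[j] = history0[j];

  // delayed lookup at time ts for stage state ys (tau == 0: instantaneous)
  // k = index of last completed grid row
  for (int k = 0; k < n; ++k) {
    double t = k * dt;
    // four stages at t, t+dt/2, t+dt/2, t+dt
    const double cs[4] = {0.0, 0.5, 0.5, 1.0};
    double* ks[4] = {k1, k2, k3, k4};
    for (int s = 0; s < 4; ++s) {
      double ts = t + cs[s] * dt;
      if (s == 0) {
        for (int j = 0; j < 5; ++j) ys[j] = y[j];
      } else {
        double* kp = ks[s - 1];
        double h = cs[s] * dt;
        for (int j = 0; j < 5; ++j) ys[j] = y[j] + h * kp[j];
      }
      for (int j = 0; j < 5; ++j) {
        if (P.tau[j] == 0.0) {
          lag[j] = ys[j];
        } else {
          double u = (ts - P.tau[j]) / dt;
          lag[j] = interp_col(X[j], u, k, history0[j]);
        }
      }
      modulation(lag, P, M);
      for (int j = 0; j < 5; ++j) ks[s][j] = P.d[j] * (M[j] - ys[j]);
    }
    for (int j = 0; j < 5; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (y[j] < 0.0) {
        if (y[j] < -1e-8) stop("negative concentration beyond tolerance");
        y[j] = 0.0;
      }
      X[j][k + 1] = y[j];
    }
  }

  NumericMatrix out(n + 1, 5);
  for (int j = 0; j < 5; ++j)
    for (int i = 0; i <= n; ++i) out(i, j) = X[j][i];
  return out;
}
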