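#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of threshold-linear network dynamics
//   dx_i/dt = -x_i + [sum_j W_ij x_j + b_i]_+
// States are recorded every `thin` steps (plus the initial state).
// [[Rcpp::export]]
NumericMatrix tln_euler_cpp(NumericMatrix W, NumericVector b,
                            NumericVector x0, double T, double dt, int thin) {
  const int n = W.nrow();
  const int nsteps = (int)std::round(T / dt);
  const int nrec = nsteps / thin + 1;
  NumericMatrix out(nrec, n);
  std::vector<double> x(x0.begin(), x0.end()), xn(n);
  for (int j = 0; j < n; ++j) out(0, j) = x[j];
  int rec = 1;
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      double drive = b[i];
      for (int j = 0; j < n; ++j) drive += W(i, j) * x[j];
      if (drive < 0.0) drive = 0.0;
      xn[i] = x[i] + dt * (-x[i] + drive);
      if (!R_finite(xn[i]))
        stop("non-finite state at step %d (t = %g)", s, s * dt);
    }
    x = xn;
    if (s % thin == 0) {
      for (int j = 0; j < n; ++j) out(rec, j) = x[j];
      ++rec;
    }
  }
  return out;
}

// Euler integration of the delayed Wilson-Cowan rate model
//   tau dr_i/dt = -r_i + F(sum_j w_ij r_j(t - d_ij) + I_i)
// with F(x) = 1/(1+exp(-a(x-theta))) - 1/(1+exp(a*theta)).
// dsteps holds per-edge delays in integration steps; history before t = 0
// is clamped at r0. Records every `thin` steps.
// [[Rcpp::export]]
NumericMatrix wc_euler_cpp(NumericMatrix W, IntegerMatrix dsteps,
                           NumericVector Iext, double tau, double a,
                           double theta, NumericVector r0, double T,
                           double dt, int thin) {
  const int n = W.nrow();
  const int nsteps = (int)std::round(T / dt);
  const double Foff = 1.0 / (1.0 + std::exp(a * theta));
  int maxd = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (dsteps(i, j) > maxd) maxd = dsteps(i, j);
  const int H = maxd + 1;                 // ring buffer length
  std::vector<double> hist((size_t)H * n);
  for (int h = 0; h < H; ++h)
    for (int j = 0; j < n; ++j) hist[(size_t)h * n + j] = r0[j];
  const int nrec = nsteps / thin + 1;
  NumericMatrix out(nrec, n);
  for (int j = 0; j < n; ++j) out(0, j) = r0[j];
  int rec = 1;
  std::vector<double> x(r0.begin(), r0.end()), xn(n);
  for (int s = 1; s <= nsteps; ++s) {
    const int cur = s % H;                // slot to write state at step s
    for (int i = 0; i < n; ++i) {
      double drive = Iext[i];
      for (int j = 0; j < n; ++j) {
        if (W(i, j) == 0.0) continue;
        int back = dsteps(i, j);
        // state at step s-1-back (delayed presynaptic rate)
        int idx = (s - 1 - back) % H;
        if (idx < 0) idx += H;
        double rj = (s - 1 - back < 0) ? r0[j] : hist[(size_t)idx * n + j];
        drive += W(i, j) * rj;
      }
      double F = 1.0 / (1.0 + std::exp(-a * (drive - theta))) - Foff;
      xn[i] = x[i] + dt / tau * (-x[i] + F);
      if (!R_finite(xn[i]))
        stop("non-finite rate at step %d (t = %g)", s, s * dt);
    }
    x = xn;
    for (int j = 0; j < n; ++j) hist[(size_t)cur * n + j] = x[j];
    if (s % thin == 0) {
      for (int j = 0; j < n; ++j) out(rec, j) = x[j];
      ++rec;
    }
  }
  return out;
}
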