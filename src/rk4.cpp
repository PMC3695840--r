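#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classical fixed-step 4th-order Runge-Kutta for a mass-action network.
//
// The network is given generically: per-reaction rate constants `k`
// (stimulus dosage already folded in), 1-based substrate indices `sub1`,
// `sub2` (0 = absent, so zeroth-, first- and second-order fluxes are all
// k * prod(substrate concentrations)), and the stoichiometry matrix in
// triplet form (si = species, sj = reaction, sx = coefficient, with any
// compartment-volume factors folded into sx).
//
// States are clamped at zero before every flux evaluation; after each full
// step a value below -clamp_tol raises an integrity error, as does any
// non-finite value. The trajectory is sampled every `stride` steps
// (row 0 = initial state).
// [[Rcpp::export]]
NumericMatrix rk4_mass_action(NumericVector state0, NumericVector k,
                              IntegerVector sub1, IntegerVector sub2,
                              IntegerVector si, IntegerVector sj,
                              NumericVector sx,
                              double dt, int nsteps, int stride,
                              double clamp_tol) {
  const int ns = state0.size();
  const int nr = k.size();
  const int nt = si.size();
  if (dt <= 0.0) stop("dt must be > 0");
  if (stride < 1) stop("stride must be >= 1");

  std::vector<double> y(state0.begin(), state0.end());
  std::vector<double> yt(ns), d1(ns), d2(ns), d3(ns), d4(ns), v(nr);
  const int* p1 = INTEGER(sub1);
  const int* p2 = INTEGER(sub2);
  const int* pi = INTEGER(si);
  const int* pj = INTEGER(sj);
  const double* px = REAL(sx);
  const double* pk = REAL(k);

  const int nsamp = nsteps / stride;
  NumericMatrix out(nsamp + 1, ns);
  for (int i = 0; i < ns; ++i) out(0, i) = y[i];

  auto rhs = [&](std::vector<double>& yy, std::vector<double>& dy) {
    for (int i = 0; i < ns; ++i) if (yy[i] < 0.0) yy[i] = 0.0;
    for (int r = 0; r < nr; ++r) {
      double vv = pk[r];
      if (p1[r] > 0) vv *= yy[p1[r] - 1];
      if (p2[r] > 0) vv *= yy[p2[r] - 1];
      v[r] = vv;
    }
    std::fill(dy.begin(), dy.end(), 0.0);
    for (int t = 0; t < nt; ++t) dy[pi[t] - 1] += px[t] * v[pj[t] - 1];
  };

  int row = 1;
  for (int step = 1; step <= nsteps; ++step) {
    rhs(y, d1);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * d1[i];
    rhs(yt, d2);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * d2[i];
    rhs(yt, d3);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + dt * d3[i];
    rhs(yt, d4);
    for (int i = 0; i < ns; ++i) {
      y[i] += dt / 6.0 * (d1[i] + 2.0 * d2[i] + 2.0 * d3[i] + d4[i]);
      if (!std::isfinite(y[i])) {
        stop("integration diverged (non-finite value) at t = %f s, species index %d",
             step * dt, i + 1);
      }
      if (y[i] < 0.0) {
        if (y[i] < -clamp_tol) {
          stop("negative concentration beyond clamp tolerance at t = %f s, species index %d",
               step * dt, i + 1);
        }
        y[i] = 0.0;
      }
    }
    if (step % stride == 0 && row <= nsamp) {
      for (int i = 0; i < ns; ++i) out(row, i) = y[i];
      ++row;
    }
  }
  return out;
}
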