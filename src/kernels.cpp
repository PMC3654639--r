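// Compiled kernels for the membrane kinetics. The reaction system is stiff
// (notably the sinoatrial parameter set, whose excitation coefficient is
// nearly three orders of magnitude above the working-myocardium value), so
// the explicit RK4 updates are subcycled and run in C++.

#include <Rcpp.h>
using namespace Rcpp;

struct CellP {
  double a, b, c1, c2, d, e, k, A, B; // A, B in volts; k in 1/s
  bool san;
};

// Ionic current in model units (V/s under unit membrane scaling).
static inline double iion_c(double vm, double u, const CellP &p) {
  double w = vm - p.B;
  double v = w / p.A;
  double cur = p.k * p.c1 * w * (p.a - v) * (1.0 - v);
  cur += p.san ? p.k * p.c2 * u : p.k * p.c2 * u * w;
  return cur;
}

static inline double dudt_c(double vm, double u, const CellP &p) {
  double v = (vm - p.B) / p.A;
  return p.k * p.e * (v - p.d * u - p.b);
}

// One RK4 substep of the two-variable cell system; stim is an additive
// current (V/s) on dVm/dt, evaluated piecewise-constant over the substep.
static inline void rk4_cell(double &vm, double &u, double h, double stim,
                            const CellP &p) {
  double k1v = -iion_c(vm, u, p) + stim;
  double k1u = dudt_c(vm, u, p);
  double k2v = -iion_c(vm + 0.5 * h * k1v, u + 0.5 * h * k1u, p) + stim;
  double k2u = dudt_c(vm + 0.5 * h * k1v, u + 0.5 * h * k1u, p);
  double k3v = -iion_c(vm + 0.5 * h * k2v, u + 0.5 * h * k2u, p) + stim;
  double k3u = dudt_c(vm + 0.5 * h * k2v, u + 0.5 * h * k2u, p);
  double k4v = -iion_c(vm + h * k3v, u + h * k3u, p) + stim;
  double k4u = dudt_c(vm + h * k3v, u + h * k3u, p);
  vm += h / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
  u += h / 6.0 * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
}

// [[Rcpp::export]]
NumericMatrix cell_rk4(double a, double b, double c1, double c2, double d,
                       double e, double k, double A, double B, bool san,
                       double vm0, double u0, double duration, double dt_out,
                       int nsub, double stim_t0, double stim_dur,
                       double stim_amp) {
  CellP p{a, b, c1, c2, d, e, k, A, B, san};
  int nout = (int)std::floor(duration / dt_out + 1e-9) + 1;
  NumericMatrix out(nout, 3);
  double vm = vm0, u = u0, t = 0.0;
  double h = dt_out / nsub;
  out(0, 0) = 0.0; out(0, 1) = vm; out(0, 2) = u;
  for (int i = 1; i < nout; ++i) {
    for (int s = 0; s < nsub; ++s) {
      double stim = (stim_amp != 0.0 && t >= stim_t0 && t < stim_t0 + stim_dur)
                        ? stim_amp : 0.0;
      rk4_cell(vm, u, h, stim, p);
      t += h;
    }
    if (!std::isfinite(vm) || !std::isfinite(u))
      stop("cell integration diverged at t = %f s (Vm = %f, u = %f)", t, vm, u);
    out(i, 0) = i * dt_out;
    out(i, 1) = vm;
    out(i, 2) = u;
  }
  return out;
}

// Per-node reaction substep for the tissue solver: advances (Vm, u) at every
// heart node by dt using subcycled RK4. Parameter vectors are per node.
// [[Rcpp::export]]
List reaction_step(NumericVector vm, NumericVector u, double dt,
                   NumericVector a, NumericVector b, NumericVector c1,
                   NumericVector c2, NumericVector d, NumericVector e,
                   NumericVector k, NumericVector A, NumericVector B,
                   LogicalVector san, IntegerVector nsub) {
  int n = vm.size();
  NumericVector vmo = clone(vm), uo = clone(u);
  for (int i = 0; i < n; ++i) {
    if (k[i] == 0.0) continue; // infarcted node: kinetics switched off
    CellP p{a[i], b[i], c1[i], c2[i], d[i], e[i], k[i], A[i], B[i],
            (bool)san[i]};
    double v = vmo[i], uu = uo[i];
    int ns = nsub[i];
    double h = dt / ns;
    for (int s = 0; s < ns; ++s) rk4_cell(v, uu, h, 0.0, p);
    if (!std::isfinite(v) || !std::isfinite(uu))
      stop("reaction step diverged at node %d (Vm = %f)", i + 1, v);
    vmo[i] = v;
    uo[i] = uu;
  }
  return List::create(_["vm"] = vmo, _["u"] = uo);
}
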