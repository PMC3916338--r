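#include <Rcpp.h>
using namespace Rcpp;

// Explicit-midpoint (RK2) integration of the 8 slow receptor currents, with
// the four population rates re-resolved algebraically at every stage.
//
// Population order: 0 = 5-HT, 1 = GABA(DRN), 2 = Ox, 3 = GABA(LHA).
// Dynamic connection order (the ODE state):
//   0 5HT_auto, 1 Ox_to_5HT, 2 5HT_to_GABA_DRN, 3 Ox_to_GABA_DRN,
//   4 Ox_auto, 5 5HT_to_Ox, 6 Ox_to_GABA_LHA, 7 5HT_to_GABA_LHA.
// Instantaneous GABA_A synapses:
//   0 GABA_DRN_to_5HT, 1 GABA_DRN_self, 2 GABA_LHA_to_Ox, 3 GABA_LHA_self.

static const int SRC[8] = {0, 2, 0, 2, 2, 0, 2, 0};

struct Circuit {
  double g[4], I0[4], Ibg[4], Jd[8], tau[8], sgn[8], Ji[4];
};

// Resolve the algebraic rate system for a given slow-current state.
// GABA populations obey f = g*[X - Jself*f - I0]_+ whose unique solution is
// f = g*(X - I0)/(1 + g*Jself) on the active branch and 0 below threshold;
// the principal populations then follow from the threshold-linear transfer.
static inline void solve_rates(const Circuit &c, const double *I,
                               double stimS, double stimO,
                               double *f, double *drive) {
  const double XD = c.Ibg[1] + c.sgn[2] * I[2] + c.sgn[3] * I[3];
  const double fD = (XD > c.I0[1])
    ? c.g[1] * (XD - c.I0[1]) / (1.0 + c.g[1] * c.Ji[1]) : 0.0;
  const double XL = c.Ibg[3] + c.sgn[6] * I[6] + c.sgn[7] * I[7];
  const double fL = (XL > c.I0[3])
    ? c.g[3] * (XL - c.I0[3]) / (1.0 + c.g[3] * c.Ji[3]) : 0.0;
  const double IS = c.Ibg[0] + c.sgn[0] * I[0] + c.sgn[1] * I[1]
    - c.Ji[0] * fD + stimS;
  const double IO = c.Ibg[2] + c.sgn[4] * I[4] + c.sgn[5] * I[5]
    - c.Ji[2] * fL + stimO;
  f[0] = (IS > c.I0[0]) ? c.g[0] * (IS - c.I0[0]) : 0.0;
  f[1] = fD;
  f[2] = (IO > c.I0[2]) ? c.g[2] * (IO - c.I0[2]) : 0.0;
  f[3] = fL;
  if (drive) {
    drive[0] = IS;
    drive[1] = XD - c.Ji[1] * fD;
    drive[2] = IO;
    drive[3] = XL - c.Ji[3] * fL;
  }
}

static inline void derivs(const Circuit &c, const double *I, double t,
                          double aS, double aO, double onset, double dur,
                          double *dI) {
  const bool on = (t >= onset) && (t < onset + dur);
  double f[4];
  solve_rates(c, I, on ? aS : 0.0, on ? aO : 0.0, f, 0);
  for (int k = 0; k < 8; ++k)
    dI[k] = (-I[k] + c.Jd[k] * f[SRC[k]]) / c.tau[k];
}

// [[Rcpp::export]]
NumericMatrix rk2_integrate_cpp(NumericVector init,
                                NumericVector g, NumericVector I0,
                                NumericVector Ibg, NumericVector Jdyn,
                                NumericVector tau, NumericVector sgn,
                                NumericVector Jinst,
                                double stimS, double stimO,
                                double onset, double duration,
                                double horizon, double dt, int thin) {
  Circuit c;
  for (int i = 0; i < 4; ++i) {
    c.g[i] = g[i]; c.I0[i] = I0[i]; c.Ibg[i] = Ibg[i]; c.Ji[i] = Jinst[i];
  }
  for (int k = 0; k < 8; ++k) {
    c.Jd[k] = Jdyn[k]; c.tau[k] = tau[k]; c.sgn[k] = sgn[k];
  }
  const long nstep = (long)(horizon / dt + 0.5);
  const long nrec = nstep / thin + 1 + ((nstep % thin) ? 1 : 0);
  NumericMatrix out(nrec, 17);

  double I[8], Imid[8], k1[8], k2[8], f[4], drive[4];
  for (int k = 0; k < 8; ++k) I[k] = init[k];

  long row = 0;
  for (long n = 0; n <= nstep; ++n) {
    const double t = n * dt;
    if (n % thin == 0 || n == nstep) {
      const bool on = (t >= onset) && (t < onset + duration);
      solve_rates(c, I, on ? stimS : 0.0, on ? stimO : 0.0, f, drive);
      if (!R_finite(f[0]) || !R_finite(f[2]))
        stop("non-finite state at t = %g s (parameter pathology?)", t);
      out(row, 0) = t;
      for (int i = 0; i < 4; ++i) { out(row, 1 + i) = f[i]; out(row, 5 + i) = drive[i]; }
      for (int k = 0; k < 8; ++k) out(row, 9 + k) = I[k];
      ++row;
    }
    if (n == nstep) break;
    derivs(c, I, t, stimS, stimO, onset, duration, k1);
    for (int k = 0; k < 8; ++k) Imid[k] = I[k] + 0.5 * dt * k1[k];
    derivs(c, Imid, t + 0.5 * dt, stimS, stimO, onset, duration, k2);
    for (int k = 0; k < 8; ++k) I[k] += dt * k2[k];
  }
  return out;
}
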