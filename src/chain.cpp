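#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integrator for the 1D mechanochemical cell chain.
//
// State: junction positions x[0..N] (x[0] fixed), per-cell ERK activity
// E[0..N-1] and contractile force F[0..N-1]. Per step, all derivatives are
// evaluated on the current state and applied simultaneously:
//   eta_c * xdot_i = elastic_i + F_{cell i}          (interior junctions)
//   eta_E * Edot_j = tanh(alpha * eps_j) - E_j       (coupled regime)
//   eta_F * Fdot_j = lam * E_j - F_j
// In the uncoupled regime E is prescribed as a retrograde traveling wave
// evaluated at cell centers and is not integrated.
//
// elastic orientation 0 ("conventional"): k * (eps_i - eps_{i-1})
// elastic orientation 1 ("printed"):      k * (eps_i - eps_{i+1}), eps_{N+1}=0
// tip boundary 0 ("kinematic"): xdot_N = F_tip / eta_c
// tip boundary 1 ("force"):     xdot_N = (-k * eps_{N-1} + F_tip) / eta_c

// [[Rcpp::export(name = ".chain_run_cpp")]]
List chain_run_cpp(NumericVector x0, NumericVector E0, NumericVector F0,
                   double t0, double eta_c, double k, double L, double F_tip,
                   double alpha, double eta_E, double eta_F, double lam,
                   double dt, long n_steps, long record_every,
                   long discard_steps, int uncoupled, double w, double v,
                   int elastic_printed, int tip_force, int record_x) {
  const int N = E0.size();
  if (x0.size() != N + 1) stop("x0 must have length N + 1");
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> E(E0.begin(), E0.end());
  std::vector<double> F(F0.begin(), F0.end());
  std::vector<double> eps(N), xdot(N + 1), Edot(N), Fdot(N);

  long nrec = 0;
  if (n_steps >= discard_steps)
    nrec = (n_steps - discard_steps) / record_every + 1;
  NumericMatrix rec_eps(nrec, N), rec_E(nrec, N), rec_F(nrec, N);
  NumericMatrix rec_xm(record_x ? nrec : 0, record_x ? (N + 1) : 0);
  NumericVector rec_t(nrec);

  double t = t0;
  long irec = 0;
  for (long s = 0; s <= n_steps; ++s) {
    for (int j = 0; j < N; ++j) eps[j] = (x[j + 1] - x[j]) / L - 1.0;
    if (uncoupled) {
      for (int j = 0; j < N; ++j) {
        double X = 0.5 * (x[j] + x[j + 1]);
        E[j] = 0.5 * (std::sin(M_PI * (X + v * t) / w) + 1.0);
      }
    }
    if (s >= discard_steps && ((s - discard_steps) % record_every) == 0 &&
        irec < nrec) {
      rec_t[irec] = t;
      for (int j = 0; j < N; ++j) {
        rec_eps(irec, j) = eps[j];
        rec_E(irec, j) = E[j];
        rec_F(irec, j) = F[j];
      }
      if (record_x) for (int i = 0; i <= N; ++i) rec_xm(irec, i) = x[i];
      ++irec;
    }
    if (s == n_steps) break;

    xdot[0] = 0.0;
    for (int i = 1; i < N; ++i) {
      double el = elastic_printed
                      ? k * (eps[i] - (i + 1 < N ? eps[i + 1] : 0.0))
                      : k * (eps[i] - eps[i - 1]);
      xdot[i] = (el + F[i]) / eta_c;
    }
    xdot[N] = tip_force ? (-k * eps[N - 1] + F_tip) / eta_c : F_tip / eta_c;
    if (!uncoupled)
      for (int j = 0; j < N; ++j)
        Edot[j] = (std::tanh(alpha * eps[j]) - E[j]) / eta_E;
    for (int j = 0; j < N; ++j) Fdot[j] = (lam * E[j] - F[j]) / eta_F;

    for (int i = 0; i <= N; ++i) x[i] += dt * xdot[i];
    if (!uncoupled) for (int j = 0; j < N; ++j) E[j] += dt * Edot[j];
    for (int j = 0; j < N; ++j) F[j] += dt * Fdot[j];
    t = t0 + (s + 1) * dt;

    for (int i = 0; i < N; ++i)
      if (!(x[i + 1] > x[i]))
        stop("chain integration unstable: junction order violated at t = %f",
             t);
  }

  List out = List::create(
      _["t"] = rec_t, _["eps"] = rec_eps, _["E"] = rec_E, _["F"] = rec_F,
      _["x_final"] = NumericVector(x.begin(), x.end()),
      _["E_final"] = NumericVector(E.begin(), E.end()),
      _["F_final"] = NumericVector(F.begin(), F.end()), _["t_final"] = t);
  if (record_x) out["x"] = rec_xm;
  return out;
}
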