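#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the cohort-line prevalence ODE:
//   dp/da = (1 - p) * [ i - m * p (R - 1) / (1 + p (R - 1)) ]
// The bracket is incidence minus general mortality times the population
// attributable fraction.
static inline double prev_rhs(double p, double i, double m, double R) {
  double r1 = R - 1.0;
  double denom = 1.0 + p * r1;
  return (1.0 - p) * (i - m * p * r1 / denom);
}

// Fixed-step classical RK4 for the prevalence ODE. The rate vectors are the
// rates evaluated at half-step resolution: ages a0, a0 + h/2, a0 + h, ...
// (length 2 * nstep + 1). Returns p at the nstep + 1 full-grid nodes,
// starting from p = 0 at the first node.
// [[Rcpp::export]]
NumericVector rk4_prevalence_cpp(NumericVector inc, NumericVector mort,
                                 NumericVector relmort, double step,
                                 double p0) {
  const int npts = inc.size();
  if (npts < 3 || npts % 2 == 0 || mort.size() != npts || relmort.size() != npts)
    stop("rate vectors must share an odd length >= 3 (half-step resolution)");
  const int nstep = (npts - 1) / 2;
  NumericVector p(nstep + 1);
  p[0] = p0;
  for (int s = 0; s < nstep; ++s) {
    const int j0 = 2 * s, jm = 2 * s + 1, j1 = 2 * s + 2;
    const double y = p[s];
    const double k1 = prev_rhs(y, inc[j0], mort[j0], relmort[j0]);
    const double k2 = prev_rhs(y + 0.5 * step * k1, inc[jm], mort[jm], relmort[jm]);
    const double k3 = prev_rhs(y + 0.5 * step * k2, inc[jm], mort[jm], relmort[jm]);
    const double k4 = prev_rhs(y + step * k3, inc[j1], mort[j1], relmort[j1]);
    double yn = y + step / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    // floating-point dust is clamped; real violations abort
    if (yn < 0.0) {
      if (yn > -1e-12) yn = 0.0;
      else stop("prevalence fell below 0 (%.3e) at step %d (step size %.3g)", yn, s + 1, step);
    }
    if (yn > 1.0) {
      if (yn < 1.0 + 1e-12) yn = 1.0;
      else stop("prevalence exceeded 1 (%.6f) at step %d (step size %.3g)", yn, s + 1, step);
    }
    p[s + 1] = yn;
  }
  return p;
}

// Discrete-time individual-level illness-death cohort simulation.
// Rates are evaluated at the start age of each time step (length = number of
// steps). Within a step a healthy subject draws disease onset with
// probability 1 - exp(-i dt) and death with probability 1 - exp(-m0 dt)
// independently; if both fire, the tie is broken by competing-risk
// splitting with P(onset) = i / (i + m0). A diseased subject dies with
// probability 1 - exp(-m1 dt). Event times are recorded at the end of the
// step. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List simulate_cohort_cpp(NumericVector i_rate, NumericVector m0_rate,
                         NumericVector m1_rate, int n_subjects, double dt) {
  const int nstep = i_rate.size();
  if (m0_rate.size() != nstep || m1_rate.size() != nstep)
    stop("rate vectors must share one length (one value per time step)");
  if (n_subjects < 1) stop("need at least one subject");
  if (dt <= 0) stop("'dt' must be positive");

  std::vector<double> p_on(nstep), p_d0(nstep), p_d1(nstep), split(nstep);
  for (int k = 0; k < nstep; ++k) {
    p_on[k] = 1.0 - std::exp(-i_rate[k] * dt);
    p_d0[k] = 1.0 - std::exp(-m0_rate[k] * dt);
    p_d1[k] = 1.0 - std::exp(-m1_rate[k] * dt);
    const double tot = i_rate[k] + m0_rate[k];
    split[k] = tot > 0.0 ? i_rate[k] / tot : 0.0;
  }

  NumericVector onset(n_subjects, NA_REAL), death(n_subjects, NA_REAL);
  for (int s = 0; s < n_subjects; ++s) {
    int state = 0;  // 0 healthy, 1 diseased
    for (int k = 0; k < nstep; ++k) {
      if (state == 0) {
        bool on = unif_rand() < p_on[k];
        bool die = unif_rand() < p_d0[k];
        if (on && die) {
          if (unif_rand() < split[k]) die = false; else on = false;
        }
        if (die) { death[s] = (k + 1) * dt; break; }
        if (on)  { onset[s] = (k + 1) * dt; state = 1; }
      } else {
        if (unif_rand() < p_d1[k]) { death[s] = (k + 1) * dt; break; }
      }
    }
  }
  return List::create(_["onset_age"] = onset, _["death_age"] = death);
}
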