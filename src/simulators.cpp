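#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA for the colonization/birth/death scheme on V gut sites.
// Propensities: a_col = c*(V-N), a_birth = b*N*(V-N)/V, a_death = d*N.
// The birth scaling by E/V makes the large-V limit coincide with the
// mean-field ODE dphi/dt = (1-phi)(b*phi + c) - d*phi.

// [[Rcpp::export]]
IntegerVector gillespie_sample_cpp(double b, double c, double d, int V,
                                   int N0, NumericVector times,
                                   double max_events) {
  int nt = times.size();
  IntegerVector out(nt);
  double t = 0.0, events = 0.0;
  int N = N0, k = 0;
  while (k < nt) {
    double a1 = c * (double)(V - N);
    double a2 = b * (double)N * (double)(V - N) / (double)V;
    double a3 = d * (double)N;
    double a0 = a1 + a2 + a3;
    double tnext = (a0 > 0.0) ? t + R::exp_rand() / a0 : R_PosInf;
    while (k < nt && times[k] < tnext) { out[k] = N; ++k; }
    if (k >= nt || !R_finite(tnext)) {
      while (k < nt) { out[k] = N; ++k; }
      break;
    }
    t = tnext;
    double u = R::unif_rand() * a0;
    if (u < a1 + a2) N += 1; else N -= 1;
    if (++events > max_events)
      stop("Gillespie event cap exceeded (%.0f events); raise max_events or shorten t_end",
           max_events);
  }
  return out;
}

// Full event history; counts recorded after each event, starting at t = 0.
// [[Rcpp::export]]
List gillespie_events_cpp(double b, double c, double d, int V,
                          int N0, double t_end, double max_events) {
  std::vector<double> ev_t;
  std::vector<int> ev_n;
  ev_t.push_back(0.0);
  ev_n.push_back(N0);
  double t = 0.0, events = 0.0;
  int N = N0;
  for (;;) {
    double a1 = c * (double)(V - N);
    double a2 = b * (double)N * (double)(V - N) / (double)V;
    double a3 = d * (double)N;
    double a0 = a1 + a2 + a3;
    if (a0 <= 0.0) break;
    t += R::exp_rand() / a0;
    if (t > t_end) break;
    double u = R::unif_rand() * a0;
    if (u < a1 + a2) N += 1; else N -= 1;
    ev_t.push_back(t);
    ev_n.push_back(N);
    if (++events > max_events)
      stop("Gillespie event cap exceeded (%.0f events); raise max_events or shorten t_end",
           max_events);
  }
  return List::create(_["event_times"] = wrap(ev_t), _["counts"] = wrap(ev_n));
}

// Euler-Maruyama for the two-state switching SDE on log-load phi:
//   dphi = r_s * phi * (C_s - phi) dt + sqrt(2 D_s dt) xi
// (noise autocovariance 2 D delta, so the stationary density is exp(-U/D))
// State flips per step with probability alpha*dt (bernoulli mode) or
// 1 - exp(-alpha*dt) (exact per-step waiting-time marginal).
// reflect: reflect phi at 0 so log-load stays physical.
// [[Rcpp::export]]
List sim_switching_cpp(double r_low, double C_low, double D_low,
                       double r_high, double C_high, double D_high,
                       double alpha_h, double alpha_l,
                       double phi0, int s0, double t_end, double dt,
                       int record_every, bool exact_flip, bool reflect) {
  int nsteps = (int)std::ceil(t_end / dt);
  int nrec = nsteps / record_every + 1;
  NumericVector t_out(nrec), phi_out(nrec);
  IntegerVector s_out(nrec);
  double phi = phi0;
  int s = s0;  // 0 = low, 1 = high
  t_out[0] = 0.0; phi_out[0] = phi; s_out[0] = s;
  int j = 1;
  double p_hl = exact_flip ? 1.0 - std::exp(-alpha_l * dt) : alpha_l * dt;
  double p_lh = exact_flip ? 1.0 - std::exp(-alpha_h * dt) : alpha_h * dt;
  for (int i = 1; i <= nsteps; ++i) {
    double pflip = (s == 1) ? p_hl : p_lh;
    if (pflip > 0.0 && R::unif_rand() < pflip) s = 1 - s;
    double r = s ? r_high : r_low;
    double C = s ? C_high : C_low;
    double D = s ? D_high : D_low;
    phi += r * phi * (C - phi) * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();
    if (reflect && phi < 0.0) phi = -phi;
    if (i % record_every == 0 && j < nrec) {
      t_out[j] = i * dt; phi_out[j] = phi; s_out[j] = s; ++j;
    }
  }
  if (j < nrec) {
    t_out = head(t_out, j); phi_out = head(phi_out, j); s_out = head(s_out, j);
  }
  return List::create(_["time_h"] = t_out, _["phi"] = phi_out, _["state"] = s_out);
}

static inline double polyval(const NumericVector& coef, double x) {
  // coefficients ascending: coef[0] + coef[1]*x + ...
  double y = 0.0;
  for (int i = coef.size() - 1; i >= 0; --i) y = y * x + coef[i];
  return y;
}

// Overdamped Langevin dphi = -U'(phi) dt + sqrt(2 D dt) xi.
// dU holds ascending coefficients of U'(phi).
// [[Rcpp::export]]
List sim_potential_cpp(NumericVector dU, double D, double phi0,
                       double t_end, double dt, int record_every,
                       double guard_lo, double guard_hi) {
  int nsteps = (int)std::ceil(t_end / dt);
  int nrec = nsteps / record_every + 1;
  NumericVector t_out(nrec), phi_out(nrec);
  double phi = phi0;
  t_out[0] = 0.0; phi_out[0] = phi;
  int j = 1;
  for (int i = 1; i <= nsteps; ++i) {
    phi += -polyval(dU, phi) * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();
    if (phi < guard_lo || phi > guard_hi)
      stop("Langevin trajectory left the working support (phi = %g at t = %g); "
           "the potential may be non-confining at this noise level", phi, i * dt);
    if (i % record_every == 0 && j < nrec) {
      t_out[j] = i * dt; phi_out[j] = phi; ++j;
    }
  }
  if (j < nrec) { t_out = head(t_out, j); phi_out = head(phi_out, j); }
  return List::create(_["time_h"] = t_out, _["phi"] = phi_out);
}

// First-passage time from phi0 to the absorbing level `target`
// (crossing from above if phi0 > target, from below otherwise).
// Returns NA_real_ if not reached by t_max.
// [[Rcpp::export]]
double first_passage_cpp(NumericVector dU, double D, double phi0,
                         double target, double dt, double t_max) {
  double phi = phi0, t = 0.0;
  bool from_above = phi0 > target;
  while (t < t_max) {
    phi += -polyval(dU, phi) * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();
    t += dt;
    if (from_above ? (phi <= target) : (phi >= target)) return t;
  }
  return NA_REAL;
}
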