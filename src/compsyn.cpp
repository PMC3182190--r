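#include <Rcpp.h>
using namespace Rcpp;

// Cubic drift polynomial c0 + c1*x + c2*x^2 + c3*x^3. Coefficients are
// extracted in R from the enumeration-built drift (exact for a cubic), so the
// compiled integrators stay consistent with the single source of truth.
static inline double poly3(const double* c, double x) {
  return c[0] + x * (c[1] + x * (c[2] + x * c[3]));
}

// [[Rcpp::export]]
List cpp_euler_integrate(NumericVector coef, double x0, double dt,
                         int n_steps, int record_every) {
  if (coef.size() != 4) stop("coef must have length 4");
  const double c[4] = {coef[0], coef[1], coef[2], coef[3]};
  int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 2;
  std::vector<double> ts, xs;
  ts.reserve(n_rec + 1);
  xs.reserve(n_rec + 1);
  double x = x0;
  ts.push_back(0.0);
  xs.push_back(x);
  bool unstable = false;
  for (int i = 1; i <= n_steps; ++i) {
    x += dt * poly3(c, x);
    if (x < -1e-12 || x > 1.0 + 1e-12) { unstable = true; break; }
    // clamp roundoff at the boundaries
    if (x < 0.0) x = 0.0;
    if (x > 1.0) x = 1.0;
    if ((record_every > 0 && i % record_every == 0) || i == n_steps) {
      ts.push_back(i * dt);
      xs.push_back(x);
    }
  }
  return List::create(_["t"] = ts, _["x"] = xs, _["unstable"] = unstable);
}

// Integrate to saturation: stop when the fractional change of x per unit
// time drops below tol. Optionally record the trajectory and the first
// (linearly interpolated) crossing of cross_level.
// [[Rcpp::export]]
List cpp_euler_saturate(NumericVector coef, double x0, double dt, double tol,
                        double max_time, int record_every, double cross_level,
                        bool relative) {
  if (coef.size() != 4) stop("coef must have length 4");
  const double c[4] = {coef[0], coef[1], coef[2], coef[3]};
  const double eps = 1e-9;
  const bool track_cross = R_finite(cross_level);
  const long max_steps = (long)std::ceil(max_time / dt);
  std::vector<double> ts, xs;
  ts.push_back(0.0);
  xs.push_back(x0);
  double x = x0, t_cross = NA_REAL;
  bool degenerate = false, converged = false, unstable = false;
  long i = 0;
  if (track_cross && x0 == cross_level) t_cross = 0.0;
  while (i < max_steps) {
    double x_new = x + dt * poly3(c, x);
    ++i;
    if (x_new < -1e-12 || x_new > 1.0 + 1e-12) { unstable = true; break; }
    if (x_new < 0.0) x_new = 0.0;
    if (x_new > 1.0) x_new = 1.0;
    if (track_cross && !R_finite(t_cross)) {
      double a = x - cross_level, b = x_new - cross_level;
      if (a == 0.0) {
        t_cross = (i - 1) * dt;
      } else if ((a > 0.0) != (b > 0.0)) {
        t_cross = (i - 1) * dt + dt * a / (a - b);
      }
    }
    double frac = std::fabs(x_new - x) / dt;
    if (relative) frac /= std::max(std::fabs(x), eps);
    x = x_new;
    if ((record_every > 0 && i % record_every == 0)) {
      ts.push_back(i * dt);
      xs.push_back(x);
    }
    if (frac < tol) {
      converged = true;
      if (i == 1) degenerate = true;
      break;
    }
  }
  double t_sat = i * dt;
  if (ts.back() != t_sat) { ts.push_back(t_sat); xs.push_back(x); }
  if (degenerate) t_sat = 0.0;
  return List::create(_["t_sat"] = t_sat, _["x_end"] = x,
                      _["t"] = ts, _["x"] = xs, _["t_cross"] = t_cross,
                      _["degenerate"] = degenerate,
                      _["converged"] = converged, _["unstable"] = unstable);
}

// Random-sequential Monte-Carlo sweeps over the periodic chain of binary
// synapses. state: 1 = strong, 0 = weak. Each update draws a site, then the
// activations of the two flanking neurons; each neuron fires with probability
// alpha (beta) when its *other* adjacent synapse is strong (weak). The
// candidate synapse is ignored in both activations. Uses R's RNG so that
// set.seed() makes runs reproducible. Three uniforms are drawn per update in
// a fixed order (site, left neuron, right neuron), matching the R reference
// implementation update by update.
// [[Rcpp::export]]
List cpp_run_sweeps(IntegerVector state0, double alpha, double beta,
                    int n_sweeps, int record_every) {
  const int n = state0.size();
  std::vector<int> st(state0.begin(), state0.end());
  long n_strong = 0;
  for (int k = 0; k < n; ++k) n_strong += st[k];
  std::vector<double> sweeps, frac;
  sweeps.reserve(n_sweeps / std::max(record_every, 1) + 2);
  frac.reserve(sweeps.capacity());
  sweeps.push_back(0.0);
  frac.push_back((double)n_strong / n);
  bool absorbed = (n_strong == 0 || n_strong == n);
  RNGScope scope;
  for (int sw = 1; sw <= n_sweeps; ++sw) {
    if (!absorbed) {
      for (int u = 0; u < n; ++u) {
        int i = (int)(unif_rand() * n);
        if (i == n) i = n - 1;
        double u_l = unif_rand();
        double u_r = unif_rand();
        int lt = st[(i - 1 + n) % n];
        int rt = st[(i + 1) % n];
        if (lt == rt) continue;  // same-type neighbours: zero/unpolarized
        bool fire_l = u_l < (lt ? alpha : beta);
        bool fire_r = u_r < (rt ? alpha : beta);
        if (fire_l == fire_r) continue;  // both or neither: unpolarized
        // exactly one fires: potentiate if it is the strong-adjacent neuron
        int fired_type = fire_l ? lt : rt;
        int new_state = fired_type ? 1 : 0;
        if (new_state != st[i]) {
          n_strong += new_state - st[i];
          st[i] = new_state;
        }
      }
      if (n_strong == 0 || n_strong == n) absorbed = true;
    }
    if ((record_every > 0 && sw % record_every == 0) || sw == n_sweeps) {
      sweeps.push_back((double)sw);
      frac.push_back((double)n_strong / n);
    }
  }
  return List::create(_["sweep"] = sweeps, _["strong_fraction"] = frac,
                      _["state"] = IntegerVector(st.begin(), st.end()),
                      _["absorbed"] = absorbed);
}
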