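#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Potential encodings (beta*U, dimensionless):
//   kind 0: flat
//   kind 1: harmonic            par = (stiffness k, center c)        0.5*k*(x-c)^2
//   kind 2: double_barrier      par = (p1, h1, p2, h2, depth, width)
//           two Gaussian barriers of height h at p with sd = width, plus a
//           logistic bound well of given depth centred at p1 - 2*width
//   kind 3: tabulated           par = (n, x[1..n], y[1..n]), linear interp,
//           flat (clamped) outside the knot range

static inline double pot_energy(const int kind, const double* p, const double x) {
  switch (kind) {
  case 0: return 0.0;
  case 1: { const double d = x - p[1]; return 0.5 * p[0] * d * d; }
  case 2: {
    const double w = p[5], w2 = w * w;
    const double d1 = x - p[0], d2 = x - p[2];
    const double c = p[0] - 2.0 * w;
    const double s = 1.0 / (1.0 + std::exp((x - c) / w));
    return p[1] * std::exp(-0.5 * d1 * d1 / w2)
         + p[3] * std::exp(-0.5 * d2 * d2 / w2)
         - p[4] * s;
  }
  case 3: {
    const int n = (int) p[0];
    const double* xs = p + 1;
    const double* ys = p + 1 + n;
    if (x <= xs[0]) return ys[0];
    if (x >= xs[n - 1]) return ys[n - 1];
    int i = 0;
    while (x > xs[i + 1]) ++i;
    const double t = (x - xs[i]) / (xs[i + 1] - xs[i]);
    return ys[i] + t * (ys[i + 1] - ys[i]);
  }
  }
  return 0.0;
}

// d(beta U)/dx
static inline double pot_grad(const int kind, const double* p, const double x) {
  switch (kind) {
  case 0: return 0.0;
  case 1: return p[0] * (x - p[1]);
  case 2: {
    const double w = p[5], w2 = w * w;
    const double d1 = x - p[0], d2 = x - p[2];
    const double c = p[0] - 2.0 * w;
    const double e = std::exp((x - c) / w);
    const double s = 1.0 / (1.0 + e);
    return -p[1] * d1 / w2 * std::exp(-0.5 * d1 * d1 / w2)
           -p[3] * d2 / w2 * std::exp(-0.5 * d2 * d2 / w2)
           + p[4] * s * (1.0 - s) / w;
  }
  case 3: {
    const int n = (int) p[0];
    const double* xs = p + 1;
    const double* ys = p + 1 + n;
    if (x <= xs[0] || x >= xs[n - 1]) return 0.0;
    int i = 0;
    while (x > xs[i + 1]) ++i;
    return (ys[i + 1] - ys[i]) / (xs[i + 1] - xs[i]);
  }
  }
  return 0.0;
}

// [[Rcpp::export]]
NumericVector pot_energy_cpp(int kind, NumericVector par, NumericVector x) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pot_energy(kind, par.begin(), x[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector pot_grad_cpp(int kind, NumericVector par, NumericVector x) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pot_grad(kind, par.begin(), x[i]);
  return out;
}

// P(the continuous path bridging x -> xp within one step of variance 2*D*dt
// touched the boundary b), both endpoints on the same side of b: the
// standard Brownian-bridge crossing probability exp(-(b-x)(b-xp)/(D*dt)).
static inline double bridge_touch_prob(double b, double x, double xp,
                                       double Ddt) {
  const double e = (b - x) * (b - xp) / Ddt;
  return (e > 36.0) ? 0.0 : std::exp(-e);
}

// Overdamped Euler-Maruyama confined to [lo, hi) by position reflection.
// A proposed step that leaves the interval is one collision with the crossed
// boundary (at most one event per step, attributed to the first boundary
// crossed); time of the collision is the end of the offending step. Steps
// that stay inside may still have touched a boundary mid-step: such touches
// are recovered stochastically with the Brownian-bridge crossing
// probability, removing the O(sqrt(dt)) undercount of collision statistics.
// The lower wall of the innermost cell (lo = 0) is reflective but is not a
// milestone, so touches there are not recorded.
// [[Rcpp::export]]
List bd_confined_cpp(double lo, double hi, bool lower_is_milestone,
                     double x0, double n_steps, double dt, double D,
                     int pot_kind, NumericVector pot_par) {
  RNGScope scope;
  const double* pp = pot_par.begin();
  const double sig = std::sqrt(2.0 * D * dt);
  const double Ddt = D * dt;
  std::vector<double> ev_t;
  std::vector<int> ev_b;  // 0 = lower boundary, 1 = upper boundary
  double x = x0, xmin = x0, xmax = x0;
  const long long N = (long long) n_steps;
  for (long long k = 0; k < N; ++k) {
    const double g = pot_grad(pot_kind, pp, x);
    if (!std::isfinite(g))
      stop("non-finite force at cv = %f", x);
    double xp = x - D * dt * g + sig * norm_rand();
    bool recorded = false;
    int guard = 0;
    while ((xp < lo || xp >= hi) && guard++ < 64) {
      if (xp >= hi) {
        if (!recorded) { ev_t.push_back((k + 1) * dt); ev_b.push_back(1); recorded = true; }
        xp = 2.0 * hi - xp;
      } else {
        if (!recorded && lower_is_milestone) {
          ev_t.push_back((k + 1) * dt); ev_b.push_back(0); recorded = true;
        }
        xp = 2.0 * lo - xp;
      }
    }
    if (xp < lo || xp >= hi) xp = 0.5 * (lo + hi);  // pathological dt only
    if (!recorded) {
      // mid-step touches without boundary crossing (endpoints inside)
      const double p_hi = bridge_touch_prob(hi, x, xp, Ddt);
      const double p_lo = lower_is_milestone ?
        bridge_touch_prob(lo, x, xp, Ddt) : 0.0;
      if (p_hi > 0.0 || p_lo > 0.0) {
        const bool hit_hi = p_hi > 0.0 && unif_rand() < p_hi;
        const bool hit_lo = p_lo > 0.0 && unif_rand() < p_lo;
        if (hit_hi && (!hit_lo || hi - xp <= xp - lo)) {
          ev_t.push_back((k + 1) * dt); ev_b.push_back(1);
        } else if (hit_lo) {
          ev_t.push_back((k + 1) * dt); ev_b.push_back(0);
        }
      }
    }
    x = xp;
    if (x < xmin) xmin = x;
    if (x > xmax) xmax = x;
  }
  return List::create(_["times"] = wrap(ev_t), _["boundary"] = wrap(ev_b),
                      _["cv_min"] = xmin, _["cv_max"] = xmax, _["cv_final"] = x);
}

// First passage from start to absorb_at with a reflecting wall at reflect_at.
// Absorption is checked at the end of each step, including mid-step hits via
// the Brownian-bridge crossing probability; returns NA for samples that
// exceed max_steps.
// [[Rcpp::export]]
NumericVector bd_fpt_cpp(double start, double reflect_at, double absorb_at,
                         double dt, double D, int pot_kind, NumericVector pot_par,
                         int n_samples, double max_steps) {
  RNGScope scope;
  const double* pp = pot_par.begin();
  const double sig = std::sqrt(2.0 * D * dt);
  const long long S = (long long) max_steps;
  NumericVector out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    if (start >= absorb_at) { out[s] = 0.0; continue; }
    double x = start;
    double t = NA_REAL;
    for (long long k = 0; k < S; ++k) {
      const double g = pot_grad(pot_kind, pp, x);
      if (!std::isfinite(g)) stop("non-finite force at cv = %f", x);
      const double xprev = x;
      x += -D * dt * g + sig * norm_rand();
      if (x >= absorb_at) { t = (k + 1) * dt; break; }
      if (x < reflect_at) x = 2.0 * reflect_at - x;
      if (unif_rand() < bridge_touch_prob(absorb_at, xprev, x, D * dt)) {
        t = (k + 1) * dt; break;
      }
    }
    out[s] = t;
    if (s % 16 == 0) checkUserInterrupt();
  }
  return out;
}

// Exact Gillespie simulation of a continuous-time Markov jump process with
// generator Q (off-diagonal rates, rows sum to zero). Stops early on
// absorption (a state with zero exit rate).
// [[Rcpp::export]]
List gillespie_cpp(NumericMatrix Q, int start, double total_jumps) {
  RNGScope scope;
  const int n = Q.nrow();
  const long long J = (long long) total_jumps;
  std::vector<int> states;
  std::vector<double> hold;
  states.reserve((size_t) J + 1);
  hold.reserve((size_t) J);
  int s = start;
  bool absorbed = false;
  states.push_back(s);
  for (long long j = 0; j < J; ++j) {
    const double rate = -Q(s, s);
    if (rate <= 0.0) { absorbed = true; break; }
    hold.push_back(exp_rand() / rate);
    const double u = unif_rand() * rate;
    double acc = 0.0;
    int tgt = -1;
    for (int k = 0; k < n; ++k) {
      if (k == s) continue;
      acc += Q(s, k);
      if (u <= acc) { tgt = k; break; }
    }
    if (tgt < 0) {  // numerical slack: take the last state with positive rate
      for (int k = n - 1; k >= 0; --k)
        if (k != s && Q(s, k) > 0.0) { tgt = k; break; }
    }
    s = tgt;
    states.push_back(s);
  }
  return List::create(_["states"] = wrap(states), _["holding"] = wrap(hold),
                      _["absorbed"] = absorbed);
}

// Steered pulling stand-in: BD under the cell potential plus a harmonic
// restraint whose centre moves linearly from c_start to c_end; records the
// first position observed inside each cell. Cell k is [m_{k-1}, m_k) with
// m_{-1} = 0; positions at or beyond the outermost milestone are ignored.
// [[Rcpp::export]]
NumericVector smd_cpp(NumericVector milestones, double x0, double c_start,
                      double c_end, double k_restraint, double n_steps,
                      double dt, double D, int pot_kind, NumericVector pot_par) {
  RNGScope scope;
  const double* pp = pot_par.begin();
  const int M = milestones.size();
  const double sig = std::sqrt(2.0 * D * dt);
  const double outer = milestones[M - 1];
  NumericVector starts(M, NA_REAL);
  const long long N = (long long) n_steps;
  double x = x0;
  {
    int cell = 0;
    while (cell < M && x >= milestones[cell]) ++cell;
    if (cell < M) starts[cell] = x;
  }
  for (long long k = 0; k < N; ++k) {
    const double c = c_start + (c_end - c_start) * ((double)(k + 1) / (double) N);
    const double g = pot_grad(pot_kind, pp, x) + k_restraint * (x - c);
    if (!std::isfinite(g)) stop("non-finite force at cv = %f", x);
    x += -D * dt * g + sig * norm_rand();
    if (x < 0.0) x = -x;
    if (x < outer) {
      int cell = 0;
      while (cell < M && x >= milestones[cell]) ++cell;
      if (cell < M && NumericVector::is_na(starts[cell])) starts[cell] = x;
    }
  }
  return starts;
}
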