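#include <Rcpp.h>
using namespace Rcpp;

// Mass-action propensity of reaction j given state x.
// Conventions: order 0 -> k; A -> k*x[A]; A+B -> k*x[A]*x[B];
// 2A -> k*x[A]*(x[A]-1)/2 (combinatorial pair count).
static inline double propensity(const double k, const int i1, const int i2,
                                const bool same, const NumericVector &x) {
  if (i1 < 0) return k;
  if (i2 < 0) return k * x[i1];
  if (same) return k * x[i1] * (x[i1] - 1.0) / 2.0;
  return k * x[i1] * x[i2];
}

// Exact stochastic simulation (Gillespie direct method).
// S: ns x nr net stoichiometry; i1,i2: 0-based reactant indices (-1 = none);
// same: logical, both reactant slots are the same species (2A);
// k: effective rate constants; x0: initial counts (integers as doubles);
// grid: recording times (seconds), grid[0] is the start time.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix ssa_exact_cpp(const IntegerMatrix S, const IntegerVector i1,
                            const IntegerVector i2, const LogicalVector same,
                            const NumericVector k, const NumericVector x0,
                            const NumericVector grid, const double max_events) {
  const int ns = S.nrow(), nr = S.ncol(), ng = grid.size();
  NumericVector x = clone(x0);
  NumericMatrix out(ng, ns);
  double t = grid[0];
  int g = 0;
  // record initial state
  for (int s = 0; s < ns; ++s) out(0, s) = x[s];
  g = 1;
  double events = 0.0;
  RNGScope scope;
  while (g < ng) {
    double a0 = 0.0;
    static thread_local std::vector<double> a;
    a.assign(nr, 0.0);
    for (int j = 0; j < nr; ++j) {
      a[j] = propensity(k[j], i1[j], i2[j], same[j], x);
      if (a[j] < 0) a[j] = 0;
      a0 += a[j];
    }
    double dt = (a0 > 0) ? -std::log(unif_rand()) / a0 : R_PosInf;
    double tnext = t + dt;
    while (g < ng && grid[g] <= tnext) {      // record state before the jump
      for (int s = 0; s < ns; ++s) out(g, s) = x[s];
      ++g;
    }
    if (g >= ng || !R_FINITE(tnext)) break;
    t = tnext;
    double u = unif_rand() * a0, cum = 0.0;
    int j = nr - 1;
    for (int jj = 0; jj < nr; ++jj) {
      cum += a[jj];
      if (u <= cum) { j = jj; break; }
    }
    for (int s = 0; s < ns; ++s) x[s] += S(s, j);
    if (++events > max_events)
      stop("SSA event budget exceeded (%g events); use tau-leaping for this regime",
           max_events);
  }
  return out;
}

// Tau-leaping approximation with fixed leap tau (seconds).
// Poisson firing counts per channel per leap; species are clamped at zero
// (negative excursions are truncated, appropriate at the large copy
// numbers this path is intended for).
// [[Rcpp::export]]
NumericMatrix ssa_tau_cpp(const IntegerMatrix S, const IntegerVector i1,
                          const IntegerVector i2, const LogicalVector same,
                          const NumericVector k, const NumericVector x0,
                          const NumericVector grid, const double tau) {
  const int ns = S.nrow(), nr = S.ncol(), ng = grid.size();
  NumericVector x = clone(x0);
  NumericMatrix out(ng, ns);
  for (int s = 0; s < ns; ++s) out(0, s) = x[s];
  double t = grid[0];
  RNGScope scope;
  std::vector<double> fire(nr);
  for (int g = 1; g < ng; ++g) {
    while (t < grid[g]) {
      double step = std::min(tau, grid[g] - t);
      // standard leap: all propensities at the leap start, then update
      for (int j = 0; j < nr; ++j) {
        double aj = propensity(k[j], i1[j], i2[j], same[j], x);
        fire[j] = (aj > 0) ? R::rpois(aj * step) : 0.0;
      }
      for (int j = 0; j < nr; ++j) {
        double n = fire[j];
        if (n <= 0) continue;
        // cap firings by current reactant availability so an over-drawn
        // channel cannot create mass (a clamp alone would consume the
        // reactants but still credit the products)
        if (i1[j] >= 0) {
          double cap = same[j] ? std::floor(x[i1[j]] / 2.0) : x[i1[j]];
          if (i2[j] >= 0 && !same[j]) cap = std::min(cap, x[i2[j]]);
          if (n > cap) n = cap;
        }
        if (n > 0)
          for (int s = 0; s < ns; ++s) x[s] += n * S(s, j);
      }
      for (int s = 0; s < ns; ++s) if (x[s] < 0) x[s] = 0;
      t += step;
    }
    for (int s = 0; s < ns; ++s) out(g, s) = x[s];
  }
  return out;
}
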