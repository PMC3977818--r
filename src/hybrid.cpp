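#include <Rcpp.h>
#include <R_ext/Lapack.h>
using namespace Rcpp;

// Hybrid stochastic/deterministic core: gene-switching channels fire as a
// jump process with the integrated-hazard construction; all other species
// follow the deterministic mass-action flow. The flow is stiff (nuclear
// import/capture cycles relax on sub-second scales while expression evolves
// over hours), so it is integrated with a fixed-step backward-Euler method
// (L-stable) using the analytic mass-action Jacobian and LAPACK dense
// solves; the integrated gene hazard is accumulated by the trapezoid rule
// and a unit-exponential threshold crossing is located by shortening the
// step onto the crossing.

struct Part {
  const IntegerMatrix S;
  const IntegerVector i1, i2;
  const LogicalVector same;
  const NumericVector k;
  std::vector< std::vector< std::pair<int, int> > > sp;  // sparse columns
  Part(IntegerMatrix S_, IntegerVector i1_, IntegerVector i2_,
       LogicalVector same_, NumericVector k_)
    : S(S_), i1(i1_), i2(i2_), same(same_), k(k_) {
    sp.resize(S.ncol());
    for (int j = 0; j < S.ncol(); ++j)
      for (int s = 0; s < S.nrow(); ++s)
        if (S(s, j) != 0) sp[j].push_back(std::make_pair(s, S(s, j)));
  }
};

static inline double prop1(const Part &p, int j, const std::vector<double> &x) {
  const int a = p.i1[j], b = p.i2[j];
  if (a < 0) return p.k[j];
  double xa = x[a] > 0 ? x[a] : 0;
  if (b < 0) return p.k[j] * xa;
  if (p.same[j]) return p.k[j] * xa * (xa > 1 ? xa - 1 : 0) / 2.0;
  double xb = x[b] > 0 ? x[b] : 0;
  return p.k[j] * xa * xb;
}

static void flow(const Part &det, const std::vector<double> &x,
                 std::vector<double> &dx) {
  std::fill(dx.begin(), dx.end(), 0.0);
  for (int j = 0; j < det.S.ncol(); ++j) {
    double v = prop1(det, j, x);
    if (v == 0) continue;
    for (size_t q = 0; q < det.sp[j].size(); ++q)
      dx[det.sp[j][q].first] += det.sp[j][q].second * v;
  }
}

static double hazard(const Part &gene, const std::vector<double> &x) {
  double h = 0.0;
  for (int j = 0; j < gene.S.ncol(); ++j) h += prop1(gene, j, x);
  return h;
}

// dense mass-action Jacobian of the deterministic flow (ns x ns, col-major)
static void jacobian(const Part &det, const std::vector<double> &x,
                     std::vector<double> &J, int ns) {
  std::fill(J.begin(), J.end(), 0.0);
  for (int j = 0; j < det.S.ncol(); ++j) {
    const int a = det.i1[j], b = det.i2[j];
    if (a < 0) continue;
    double da = 0, db = 0;
    if (b < 0) { da = det.k[j]; }
    else if (det.same[j]) {
      double xa = x[a] > 0 ? x[a] : 0;
      da = det.k[j] * (xa - 0.5);
      if (da < 0) da = 0;
    } else {
      double xa = x[a] > 0 ? x[a] : 0, xb = x[b] > 0 ? x[b] : 0;
      da = det.k[j] * xb; db = det.k[j] * xa;
    }
    for (size_t q = 0; q < det.sp[j].size(); ++q) {
      const int s = det.sp[j][q].first, st = det.sp[j][q].second;
      J[a * ns + s] += st * da;
      if (b >= 0 && !det.same[j]) J[b * ns + s] += st * db;
      else if (det.same[j]) J[a * ns + s] += 0;  // handled in da
    }
  }
}

// one backward-Euler step of size h from x into xn; returns false if the
// Newton iteration failed to converge
static bool be_step(const Part &det, const std::vector<double> &x, double h,
                    std::vector<double> &xn, std::vector<double> &J,
                    std::vector<double> &A, std::vector<int> &ipiv,
                    std::vector<double> &f, std::vector<double> &rhs,
                    int ns) {
  xn = x;
  for (int it = 0; it < 8; ++it) {
    flow(det, xn, f);
    double rmax = 0.0;
    for (int s = 0; s < ns; ++s) {
      rhs[s] = x[s] + h * f[s] - xn[s];
      double sc = 1.0 + std::fabs(xn[s]);
      rmax = std::max(rmax, std::fabs(rhs[s]) / sc);
    }
    if (rmax < 1e-10) return true;
    jacobian(det, xn, J, ns);
    // A = I - h J
    for (int c = 0; c < ns; ++c)
      for (int r = 0; r < ns; ++r)
        A[c * ns + r] = (r == c ? 1.0 : 0.0) - h * J[c * ns + r];
    int n = ns, nrhs = 1, info = 0;
    F77_CALL(dgesv)(&n, &nrhs, A.data(), &n, ipiv.data(), rhs.data(), &n,
                    &info);
    if (info != 0) return false;
    double step_rel = 0.0;
    for (int s = 0; s < ns; ++s) {
      xn[s] += rhs[s];
      if (xn[s] < 0) xn[s] = 0;
      step_rel = std::max(step_rel,
                          std::fabs(rhs[s]) / (1.0 + std::fabs(xn[s])));
    }
    if (step_rel < 1e-8) return true;
  }
  return false;
}

// [[Rcpp::export]]
NumericMatrix hybrid_cpp(const IntegerMatrix Sd, const IntegerVector i1d,
                         const IntegerVector i2d, const LogicalVector samed,
                         const NumericVector kd, const IntegerMatrix Sg,
                         const IntegerVector i1g, const IntegerVector i2g,
                         const LogicalVector sameg, const NumericVector kg,
                         const NumericVector x0, const NumericVector grid,
                         const double h_max) {
  const Part det(Sd, i1d, i2d, samed, kd);
  const Part gene(Sg, i1g, i2g, sameg, kg);
  const int ns = Sd.nrow(), ng = grid.size(), nrg = Sg.ncol();

  std::vector<double> x(x0.begin(), x0.end()), xn(ns), f(ns), rhs(ns);
  std::vector<double> J(ns * ns), A(ns * ns);
  std::vector<int> ipiv(ns);
  NumericMatrix out(ng, ns);
  for (int s = 0; s < ns; ++s) out(0, s) = x[s];

  RNGScope scope;
  double E = exp_rand(), L = 0.0;
  double t = grid[0];
  const double h_min = 1e-6;

  for (int g = 1; g < ng; ++g) {
    const double t_target = grid[g];
    while (t < t_target - 1e-9) {
      double h = std::min(h_max, t_target - t);
      double hz0 = hazard(gene, x);
      bool ok = false;
      double Lh = L;
      for (int tries = 0; tries < 60; ++tries) {
        if (!be_step(det, x, h, xn, J, A, ipiv, f, rhs, ns)) {
          h /= 2;
          if (h < h_min) stop("hybrid implicit step failed at t=%g", t);
          continue;
        }
        double hz1 = hazard(gene, xn);
        Lh = L + h * 0.5 * (hz0 + hz1);
        if (Lh >= E && h > h_min) {
          double frac = (E - L) / (Lh - L);
          double hnew = h * std::min(0.95, std::max(0.02, frac));
          if (hnew > h_min) { h = hnew; continue; }
        }
        ok = true;
        break;
      }
      if (!ok) stop("hybrid stepper failed to take a step at t=%g", t);
      x = xn;
      t += h;
      L = Lh;
      if (L >= E) {
        double a0 = 0.0;
        std::vector<double> a(nrg);
        for (int j = 0; j < nrg; ++j) { a[j] = prop1(gene, j, x); a0 += a[j]; }
        if (a0 > 0) {
          double u = unif_rand() * a0, cum = 0.0;
          int jf = nrg - 1;
          for (int j = 0; j < nrg; ++j) {
            cum += a[j];
            if (u <= cum) { jf = j; break; }
          }
          for (int s = 0; s < ns; ++s) {
            x[s] += Sg(s, jf);
            if (x[s] < 0) x[s] = 0;
          }
        }
        L = 0.0;
        E = exp_rand();
      }
    }
    for (int s = 0; s < ns; ++s) out(g, s) = x[s];
  }
  return out;
}
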