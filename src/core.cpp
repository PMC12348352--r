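// Core numerics: nearest-point projection of torsion-angle points onto a
// densely discretized path, free-energy evaluation F = profile(s*) +
// 0.5*kt*d^2, central finite-difference gradients, restrained overdamped
// Langevin propagation of umbrella windows, and steepest-descent basin
// labeling on a periodic grid.
//
// Conventions: coordinates in degrees. Path nodes live in a continuous
// (unwrapped) chart; the displacement of an arbitrary point from a path node
// is taken along the shortest arc per component, so evaluation is exactly
// 360-periodic in both coordinates.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

static inline double wrapd(double x) { // reduce to [-180, 180)
  const double y = (x + 180.0) / 360.0;
  return x - 360.0 * std::floor(y);
  // x - 360*floor((x+180)/360) lies in [-180, 180)
}

struct PathRef {
  const double* px;
  const double* py;
  const double* prof;
  const double* dprof; // dF/dt per segment-local t, at the nodes
  int n;               // number of nodes; n-1 segments
};

struct Proj {
  double F;   // free energy at the point
  double s;   // path parameter in [0,1]
  double d2;  // squared perpendicular distance, deg^2
  int seg;    // winning segment index
  double gx;  // analytic gradient of F at the point (deg units)
  double gy;
};

// Project (x, y) onto segments [lo, hi) of the path; the nearest point
// wins. The along-path profile is interpolated by a cubic Hermite within
// the segment (values and derivatives at the nodes), which reproduces the
// R-side C^1 profile exactly because the dense nodes subdivide its cubic
// pieces.
static inline Proj project_range(const PathRef& P, double x, double y,
                                 int lo, int hi, double kt) {
  Proj out;
  double best = 1e300;
  double best_t = 0.0;
  int best_seg = lo;
  for (int i = lo; i < hi; ++i) {
    const double ax = P.px[i], ay = P.py[i];
    const double abx = P.px[i + 1] - ax, aby = P.py[i + 1] - ay;
    const double dx = wrapd(x - ax), dy = wrapd(y - ay);
    const double ab2 = abx * abx + aby * aby;
    double t = (dx * abx + dy * aby) / ab2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    const double ex = dx - t * abx, ey = dy - t * aby;
    const double d2 = ex * ex + ey * ey;
    if (d2 < best) { best = d2; best_t = t; best_seg = i; }
  }
  const double t = best_t, u = 1.0 - t;
  const double h00 = (1.0 + 2.0 * t) * u * u;
  const double h10 = t * u * u;
  const double h01 = t * t * (3.0 - 2.0 * t);
  const double h11 = t * t * (t - 1.0);
  const double fpath = h00 * P.prof[best_seg] + h10 * P.dprof[best_seg] +
                       h01 * P.prof[best_seg + 1] +
                       h11 * P.dprof[best_seg + 1];
  out.F = fpath + 0.5 * kt * best;
  out.s = (best_seg + best_t) / (P.n - 1);
  out.d2 = best;
  out.seg = best_seg;
  // analytic gradient of the winning branch: along-segment chain rule for
  // the profile term (zero when the projection is clamped at a segment
  // end), plus kt * perpendicular displacement
  {
    const double ax = P.px[best_seg], ay = P.py[best_seg];
    const double abx = P.px[best_seg + 1] - ax, aby = P.py[best_seg + 1] - ay;
    const double ab2 = abx * abx + aby * aby;
    const double dx = wrapd(x - ax), dy = wrapd(y - ay);
    const double ex = dx - t * abx, ey = dy - t * aby;
    double dfdt = 0.0;
    if (t > 0.0 && t < 1.0) {
      const double d00 = 6.0 * t * (t - 1.0);
      const double d10 = (1.0 - t) * (1.0 - 3.0 * t);
      const double d01 = -d00;
      const double d11 = t * (3.0 * t - 2.0);
      dfdt = d00 * P.prof[best_seg] + d10 * P.dprof[best_seg] +
             d01 * P.prof[best_seg + 1] + d11 * P.dprof[best_seg + 1];
    }
    out.gx = dfdt * abx / ab2 + kt * ex;
    out.gy = dfdt * aby / ab2 + kt * ey;
  }
  return out;
}

static inline PathRef make_ref(const NumericMatrix& path,
                               const NumericVector& prof,
                               const NumericVector& dprof) {
  if (path.nrow() != prof.size() || path.nrow() != dprof.size() ||
      path.nrow() < 2)
    stop("path nodes and profile values must align (>= 2 nodes)");
  PathRef P;
  P.px = &path(0, 0);
  P.py = &path(0, 1);
  P.prof = &prof[0];
  P.dprof = &dprof[0];
  P.n = path.nrow();
  return P;
}

// [[Rcpp::export(name = ".fe_eval_cpp")]]
NumericVector fe_eval_cpp(NumericMatrix points, NumericMatrix path,
                          NumericVector prof, NumericVector dprof,
                          double kt) {
  PathRef P = make_ref(path, prof, dprof);
  const int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = project_range(P, points(i, 0), points(i, 1), 0, P.n - 1, kt).F;
  return out;
}

// [[Rcpp::export(name = ".fe_detail_cpp")]]
DataFrame fe_detail_cpp(NumericMatrix points, NumericMatrix path,
                        NumericVector prof, NumericVector dprof, double kt) {
  PathRef P = make_ref(path, prof, dprof);
  const int n = points.nrow();
  NumericVector F(n), s(n), d(n);
  for (int i = 0; i < n; ++i) {
    Proj p = project_range(P, points(i, 0), points(i, 1), 0, P.n - 1, kt);
    F[i] = p.F; s[i] = p.s; d[i] = std::sqrt(p.d2);
  }
  return DataFrame::create(_["F"] = F, _["s"] = s, _["d"] = d);
}

// Central finite differences with step h (degrees).
// [[Rcpp::export(name = ".fe_grad_cpp")]]
NumericMatrix fe_grad_cpp(NumericMatrix points, NumericMatrix path,
                          NumericVector prof, NumericVector dprof,
                          double kt, double h) {
  PathRef P = make_ref(path, prof, dprof);
  const int n = points.nrow();
  const int hi = P.n - 1;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const double x = points(i, 0), y = points(i, 1);
    out(i, 0) = (project_range(P, x + h, y, 0, hi, kt).F -
                 project_range(P, x - h, y, 0, hi, kt).F) / (2.0 * h);
    out(i, 1) = (project_range(P, x, y + h, 0, hi, kt).F -
                 project_range(P, x, y - h, 0, hi, kt).F) / (2.0 * h);
  }
  return out;
}

// --- RNG: mt19937_64 + Box-Muller (implementation-independent normals) ---
struct Gauss {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() { // (0, 1)
    const double u = ((eng() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
    return u;
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Restrained overdamped Langevin propagation of several umbrella windows
// sharing one landscape and one RNG stream, using the Leimkuhler-Matthews
// update (Euler drift with the average of consecutive Gaussian increments),
// whose stationary distribution is second-order accurate in dt for
// Brownian dynamics. All quantities in degree units (kappa_deg in
// kJ/mol/deg^2, mob_deg in deg^2 per kJ/mol per time unit). The gradient of
// the projected free energy is analytic within the winning segment and is
// evaluated against a warm-started local window of path segments
// (re-anchored by a full projection every `refresh` steps).
// [[Rcpp::export(name = ".run_windows_cpp")]]
List run_windows_cpp(NumericMatrix centers, NumericMatrix path,
                     NumericVector prof, NumericVector dprof, double kt,
                     double kappa_deg, double RT, double mob_deg, double dt,
                     int nprod, int nburn, double seed,
                     int thin, bool keep_traj,
                     int refresh, int halfwin) {
  PathRef P = make_ref(path, prof, dprof);
  const int W = centers.nrow();
  const int nseg = P.n - 1;
  if (nprod < 1) stop("need at least one production step");
  Gauss rng(static_cast<uint64_t>(seed));

  std::vector<double> zx(W), zy(W);
  std::vector<int> hint(W);
  for (int w = 0; w < W; ++w) {
    zx[w] = centers(w, 0); zy[w] = centers(w, 1);
    hint[w] = project_range(P, zx[w], zy[w], 0, nseg, kt).seg;
  }

  std::vector<double> sx(W, 0.0), sy(W, 0.0), sxx(W, 0.0), syy(W, 0.0),
      sxy(W, 0.0);
  const double sigma = std::sqrt(2.0 * RT * mob_deg * dt);
  std::vector<double> nx_prev(W), ny_prev(W);
  for (int w = 0; w < W; ++w) { nx_prev[w] = rng.norm(); ny_prev[w] = rng.norm(); }
  const int ntot = nburn + nprod;
  int nkept = 0;
  NumericMatrix traj;
  if (keep_traj) {
    if (thin < 1) stop("thin must be >= 1");
    nkept = (nprod + thin - 1) / thin;
    traj = NumericMatrix(nkept, 2 * W);
  }

  for (int step = 0; step < ntot; ++step) {
    const bool full = (step % refresh) == 0;
    for (int w = 0; w < W; ++w) {
      int lo = 0, hi = nseg;
      if (!full) {
        lo = hint[w] - halfwin; if (lo < 0) lo = 0;
        hi = hint[w] + halfwin; if (hi > nseg) hi = nseg;
      }
      Proj base = project_range(P, zx[w], zy[w], lo, hi, kt);
      hint[w] = base.seg;
      const double gx = base.gx, gy = base.gy;
      // Leimkuhler-Matthews update: Euler drift with the average of the
      // current and previous Gaussian increments. The averaged noise gives
      // second-order accuracy of the stationary distribution for Brownian
      // dynamics at no extra force evaluations.
      const double nx_new = rng.norm(), ny_new = rng.norm();
      const double fx = gx + kappa_deg * (zx[w] - centers(w, 0));
      const double fy = gy + kappa_deg * (zy[w] - centers(w, 1));
      zx[w] += -dt * mob_deg * fx + sigma * 0.5 * (nx_prev[w] + nx_new);
      zy[w] += -dt * mob_deg * fy + sigma * 0.5 * (ny_prev[w] + ny_new);
      nx_prev[w] = nx_new; ny_prev[w] = ny_new;
      if (!std::isfinite(zx[w]) || !std::isfinite(zy[w]))
        stop("non-finite state in window %d at step %d", w + 1, step + 1);
      if (step >= nburn) {
        const double ux = zx[w] - centers(w, 0);
        const double uy = zy[w] - centers(w, 1);
        sx[w] += ux; sy[w] += uy;
        sxx[w] += ux * ux; syy[w] += uy * uy; sxy[w] += ux * uy;
        if (keep_traj && ((step - nburn) % thin) == 0) {
          const int row = (step - nburn) / thin;
          if (row < nkept) {
            traj(row, 2 * w) = zx[w];
            traj(row, 2 * w + 1) = zy[w];
          }
        }
      }
    }
  }

  NumericMatrix mean_op(W, 2), cov(W, 4);
  const double N = static_cast<double>(nprod);
  for (int w = 0; w < W; ++w) {
    const double mx = sx[w] / N, my = sy[w] / N;
    mean_op(w, 0) = centers(w, 0) + mx;
    mean_op(w, 1) = centers(w, 1) + my;
    cov(w, 0) = sxx[w] / N - mx * mx;
    cov(w, 1) = sxy[w] / N - mx * my;
    cov(w, 2) = cov(w, 1);
    cov(w, 3) = syy[w] / N - my * my;
  }
  List out = List::create(_["mean_op"] = mean_op, _["cov"] = cov,
                          _["n_kept"] = nprod);
  if (keep_traj) out["traj"] = traj;
  return out;
}

// Steepest-descent basin labeling on a periodic grid: each cell points to
// its lowest 8-neighbor (itself if it is a local minimum); labels are the
// roots of the resulting forest.
// [[Rcpp::export(name = ".basin_labels_cpp")]]
IntegerMatrix basin_labels_cpp(NumericMatrix F) {
  const int nr = F.nrow(), nc = F.ncol();
  std::vector<int> parent(nr * nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = F(i, j);
      int bi = i, bj = j;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = (i + di + nr) % nr;
          const int jj = (j + dj + nc) % nc;
          if (F(ii, jj) < best) { best = F(ii, jj); bi = ii; bj = jj; }
        }
      }
      parent[i + nr * j] = bi + nr * bj;
    }
  }
  // path-compress
  IntegerMatrix lab(nr, nc);
  for (int k = 0; k < nr * nc; ++k) {
    int r = k;
    while (parent[r] != r) r = parent[r];
    int q = k;
    while (parent[q] != q) { int nx = parent[q]; parent[q] = r; q = nx; }
    lab[k] = r + 1; // 1-based root id
  }
  return lab;
}
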