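#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Thomas algorithm; overwrites r with the solution.
static void thomas(std::vector<double> &a, std::vector<double> &b,
                   std::vector<double> &c, std::vector<double> &r, int n) {
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    r[i] -= w * r[i - 1];
  }
  r[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    r[i] = (r[i] - c[i] * r[i + 1]) / b[i];
}

// One diffusion-decay step on a cell-centred 2D grid (rows = x, cols = y).
// Dimension splitting: implicit tridiagonal solve along x, then along y,
// then exact exponential decay. Non-Dirichlet edges are zero-flux; voxels
// with dmask true are held at dval (identity rows in the solves), which
// gives the exact discrete steady state of the pinned problem.
// [[Rcpp::export]]
NumericMatrix diffusion_step_cpp(NumericMatrix u, double D, double decay,
                                 double dt, double h, LogicalMatrix dmask,
                                 NumericMatrix dval) {
  int nx = u.nrow(), ny = u.ncol();
  NumericMatrix out = clone(u);
  double nu = D * dt / (h * h);
  int nmax = std::max(nx, ny);
  std::vector<double> a(nmax), b(nmax), c(nmax), r(nmax);

  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (dmask(i, j)) out(i, j) = dval(i, j);

  // x sweep
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (dmask(i, j)) {
        a[i] = 0.0; b[i] = 1.0; c[i] = 0.0; r[i] = dval(i, j);
        continue;
      }
      double lo = (i > 0) ? nu : 0.0;
      double hi = (i < nx - 1) ? nu : 0.0;
      a[i] = -lo; c[i] = -hi; b[i] = 1.0 + lo + hi; r[i] = out(i, j);
    }
    thomas(a, b, c, r, nx);
    for (int i = 0; i < nx; ++i) out(i, j) = r[i];
  }

  // y sweep
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      if (dmask(i, j)) {
        a[j] = 0.0; b[j] = 1.0; c[j] = 0.0; r[j] = dval(i, j);
        continue;
      }
      double lo = (j > 0) ? nu : 0.0;
      double hi = (j < ny - 1) ? nu : 0.0;
      a[j] = -lo; c[j] = -hi; b[j] = 1.0 + lo + hi; r[j] = out(i, j);
    }
    thomas(a, b, c, r, ny);
    for (int j = 0; j < ny; ++j) out(i, j) = r[j];
  }

  if (decay > 0.0) {
    double f = std::exp(-decay * dt);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (!dmask(i, j)) out(i, j) *= f;
  }

  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (dmask(i, j)) out(i, j) = dval(i, j);

  return out;
}

// One relaxation step of pairwise volume exclusion: overlapping pairs are
// pushed apart along their axis, displacement capped at half the overlap so
// a single step never over-corrects. Neighbour search uses cell-list
// binning at the maximum interaction diameter; iteration order is fixed so
// results are deterministic. Positions are clamped to the domain box.
// [[Rcpp::export]]
List relax_overlaps_cpp(NumericVector x, NumericVector y, NumericVector radius,
                        double k, double dt, double xmin, double xmax,
                        double ymin, double ymax) {
  int n = x.size();
  NumericVector xo = clone(x), yo = clone(y);
  if (n > 1) {
    double maxr = 0.0;
    for (int i = 0; i < n; ++i) maxr = std::max(maxr, radius[i]);
    double cell = std::max(2.0 * maxr, 1e-6);
    int bx = std::max(1, (int)std::floor((xmax - xmin) / cell));
    int by = std::max(1, (int)std::floor((ymax - ymin) / cell));
    double wx = (xmax - xmin) / bx, wy = (ymax - ymin) / by;
    std::vector<int> head(bx * by, -1), nxt(n, -1), binx(n), biny(n);
    for (int i = 0; i < n; ++i) {
      int ix = std::min(bx - 1, std::max(0, (int)std::floor((x[i] - xmin) / wx)));
      int iy = std::min(by - 1, std::max(0, (int)std::floor((y[i] - ymin) / wy)));
      binx[i] = ix; biny[i] = iy;
      int b = iy * bx + ix;
      nxt[i] = head[b];
      head[b] = i;
    }
    std::vector<double> dx(n, 0.0), dy(n, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int ox = -1; ox <= 1; ++ox) {
        int ix = binx[i] + ox;
        if (ix < 0 || ix >= bx) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int iy = biny[i] + oy;
          if (iy < 0 || iy >= by) continue;
          for (int j = head[iy * bx + ix]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            double rx = x[i] - x[j], ry = y[i] - y[j];
            double rsum = radius[i] + radius[j];
            double d2 = rx * rx + ry * ry;
            if (d2 >= rsum * rsum) continue;
            double d = std::sqrt(d2);
            double overlap = rsum - d;
            double push = std::min(0.5 * k * overlap * dt, 0.5 * overlap);
            double ux = 1.0, uy = 0.0;
            if (d > 1e-12) { ux = rx / d; uy = ry / d; }
            dx[i] += push * ux; dy[i] += push * uy;
            dx[j] -= push * ux; dy[j] -= push * uy;
          }
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      xo[i] = x[i] + dx[i];
      yo[i] = y[i] + dy[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    xo[i] = std::min(xmax, std::max(xmin, (double)xo[i]));
    yo[i] = std::min(ymax, std::max(ymin, (double)yo[i]));
  }
  return List::create(Named("x") = xo, Named("y") = yo);
}
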