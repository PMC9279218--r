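#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Mirror (symmetric, edge-repeating) index: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int mirror(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - 1 - i;
}

// One blanket dilation/erosion step over a 4D grid with mirror boundaries.
// u_new(x) = max(u(x)+1, max over the 8 direct (+-1 one axis) neighbours)
static void blanket_step(const std::vector<double>& u, std::vector<double>& out,
                         int nx, int ny, int nz, int np, bool upper) {
  const long sx = 1, sy = (long)nx, sz = (long)nx * ny, sp = (long)nx * ny * nz;
  for (int p = 0; p < np; ++p) {
    int pm = mirror(p - 1, np), pp = mirror(p + 1, np);
    for (int z = 0; z < nz; ++z) {
      int zm = mirror(z - 1, nz), zp = mirror(z + 1, nz);
      for (int y = 0; y < ny; ++y) {
        int ym = mirror(y - 1, ny), yp = mirror(y + 1, ny);
        long base = y * sy + z * sz + p * sp;
        long bym = ym * sy + z * sz + p * sp, byp = yp * sy + z * sz + p * sp;
        long bzm = y * sy + zm * sz + p * sp, bzp = y * sy + zp * sz + p * sp;
        long bpm = y * sy + z * sz + pm * sp, bpp = y * sy + z * sz + pp * sp;
        for (int x = 0; x < nx; ++x) {
          int xm = mirror(x - 1, nx), xp = mirror(x + 1, nx);
          double v;
          if (upper) {
            v = u[base + x] + 1.0;
            v = std::max(v, u[base + xm]); v = std::max(v, u[base + xp]);
            v = std::max(v, u[bym + x]);  v = std::max(v, u[byp + x]);
            v = std::max(v, u[bzm + x]);  v = std::max(v, u[bzp + x]);
            v = std::max(v, u[bpm + x]);  v = std::max(v, u[bpp + x]);
          } else {
            v = u[base + x] - 1.0;
            v = std::min(v, u[base + xm]); v = std::min(v, u[base + xp]);
            v = std::min(v, u[bym + x]);  v = std::min(v, u[byp + x]);
            v = std::min(v, u[bzm + x]);  v = std::min(v, u[bzp + x]);
            v = std::min(v, u[bpm + x]);  v = std::min(v, u[bpp + x]);
          }
          out[base + x] = v;
        }
      }
    }
  }
}

// Full blanket iteration returning the inter-blanket volume V(eps) summed over
// an optional 3D ROI (all phases). roi may be length 0 (whole grid).
// [[Rcpp::export]]
NumericVector cpp_blanket_volumes(NumericVector stack, IntegerVector dims,
                                  int maxeps, LogicalVector roi) {
  int nx = dims[0], ny = dims[1], nz = dims[2], np = dims[3];
  long n = (long)nx * ny * nz * np, nsp = (long)nx * ny * nz;
  bool useroi = roi.size() > 0;
  std::vector<double> u(stack.begin(), stack.end()), b(u), tmp(n);
  NumericVector V(maxeps);
  for (int e = 1; e <= maxeps; ++e) {
    blanket_step(u, tmp, nx, ny, nz, np, true);  u.swap(tmp);
    blanket_step(b, tmp, nx, ny, nz, np, false); b.swap(tmp);
    double s = 0.0;
    if (useroi) {
      for (int p = 0; p < np; ++p) {
        long off = (long)p * nsp;
        for (long i = 0; i < nsp; ++i)
          if (roi[i]) s += u[off + i] - b[off + i];
      }
    } else {
      for (long i = 0; i < n; ++i) s += u[i] - b[i];
    }
    V[e - 1] = s;
  }
  return V;
}

// Materialized blanket sequence for small inputs (oracle/interactive use).
// Returns list of list(upper=, lower=) in iteration order.
// [[Rcpp::export]]
List cpp_blanket_pairs(NumericVector stack, IntegerVector dims, int maxeps) {
  int nx = dims[0], ny = dims[1], nz = dims[2], np = dims[3];
  long n = (long)nx * ny * nz * np;
  std::vector<double> u(stack.begin(), stack.end()), b(u), tmp(n);
  List out(maxeps);
  for (int e = 1; e <= maxeps; ++e) {
    blanket_step(u, tmp, nx, ny, nz, np, true);  u.swap(tmp);
    blanket_step(b, tmp, nx, ny, nz, np, false); b.swap(tmp);
    NumericVector uu(u.begin(), u.end()), bb(b.begin(), b.end());
    out[e - 1] = List::create(Named("upper") = uu, Named("lower") = bb);
  }
  return out;
}

// Local FD map: for every spatial voxel, extract its mirror-padded 4D window
// (radius `wr` spatially and across the phase axis), run the blanket there,
// and fit log A(eps) ~ log eps by least squares. fd = 4 - slope, clamped to
// [4,5]. Returns list(map=3D values, clamped=count of clamped voxels).
// [[Rcpp::export]]
List cpp_local_fd(NumericVector stack, IntegerVector dims, int wr,
                  IntegerVector scales, bool centerPhases) {
  int nx = dims[0], ny = dims[1], nz = dims[2], np = dims[3];
  long nsp = (long)nx * ny * nz;
  int w = 2 * wr + 1;
  // the window spans the voxel's spatial vicinity and the full phase axis;
  // the blanket iteration mirrors at all window boundaries including phase
  long wn = (long)w * w * w * np;
  int maxeps = 0, ns = scales.size();
  for (int i = 0; i < ns; ++i) maxeps = std::max(maxeps, scales[i]);
  std::vector<double> win(wn), u(wn), b(wn), tmp(wn), V(maxeps);
  // precompute regression of y on log(eps): slope = sum(cx*y)
  std::vector<double> lx(ns), cx(ns);
  double mx = 0;
  for (int i = 0; i < ns; ++i) { lx[i] = std::log((double)scales[i]); mx += lx[i]; }
  mx /= ns;
  double sxx = 0;
  for (int i = 0; i < ns; ++i) { cx[i] = lx[i] - mx; sxx += cx[i] * cx[i]; }
  for (int i = 0; i < ns; ++i) cx[i] /= sxx;

  NumericVector map(nsp);
  long nclamp = 0;
  const long sy = nx, sz = (long)nx * ny, sp = (long)nx * ny * nz;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        // fill window (mirror padding on the spatial axes)
        long k = 0;
        for (int p = 0; p < np; ++p) {
          long op = (long)p * sp;
          for (int dz = -wr; dz <= wr; ++dz) {
            long oz = (long)mirror(z0 + dz, nz) * sz;
            for (int dy = -wr; dy <= wr; ++dy) {
              long oy = (long)mirror(y0 + dy, ny) * sy;
              for (int dx = -wr; dx <= wr; ++dx)
                win[k++] = stack[op + oz + oy + mirror(x0 + dx, nx)];
            }
          }
        }
        if (centerPhases) {
          // remove each phase-slab's window mean so the blanket sees the
          // enhancement pattern, not bulk per-phase enhancement levels
          long slab = (long)w * w * w;
          for (int p = 0; p < np; ++p) {
            double m = 0;
            for (long i = 0; i < slab; ++i) m += win[p * slab + i];
            m /= slab;
            for (long i = 0; i < slab; ++i) win[p * slab + i] -= m;
          }
        }
        std::copy(win.begin(), win.end(), u.begin());
        std::copy(win.begin(), win.end(), b.begin());
        for (int e = 1; e <= maxeps; ++e) {
          blanket_step(u, tmp, w, w, w, np, true);  u.swap(tmp);
          blanket_step(b, tmp, w, w, w, np, false); b.swap(tmp);
          double s = 0;
          for (long i = 0; i < wn; ++i) s += u[i] - b[i];
          V[e - 1] = s;
        }
        // incremental surface measure A(eps) = (V(eps)-V(eps-1))/2
        double slope = 0;
        bool bad = false;
        double Amin = R_PosInf, Amax = R_NegInf;
        for (int i = 0; i < ns; ++i) {
          int e = scales[i];
          double A = (V[e - 1] - (e > 1 ? V[e - 2] : 0.0)) / 2.0;
          if (A <= 0) { bad = true; break; }
          Amin = std::min(Amin, A); Amax = std::max(Amax, A);
          slope += cx[i] * std::log(A);
        }
        if (Amin == Amax) slope = 0;  // flat-texture limit, exactly
        double fd = bad ? 4.0 : 4.0 - slope;
        if (fd < 4.0) { fd = 4.0; ++nclamp; }
        else if (fd > 5.0) { fd = 5.0; ++nclamp; }
        map[(long)z0 * sz + (long)y0 * sy + x0] = fd;
      }
  return List::create(Named("map") = map, Named("clamped") = (double)nclamp);
}
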