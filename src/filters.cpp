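#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int mirror3(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - 1 - i;
}

// 3D median filter, cubic neighbourhood of half-width `radius`, mirror padding.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dims, int radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny;
  int w = 2 * radius + 1;
  std::vector<double> buf((size_t)w * w * w);
  NumericVector out((long)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t k = 0;
        for (int dz = -radius; dz <= radius; ++dz) {
          long oz = (long)mirror3(z + dz, nz) * sz;
          for (int dy = -radius; dy <= radius; ++dy) {
            long oy = (long)mirror3(y + dy, ny) * sy;
            for (int dx = -radius; dx <= radius; ++dx)
              buf[k++] = vol[oz + oy + mirror3(x + dx, nx)];
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[(long)z * sz + (long)y * sy + x] = buf[mid];
      }
  return out;
}

// 3D bilateral filter: Gaussian spatial weight (sigma in voxels) over a cubic
// window of half-width `radius`, Gaussian range weight with sd `rangeSigma`
// in intensity units. Mirror padding.
// [[Rcpp::export]]
NumericVector cpp_bilateral3d(NumericVector vol, IntegerVector dims,
                              double spatialSigma, double rangeSigma, int radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny;
  int w = 2 * radius + 1;
  std::vector<double> gw((size_t)w * w * w);
  size_t k = 0;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        gw[k++] = std::exp(-0.5 * (dx * dx + dy * dy + dz * dz) /
                           (spatialSigma * spatialSigma));
  double r2 = 2.0 * rangeSigma * rangeSigma;
  NumericVector out((long)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double c = vol[(long)z * sz + (long)y * sy + x];
        double num = 0, den = 0;
        k = 0;
        for (int dz = -radius; dz <= radius; ++dz) {
          long oz = (long)mirror3(z + dz, nz) * sz;
          for (int dy = -radius; dy <= radius; ++dy) {
            long oy = (long)mirror3(y + dy, ny) * sy;
            for (int dx = -radius; dx <= radius; ++dx) {
              double v = vol[oz + oy + mirror3(x + dx, nx)];
              double d = v - c;
              double wgt = gw[k++] * std::exp(-d * d / r2);
              num += wgt * d; den += wgt;
            }
          }
        }
        // accumulate deviations from the centre value: constant regions
        // pass through exactly
        out[(long)z * sz + (long)y * sy + x] = c + num / den;
      }
  return out;
}

// Trilinear (or nearest-neighbour) resampling of a 3D volume from voxel-centre
// grid index*spacing onto index*target. Output dims supplied by caller.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector dims,
                             NumericVector spacing, NumericVector target,
                             IntegerVector odims, bool nearest) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = odims[0], my = odims[1], mz = odims[2];
  long sy = nx, sz = (long)nx * ny;
  NumericVector out((long)mx * my * mz);
  for (int z = 0; z < mz; ++z) {
    double gz = z * target[2] / spacing[2];
    for (int y = 0; y < my; ++y) {
      double gy = y * target[1] / spacing[1];
      for (int x = 0; x < mx; ++x) {
        double gx = x * target[0] / spacing[0];
        long o = (long)z * (long)mx * my + (long)y * mx + x;
        if (nearest) {
          int ix = std::min(nx - 1, std::max(0, (int)std::lround(gx)));
          int iy = std::min(ny - 1, std::max(0, (int)std::lround(gy)));
          int iz = std::min(nz - 1, std::max(0, (int)std::lround(gz)));
          out[o] = vol[(long)iz * sz + (long)iy * sy + ix];
        } else {
          double cx = std::min((double)(nx - 1), std::max(0.0, gx));
          double cy = std::min((double)(ny - 1), std::max(0.0, gy));
          double cz = std::min((double)(nz - 1), std::max(0.0, gz));
          int x0 = (int)cx, y0 = (int)cy, z0 = (int)cz;
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          double v000 = vol[(long)z0 * sz + (long)y0 * sy + x0];
          double v100 = vol[(long)z0 * sz + (long)y0 * sy + x1];
          double v010 = vol[(long)z0 * sz + (long)y1 * sy + x0];
          double v110 = vol[(long)z0 * sz + (long)y1 * sy + x1];
          double v001 = vol[(long)z1 * sz + (long)y0 * sy + x0];
          double v101 = vol[(long)z1 * sz + (long)y0 * sy + x1];
          double v011 = vol[(long)z1 * sz + (long)y1 * sy + x0];
          double v111 = vol[(long)z1 * sz + (long)y1 * sy + x1];
          double v00 = v000 + fx * (v100 - v000), v10 = v010 + fx * (v110 - v010);
          double v01 = v001 + fx * (v101 - v001), v11 = v011 + fx * (v111 - v011);
          double v0 = v00 + fy * (v10 - v00), v1 = v01 + fy * (v11 - v01);
          out[o] = v0 + fz * (v1 - v0);
        }
      }
    }
  }
  return out;
}

// Maximum pairwise Euclidean distance between rows of an n x 3 matrix (mm).
// [[Rcpp::export]]
double cpp_max_pairdist(NumericMatrix pts) {
  long n = pts.nrow();
  double best = 0;
  for (long i = 0; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (long j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  }
  return std::sqrt(best);
}

// 26-connected component of `mask` containing `seed` (0-based index vector).
// [[Rcpp::export]]
LogicalVector cpp_flood26(LogicalVector mask, IntegerVector dims,
                          IntegerVector seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny, n = (long)nx * ny * nz;
  LogicalVector out(n);
  long s = (long)seed[2] * sz + (long)seed[1] * sy + seed[0];
  if (!mask[s]) return out;
  std::vector<long> stack;
  stack.push_back(s);
  out[s] = true;
  while (!stack.empty()) {
    long cur = stack.back(); stack.pop_back();
    int x = cur % nx, y = (cur / nx) % ny, z = cur / sz;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
          long idx = (long)Z * sz + (long)Y * sy + X;
          if (mask[idx] && !out[idx]) { out[idx] = true; stack.push_back(idx); }
        }
  }
  return out;
}
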