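// Numeric kernels for volumetric registration: separable convolution,
// interpolation, cubic B-spline FFD evaluation/scatter, extrema scans,
// SIFT-style descriptors and brute-force surface distances.
//
// All volumes are dense column-major arrays (x fastest), 0-based indices.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // half-sample symmetric border: -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export(name = ".conv1dReflect")]]
NumericVector conv1d_reflect(NumericVector vol, NumericVector kern, int axis) {
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kn = kern.size();
  int kr = (kn - 1) / 2;           // kernel assumed odd-length, centred
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  // strides
  long sx = 1, sy = nx, sz = (long)nx * ny;
  long stride[3] = {sx, sy, sz};
  long s = stride[axis];
  // iterate over all lines along `axis`
  int na = (axis == 0) ? ny : nx;
  int nb = (axis == 2) ? ny : nz;
  long sa = (axis == 0) ? sy : sx;
  long sb = (axis == 2) ? sy : sz;
  std::vector<double> line(len);
  for (int b = 0; b < nb; ++b) {
    for (int a = 0; a < na; ++a) {
      long base = a * sa + b * sb;
      for (int i = 0; i < len; ++i) line[i] = vol[base + i * s];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int k = 0; k < kn; ++k) {
          int j = reflect_idx(i + k - kr, len);
          acc += kern[k] * line[j];
        }
        out[base + i * s] = acc;
      }
    }
  }
  return out;
}

static inline bool inside3(double x, int n) { return x >= 0.0 && x <= (double)(n - 1); }

// [[Rcpp::export(name = ".trilinearSample")]]
NumericMatrix trilinear_sample(NumericVector vol, NumericMatrix idx, double fill) {
  // returns n x 5: value, d/dx, d/dy, d/dz (index units), inside flag
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny;
  int n = idx.nrow();
  NumericMatrix out(n, 5);
  for (int p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!inside3(x, nx) || !inside3(y, ny) || !inside3(z, nz)) {
      out(p, 0) = fill; out(p, 4) = 0.0;
      continue;
    }
    int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (nx == 1) x0 = 0;
    int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (ny == 1) y0 = 0;
    int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    long b = x0 + (long)y0 * sy + (long)z0 * sz;
    double c000 = vol[b],            c100 = (nx>1)? vol[b+1] : vol[b];
    double c010 = (ny>1)? vol[b+sy] : c000, c110 = (nx>1&&ny>1)? vol[b+1+sy] : c100;
    double c001 = (nz>1)? vol[b+sz] : c000, c101 = (nx>1&&nz>1)? vol[b+1+sz] : c100;
    double c011 = (ny>1&&nz>1)? vol[b+sy+sz] : c010;
    double c111 = (nx>1&&ny>1&&nz>1)? vol[b+1+sy+sz] : c110;
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    out(p, 0) = c0 + fz * (c1 - c0);
    // exact derivatives of the trilinear interpolant
    double gx00 = c100 - c000, gx10 = c110 - c010, gx01 = c101 - c001, gx11 = c111 - c011;
    double gx0 = gx00 + fy * (gx10 - gx00), gx1 = gx01 + fy * (gx11 - gx01);
    out(p, 1) = gx0 + fz * (gx1 - gx0);
    double gy0 = c10 - c00, gy1 = c11 - c01;
    out(p, 2) = gy0 + fz * (gy1 - gy0);
    out(p, 3) = c1 - c0;
    out(p, 4) = 1.0;
  }
  return out;
}

// [[Rcpp::export(name = ".nearestSample")]]
NumericVector nearest_sample(NumericVector vol, NumericMatrix idx, double fill) {
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny;
  int n = idx.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!inside3(x, nx) || !inside3(y, ny) || !inside3(z, nz)) { out[p] = fill; continue; }
    int xi = (int)std::floor(x + 0.5); if (xi > nx - 1) xi = nx - 1;
    int yi = (int)std::floor(y + 0.5); if (yi > ny - 1) yi = ny - 1;
    int zi = (int)std::floor(z + 0.5); if (zi > nz - 1) zi = nz - 1;
    out[p] = vol[xi + (long)yi * sy + (long)zi * sz];
  }
  return out;
}

static inline void bspline3_w(double u, double* w) {
  // uniform cubic B-spline basis on [0,1), four overlapping pieces
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - 3.0 * u + 3.0 * u2 - u3) / 6.0;
  w[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  w[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  w[3] = u3 / 6.0;
}

// grid coordinate of a world point, clamped so the 4^3 support stays in-grid
static inline void grid_coord(double x, double o, double h, int K, int* i0, double* u,
                              bool* clamped) {
  double t = (x - o) / h;
  *clamped = false;
  if (t < 1.0) { t = 1.0; *clamped = true; }
  if (t > (double)(K - 2)) { t = (double)(K - 2); *clamped = true; }
  int i = (int)std::floor(t);
  if (i > K - 3) i = K - 3;   // keep i-1 .. i+2 within 0..K-1
  *i0 = i;
  *u = t - i;
}

// [[Rcpp::export(name = ".ffdDisplace")]]
NumericMatrix ffd_displace(NumericMatrix coef, NumericVector origin,
                           NumericVector spacing, IntegerVector gsize,
                           NumericMatrix pts) {
  int K1 = gsize[0], K2 = gsize[1], K3 = gsize[2];
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    int ix, iy, iz; double ux, uy, uz; bool cl;
    grid_coord(pts(p, 0), origin[0], spacing[0], K1, &ix, &ux, &cl);
    grid_coord(pts(p, 1), origin[1], spacing[1], K2, &iy, &uy, &cl);
    grid_coord(pts(p, 2), origin[2], spacing[2], K3, &iz, &uz, &cl);
    bspline3_w(ux, wx); bspline3_w(uy, wy); bspline3_w(uz, wz);
    double dx = 0, dy = 0, dz = 0;
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        double wbc = wy[b] * wz[c];
        long base = (long)(ix - 1) + (long)(iy - 1 + b) * K1 +
                    (long)(iz - 1 + c) * K1 * K2;
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wbc;
          long ci = base + a;
          dx += w * coef(ci, 0);
          dy += w * coef(ci, 1);
          dz += w * coef(ci, 2);
        }
      }
    }
    out(p, 0) = dx; out(p, 1) = dy; out(p, 2) = dz;
  }
  return out;
}

// [[Rcpp::export(name = ".ffdScatter")]]
NumericMatrix ffd_scatter(NumericVector origin, NumericVector spacing,
                          IntegerVector gsize, NumericMatrix pts,
                          NumericMatrix alpha) {
  // accumulate grad[k, c] += w_k(x_p) * alpha[p, c]
  int K1 = gsize[0], K2 = gsize[1], K3 = gsize[2];
  long K = (long)K1 * K2 * K3;
  int n = pts.nrow();
  NumericMatrix grad(K, 3);
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    int ix, iy, iz; double ux, uy, uz; bool cl;
    grid_coord(pts(p, 0), origin[0], spacing[0], K1, &ix, &ux, &cl);
    grid_coord(pts(p, 1), origin[1], spacing[1], K2, &iy, &uy, &cl);
    grid_coord(pts(p, 2), origin[2], spacing[2], K3, &iz, &uz, &cl);
    bspline3_w(ux, wx); bspline3_w(uy, wy); bspline3_w(uz, wz);
    double a0 = alpha(p, 0), a1 = alpha(p, 1), a2 = alpha(p, 2);
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        double wbc = wy[b] * wz[c];
        long base = (long)(ix - 1) + (long)(iy - 1 + b) * K1 +
                    (long)(iz - 1 + c) * K1 * K2;
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wbc;
          long ci = base + a;
          grad(ci, 0) += w * a0;
          grad(ci, 1) += w * a1;
          grad(ci, 2) += w * a2;
        }
      }
    }
  }
  return grad;
}

// [[Rcpp::export(name = ".ffdJacobian")]]
NumericMatrix ffd_jacobian(NumericVector origin, NumericVector spacing,
                           IntegerVector gsize, NumericMatrix pts) {
  // triplets (point 0-based, control-point 0-based, weight); error if a
  // point falls outside the valid spline domain
  int K1 = gsize[0], K2 = gsize[1], K3 = gsize[2];
  int n = pts.nrow();
  NumericMatrix out(n * 64, 3);
  double wx[4], wy[4], wz[4];
  long r = 0;
  for (int p = 0; p < n; ++p) {
    int ix, iy, iz; double ux, uy, uz; bool c1, c2, c3;
    grid_coord(pts(p, 0), origin[0], spacing[0], K1, &ix, &ux, &c1);
    grid_coord(pts(p, 1), origin[1], spacing[1], K2, &iy, &uy, &c2);
    grid_coord(pts(p, 2), origin[2], spacing[2], K3, &iz, &uz, &c3);
    if (c1 || c2 || c3)
      stop("point %d lies outside the FFD grid domain", p + 1);
    bspline3_w(ux, wx); bspline3_w(uy, wy); bspline3_w(uz, wz);
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b)
        for (int a = 0; a < 4; ++a) {
          long ci = (long)(ix - 1 + a) + (long)(iy - 1 + b) * K1 +
                    (long)(iz - 1 + c) * K1 * K2;
          out(r, 0) = p; out(r, 1) = (double)ci;
          out(r, 2) = wx[a] * wy[b] * wz[c];
          ++r;
        }
  }
  return out;
}

// [[Rcpp::export(name = ".localMaxima26")]]
NumericMatrix local_maxima_26(NumericVector vol, double thresh) {
  // strict 26-neighbourhood maxima above thresh, interior voxels only;
  // rows: x, y, z (0-based), value
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny;
  std::vector<double> hits;
  for (int z = 1; z < nz - 1; ++z)
    for (int y = 1; y < ny - 1; ++y)
      for (int x = 1; x < nx - 1; ++x) {
        long i = x + y * sy + z * sz;
        double v = vol[i];
        if (!(v > thresh)) continue;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              if (!(v > vol[i + dx + dy * sy + dz * sz])) { ok = false; break; }
            }
        if (ok) { hits.push_back(x); hits.push_back(y); hits.push_back(z); hits.push_back(v); }
      }
  int n = hits.size() / 4;
  NumericMatrix out(n, 4);
  for (int p = 0; p < n; ++p)
    for (int c = 0; c < 4; ++c) out(p, c) = hits[4 * p + c];
  return out;
}

// [[Rcpp::export(name = ".dogExtrema")]]
NumericMatrix dog_extrema(NumericVector below, NumericVector cur,
                          NumericVector above, double t3) {
  // strict extrema of |cur| > t3 over 26 spatial neighbours plus the full
  // 27-voxel blocks in the scales below and above (80 comparisons)
  IntegerVector dims = cur.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny;
  std::vector<double> hits;
  for (int z = 1; z < nz - 1; ++z)
    for (int y = 1; y < ny - 1; ++y)
      for (int x = 1; x < nx - 1; ++x) {
        long i = x + y * sy + z * sz;
        double v = cur[i];
        if (!(std::fabs(v) > t3)) continue;
        bool isMax = true, isMin = true;
        for (int dz = -1; dz <= 1 && (isMax || isMin); ++dz)
          for (int dy = -1; dy <= 1 && (isMax || isMin); ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              long j = i + dx + dy * sy + dz * sz;
              if (j != i) {
                if (!(v > cur[j])) isMax = false;
                if (!(v < cur[j])) isMin = false;
              }
              if (!(v > below[j])) isMax = false;
              if (!(v < below[j])) isMin = false;
              if (!(v > above[j])) isMax = false;
              if (!(v < above[j])) isMin = false;
              if (!isMax && !isMin) break;
            }
        if (isMax || isMin) {
          hits.push_back(x); hits.push_back(y); hits.push_back(z); hits.push_back(v);
        }
      }
  int n = hits.size() / 4;
  NumericMatrix out(n, 4);
  for (int p = 0; p < n; ++p)
    for (int c = 0; c < 4; ++c) out(p, c) = hits[4 * p + c];
  return out;
}

// [[Rcpp::export(name = ".siftDescriptors")]]
NumericMatrix sift_descriptors(NumericVector vol, IntegerMatrix centers,
                               int patchWidth) {
  // 4 x 4 x 4 spatial subregions x 8 azimuth x 8 elevation bins = 4096.
  // Trilinear soft-binning over subregion coordinates, bilinear over
  // (azimuth wrapped, elevation clamped); Gaussian spatial weighting.
  // Gradients by central differences; window must lie >= 1 voxel inside.
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long sy = nx, sz = (long)nx * ny;
  int half = 2 * patchWidth;                  // 8 for the default width 4
  int n = centers.nrow();
  NumericMatrix out(n, 4096);
  double sigma = (double)half;                // Gaussian window scale
  double twoPi = 2.0 * M_PI;
  for (int p = 0; p < n; ++p) {
    int cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    if (cx - half < 1 || cx + half - 1 > nx - 2 ||
        cy - half < 1 || cy + half - 1 > ny - 2 ||
        cz - half < 1 || cz + half - 1 > nz - 2)
      stop("keypoint %d: descriptor support window exits the volume", p + 1);
    double* d = &out(p, 0);   // column-major: careful, fill via out(p, k)
    for (int oz = -half; oz < half; ++oz)
      for (int oy = -half; oy < half; ++oy)
        for (int ox = -half; ox < half; ++ox) {
          long i = (long)(cx + ox) + (long)(cy + oy) * sy + (long)(cz + oz) * sz;
          double gx = 0.5 * (vol[i + 1] - vol[i - 1]);
          double gy = 0.5 * (vol[i + sy] - vol[i - sy]);
          double gz = 0.5 * (vol[i + sz] - vol[i - sz]);
          double mag = std::sqrt(gx * gx + gy * gy + gz * gz);
          if (mag <= 0.0) continue;
          double r2 = (double)(ox * ox + oy * oy + oz * oz);
          double wG = std::exp(-r2 / (2.0 * sigma * sigma));
          double m = mag * wG;
          // spatial subregion coordinates in [-0.5, 3.5]
          double scx = ((double)ox + 0.5) / patchWidth + 1.5;
          double scy = ((double)oy + 0.5) / patchWidth + 1.5;
          double scz = ((double)oz + 0.5) / patchWidth + 1.5;
          // orientation coordinates
          double az = std::atan2(gy, gx); if (az < 0) az += twoPi;
          double ac = az / (twoPi / 8.0);             // bin centres at k*45deg
          double el = std::acos(std::max(-1.0, std::min(1.0, gz / mag)));
          double ec = el / (M_PI / 8.0) - 0.5;        // centres at (k+.5)*pi/8
          int sx0 = (int)std::floor(scx), sy0 = (int)std::floor(scy),
              sz0 = (int)std::floor(scz);
          double fx = scx - sx0, fy = scy - sy0, fz = scz - sz0;
          int a0 = (int)std::floor(ac); double fa = ac - a0;
          int e0 = (int)std::floor(ec); double fe = ec - e0;
          for (int dzi = 0; dzi < 2; ++dzi) {
            int szi = sz0 + dzi; if (szi < 0 || szi > 3) continue;
            double wz2 = dzi ? fz : 1.0 - fz;
            for (int dyi = 0; dyi < 2; ++dyi) {
              int syi = sy0 + dyi; if (syi < 0 || syi > 3) continue;
              double wy2 = (dyi ? fy : 1.0 - fy) * wz2;
              for (int dxi = 0; dxi < 2; ++dxi) {
                int sxi = sx0 + dxi; if (sxi < 0 || sxi > 3) continue;
                double wsp = (dxi ? fx : 1.0 - fx) * wy2;
                int sub = sxi + 4 * syi + 16 * szi;   // 0..63
                for (int dai = 0; dai < 2; ++dai) {
                  int ai = (a0 + dai) % 8;
                  double wa = dai ? fa : 1.0 - fa;
                  for (int dei = 0; dei < 2; ++dei) {
                    int ei = e0 + dei;
                    if (ei < 0) ei = 0;               // clamp poles
                    if (ei > 7) ei = 7;
                    double we = dei ? fe : 1.0 - fe;
                    int bin = sub * 64 + ai * 8 + ei;
                    d[(long)bin * n] += m * wsp * wa * we;
                  }
                }
              }
            }
          }
        }
  }
  return out;
}

// [[Rcpp::export(name = ".minDistances")]]
NumericVector min_distances(NumericMatrix a, NumericMatrix b) {
  // for each row of a, min Euclidean distance to rows of b
  int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export(name = ".jointHistParzen")]]
List joint_hist_parzen(IntegerVector fbin, NumericVector mcoord, int nbins) {
  // joint histogram: hard binning on the fixed axis (fbin, 0-based),
  // cubic B-spline Parzen window on the moving axis. mcoord is the
  // continuous moving bin coordinate; support bins floor(m)-1 .. +2.
  // Returns the unnormalised histogram and the per-sample support/weight
  // bookkeeping needed for the analytic gradient.
  int n = fbin.size();
  NumericMatrix hist(nbins, nbins);       // [fixed, moving]
  IntegerVector k0(n);
  NumericMatrix w(n, 4), dw(n, 4);
  double wt[4];
  for (int i = 0; i < n; ++i) {
    double m = mcoord[i];
    if (m < 1.0) m = 1.0;
    if (m > (double)(nbins - 2)) m = (double)(nbins - 2);
    int j0 = (int)std::floor(m);
    if (j0 > nbins - 3) j0 = nbins - 3;
    double u = m - j0;
    bspline3_w(u, wt);
    // derivative of each weight w.r.t. m (== w.r.t. u)
    double u2 = u * u;
    double dwt[4];
    dwt[0] = (-3.0 + 6.0 * u - 3.0 * u2) / 6.0;
    dwt[1] = (9.0 * u2 - 12.0 * u) / 6.0;
    dwt[2] = (-9.0 * u2 + 6.0 * u + 3.0) / 6.0;
    dwt[3] = 3.0 * u2 / 6.0;
    k0[i] = j0 - 1;
    int f = fbin[i];
    for (int k = 0; k < 4; ++k) {
      hist(f, j0 - 1 + k) += wt[k];
      w(i, k) = wt[k];
      dw(i, k) = dwt[k];
    }
  }
  return List::create(_["hist"] = hist, _["k0"] = k0, _["w"] = w, _["dw"] = dw);
}
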