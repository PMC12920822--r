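// Core numerical kernels: texture count matrices, connected components,
// spherical LBP sampling, marching-tetrahedra surface mesh, affine resampling.
// All 3D arrays are column-major with explicit dims (nx, ny, nz),
// linear index = i + nx*(j + ny*k), 0-based.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline bool ingrid(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && man > 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (!ingrid(ii, jj, kk, nx, ny, nz)) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// Symmetric GLCM counts for the 13 unique unit offsets, distance 1.
// Returns ng x ng x 13 array of pair counts (each pair counted in both orders).
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    R_xlen_t off = (R_xlen_t)ng * ng * d;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (!mask[v]) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (!ingrid(ii, jj, kk, nx, ny, nz)) continue;
          R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (!mask[w]) continue;
          int a = levels[v] - 1, b = levels[w] - 1;
          out[off + a + (R_xlen_t)ng * b] += 1.0;
          out[off + b + (R_xlen_t)ng * a] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// GLRLM counts: runs of consecutive equal in-mask levels along each of the
// 13 directions; out-of-mask voxels break runs. Returns ng x maxlen x 13.
// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, LogicalVector mask,
                               IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out((R_xlen_t)ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    R_xlen_t off = (R_xlen_t)ng * maxlen * d;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          // only start walking at line starts
          if (ingrid(i - dx, j - dy, k - dz, nx, ny, nz)) continue;
          int curlev = -1, runlen = 0;
          int ii = i, jj = j, kk = k;
          while (ingrid(ii, jj, kk, nx, ny, nz)) {
            R_xlen_t v = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            int lev = mask[v] ? levels[v] : -1;
            if (lev == curlev && lev > 0) {
              ++runlen;
            } else {
              if (curlev > 0)
                out[off + (curlev - 1) + (R_xlen_t)ng * (runlen - 1)] += 1.0;
              curlev = lev;
              runlen = 1;
            }
            ii += dx; jj += dy; kk += dz;
          }
          if (curlev > 0)
            out[off + (curlev - 1) + (R_xlen_t)ng * (runlen - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// GLSZM zones: 26-connected components of equal level within the mask.
// Returns a 2-column matrix (level, size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlev, zsize;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || seen[s]) continue;
    int lev = levels[s];
    int size = 0;
    seen[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      ++size;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (!ingrid(ii, jj, kk, nx, ny, nz)) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && !seen[w] && levels[w] == lev) {
              seen[w] = 1; stack.push_back(w);
            }
          }
    }
    zlev.push_back(lev);
    zsize.push_back(size);
  }
  IntegerMatrix out((int)zlev.size(), 2);
  for (int r = 0; r < (int)zlev.size(); ++r) {
    out(r, 0) = zlev[r];
    out(r, 1) = zsize[r];
  }
  return out;
}

// GLDM counts: dependence j = 1 + number of in-mask 26-neighbours whose level
// differs from the centre by at most alpha. Returns ng x 27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim, int ng, int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[v]) continue;
        int lev = levels[v], dep = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (!ingrid(ii, jj, kk, nx, ny, nz)) continue;
              R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (mask[w] && std::abs(levels[w] - lev) <= alpha) ++dep;
            }
        out(lev - 1, dep) += 1.0;
      }
  return out;
}

// NGTDM per-level stats: n_i (count of in-mask voxels with level i having at
// least one in-mask neighbour) and s_i (sum of |level - mean neighbour level|).
// Returns ng x 2 matrix (n_i, s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm_stats(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[v]) continue;
        double sum = 0.0; int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (!ingrid(ii, jj, kk, nx, ny, nz)) continue;
              R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (mask[w]) { sum += levels[w]; ++cnt; }
            }
        if (cnt > 0) {
          int lev = levels[v];
          out(lev - 1, 0) += 1.0;
          out(lev - 1, 1) += std::fabs((double)lev - sum / cnt);
        }
      }
  return out;
}

static inline double sample_trilinear(const NumericVector &img, int nx, int ny,
                                      int nz, double x, double y, double z) {
  // clamp-to-border replication
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2 >= 0 ? nx - 2 : 0;
  if (j0 > ny - 2) j0 = ny - 2 >= 0 ? ny - 2 : 0;
  if (k0 > nz - 2) k0 = nz - 2 >= 0 ? nz - 2 : 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  if (nx == 1) { i0 = 0; fx = 0; }
  if (ny == 1) { j0 = 0; fy = 0; }
  if (nz == 1) { k0 = 0; fz = 0; }
  double acc = 0.0;
  for (int c = 0; c < 8; ++c) {
    int bx = c & 1, by = (c >> 1) & 1, bz = (c >> 2) & 1;
    double w = (bx ? fx : 1 - fx) * (by ? fy : 1 - fy) * (bz ? fz : 1 - fz);
    if (w == 0) continue;
    R_xlen_t idx = (i0 + bx) + (R_xlen_t)nx * ((j0 + by) + (R_xlen_t)ny * (k0 + bz));
    acc += w * img[idx];
  }
  return acc;
}

// Spherical LBP maps. dirs: n x 3 unit directions; Y: n x 8 real spherical
// harmonics (3 band-1 columns then 5 band-2 columns). Returns list(m1,m2,k).
// [[Rcpp::export]]
List cpp_lbp3d(NumericVector img, IntegerVector dim, NumericMatrix dirs,
               NumericMatrix Y, double radius, IntegerVector lo,
               IntegerVector hi) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int ns = dirs.nrow();
  NumericVector m1(n), m2(n), kur(n);
  std::vector<double> b(ns), val(ns);
  for (int k = lo[2]; k <= hi[2]; ++k)
    for (int j = lo[1]; j <= hi[1]; ++j)
      for (int i = lo[0]; i <= hi[0]; ++i) {
        R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double c0 = img[v];
        // relative tolerance so interpolation round-off (~1e-16 relative)
        // cannot flip the binary pattern or fake variance on flat regions
        double tol = 1e-9 * (std::fabs(c0) + 1e-30);
        double mean = 0.0;
        for (int s = 0; s < ns; ++s) {
          double x = i + radius * dirs(s, 0);
          double y = j + radius * dirs(s, 1);
          double z = k + radius * dirs(s, 2);
          val[s] = sample_trilinear(img, nx, ny, nz, x, y, z);
          b[s] = val[s] >= c0 - tol ? 1.0 : 0.0;
          mean += val[s];
        }
        mean /= ns;
        double c[8];
        for (int h = 0; h < 8; ++h) {
          double acc = 0.0;
          for (int s = 0; s < ns; ++s) acc += b[s] * Y(s, h);
          c[h] = acc / ns;
        }
        m1[v] = c[0] * c[0] + c[1] * c[1] + c[2] * c[2];
        m2[v] = c[3] * c[3] + c[4] * c[4] + c[5] * c[5] + c[6] * c[6] + c[7] * c[7];
        double mu2 = 0.0, mu4 = 0.0;
        for (int s = 0; s < ns; ++s) {
          double d = val[s] - mean, d2 = d * d;
          mu2 += d2; mu4 += d2 * d2;
        }
        mu2 /= ns; mu4 /= ns;
        kur[v] = mu2 > tol * tol ? mu4 / (mu2 * mu2) : 0.0;
      }
  m1.attr("dim") = dim; m2.attr("dim") = dim; kur.attr("dim") = dim;
  return List::create(_["m1"] = m1, _["m2"] = m2, _["k"] = kur);
}

// Marching tetrahedra on a scalar field (the mask smoothed slightly on the
// R side), iso-level 0.5 with linearly interpolated edge crossings, averaged
// over the four cube diagonals so the result is exactly invariant under the
// octahedral group. The enclosed volume comes from the divergence theorem
// over the oriented cut surface. Returns c(volume, area) in mm units.
// [[Rcpp::export]]
NumericVector cpp_mesh_vol_area(NumericVector field, IntegerVector dim,
                                NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  static const int PERMS[6][3] = {
    {1,2,4},{1,4,2},{2,1,4},{2,4,1},{4,1,2},{4,2,1}
  };
  double vol6 = 0.0, area = 0.0;   // signed 6*volume accumulator
  auto getval = [&](int i, int j, int k) -> double {
    if (!ingrid(i, j, k, nx, ny, nz)) return 0.0;
    return field[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        double vals[8];
        int nin0 = 0;
        for (int b = 0; b < 8; ++b) {
          vals[b] = getval(i + (b & 1), j + ((b >> 1) & 1), k + ((b >> 2) & 1));
          if (vals[b] > iso) ++nin0;
        }
        if (nin0 == 0 || nin0 == 8) continue;   // no crossing in this cube
        for (int m = 0; m < 4; ++m) {
          for (int p = 0; p < 6; ++p) {
            int lab[4] = {0, PERMS[p][0], PERMS[p][0] | PERMS[p][1], 7};
            double vx[4][3], tv[4];
            int inb[4], nin = 0;
            for (int t = 0; t < 4; ++t) {
              int b = lab[t] ^ m;
              vx[t][0] = (i + (b & 1)) * sx;
              vx[t][1] = (j + ((b >> 1) & 1)) * sy;
              vx[t][2] = (k + ((b >> 2) & 1)) * sz;
              tv[t] = vals[b];
              inb[t] = tv[t] > iso ? 1 : 0;
              nin += inb[t];
            }
            if (nin == 0 || nin == 4) continue;
            auto crossing = [&](int a, int b2, double *out) {
              double t2 = (iso - tv[a]) / (tv[b2] - tv[a]);
              for (int d2 = 0; d2 < 3; ++d2)
                out[d2] = vx[a][d2] + t2 * (vx[b2][d2] - vx[a][d2]);
            };
            // emit a triangle oriented so its normal points away from `ref`
            auto emit = [&](double *a, double *b2, double *c, double *ref) {
              double u[3], w[3], nrm[3], cen[3];
              for (int d2 = 0; d2 < 3; ++d2) {
                u[d2] = b2[d2] - a[d2];
                w[d2] = c[d2] - a[d2];
                cen[d2] = (a[d2] + b2[d2] + c[d2]) / 3.0 - ref[d2];
              }
              nrm[0] = u[1] * w[2] - u[2] * w[1];
              nrm[1] = u[2] * w[0] - u[0] * w[2];
              nrm[2] = u[0] * w[1] - u[1] * w[0];
              double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
              double amag = 0.5 * std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] +
                                            nrm[2] * nrm[2]);
              area += amag;
              // signed contribution a . (b x c) with outward orientation
              double bxc0 = b2[1] * c[2] - b2[2] * c[1];
              double bxc1 = b2[2] * c[0] - b2[0] * c[2];
              double bxc2 = b2[0] * c[1] - b2[1] * c[0];
              double s6 = a[0] * bxc0 + a[1] * bxc1 + a[2] * bxc2;
              vol6 += (dot >= 0) ? s6 : -s6;
            };
            if (nin == 1 || nin == 3) {
              int apex = -1;
              for (int t = 0; t < 4; ++t)
                if ((nin == 1 && inb[t]) || (nin == 3 && !inb[t])) apex = t;
              int others[3], c2 = 0;
              for (int t = 0; t < 4; ++t) if (t != apex) others[c2++] = t;
              double p1[3], p2[3], p3[3];
              crossing(apex, others[0], p1);
              crossing(apex, others[1], p2);
              crossing(apex, others[2], p3);
              // orientation reference: an inside vertex
              double *ref = (nin == 1) ? vx[apex] : vx[others[0]];
              if (nin == 3 && !inb[others[0]]) ref = vx[others[1]];
              emit(p1, p2, p3, ref);
            } else { // nin == 2
              int in2[2], out2[2], ci = 0, co = 0;
              for (int t = 0; t < 4; ++t) {
                if (inb[t]) in2[ci++] = t; else out2[co++] = t;
              }
              double mac[3], mad[3], mbd[3], mbc[3];
              crossing(in2[0], out2[0], mac);
              crossing(in2[0], out2[1], mad);
              crossing(in2[1], out2[1], mbd);
              crossing(in2[1], out2[0], mbc);
              emit(mac, mad, mbd, vx[in2[0]]);
              emit(mac, mbd, mbc, vx[in2[0]]);
            }
          }
        }
      }
  return NumericVector::create(std::fabs(vol6) / 6.0 / 4.0, area / 4.0);
}

// Affine resampling. For each output voxel index q (0-based), source voxel
// coordinate s = A q + b in the input index space. method: 0 = trilinear with
// clamp-to-border, 1 = nearest neighbour with constant 0 outside.
// Source coordinates within 1e-9 of a lattice point are snapped so identity
// transforms are exact.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector img, IntegerVector dim,
                                  NumericMatrix A, NumericVector b,
                                  IntegerVector outdim, int method) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double s[3];
        for (int d = 0; d < 3; ++d) {
          s[d] = A(d, 0) * i + A(d, 1) * j + A(d, 2) * k + b[d];
          double r = std::round(s[d]);
          if (std::fabs(s[d] - r) < 1e-9) s[d] = r;
        }
        R_xlen_t v = i + (R_xlen_t)ox * (j + (R_xlen_t)oy * k);
        if (method == 1) {
          int ii = (int)std::round(s[0]);
          int jj = (int)std::round(s[1]);
          int kk = (int)std::round(s[2]);
          out[v] = ingrid(ii, jj, kk, nx, ny, nz)
                     ? img[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]
                     : 0.0;
        } else {
          out[v] = sample_trilinear(img, nx, ny, nz, s[0], s[1], s[2]);
        }
      }
  out.attr("dim") = outdim;
  return out;
}

// Second-largest eigenvalue sqrt of the GLCM "Q" matrix per direction (MCC).
// p: ng x ng x 13 normalized symmetric probabilities. Uses the similarity of
// Q to the symmetric B B^T with B = p_ij / sqrt(px_i px_j-col); the leading
// eigenvector sqrt(px) is deflated and the second eigenvalue found by power
// iteration. Levels with zero marginal are dropped.
// [[Rcpp::export]]
NumericVector cpp_glcm_mcc(NumericVector p, int ng) {
  NumericVector out(13);
  for (int d = 0; d < 13; ++d) {
    R_xlen_t off = (R_xlen_t)ng * ng * d;
    std::vector<double> px(ng, 0.0);
    for (int j = 0; j < ng; ++j)
      for (int i = 0; i < ng; ++i) px[i] += p[off + i + (R_xlen_t)ng * j];
    std::vector<int> keep;
    for (int i = 0; i < ng; ++i) if (px[i] > 0) keep.push_back(i);
    int m = (int)keep.size();
    if (m <= 1) { out[d] = 1.0; continue; }
    std::vector<double> B((size_t)m * m), u(m), w(m), tmp(m);
    double un = 0.0;
    for (int a = 0; a < m; ++a) { u[a] = std::sqrt(px[keep[a]]); un += px[keep[a]]; }
    un = std::sqrt(un);
    for (int a = 0; a < m; ++a) u[a] /= un;
    for (int a = 0; a < m; ++a)
      for (int c = 0; c < m; ++c)
        B[a + (size_t)m * c] = p[off + keep[a] + (R_xlen_t)ng * keep[c]] /
                               std::sqrt(px[keep[a]] * px[keep[c]]);
    // deterministic start vector orthogonal-ish to u
    for (int a = 0; a < m; ++a) w[a] = (a % 2 ? 1.0 : -1.0) + 0.1 * a / m;
    double lam = 0.0;
    for (int it = 0; it < 500; ++it) {
      double du = 0.0;
      for (int a = 0; a < m; ++a) du += u[a] * w[a];
      for (int a = 0; a < m; ++a) w[a] -= du * u[a];
      // tmp = B^T w ; w2 = B tmp  (B symmetric here, but keep generic)
      for (int c = 0; c < m; ++c) {
        double acc = 0.0;
        for (int a = 0; a < m; ++a) acc += B[a + (size_t)m * c] * w[a];
        tmp[c] = acc;
      }
      double nrm = 0.0, lamnew = 0.0;
      for (int a = 0; a < m; ++a) {
        double acc = 0.0;
        for (int c = 0; c < m; ++c) acc += B[a + (size_t)m * c] * tmp[c];
        w[a] = acc;
        nrm += acc * acc;
      }
      nrm = std::sqrt(nrm);
      if (nrm <= 0) { lam = 0.0; break; }
      for (int a = 0; a < m; ++a) w[a] /= nrm;
      lamnew = nrm; // ||B B^T w|| with ||w||=1 converges to lambda2(BB^T)
      if (it > 5 && std::fabs(lamnew - lam) < 1e-12 * std::max(1.0, lamnew)) {
        lam = lamnew; break;
      }
      lam = lamnew;
    }
    out[d] = std::sqrt(std::max(0.0, lam));
  }
  return out;
}

// Separable 1D convolution along an axis. circular: periodic wrap;
// otherwise clamp-to-border. correlate: y[n] = sum_k f[k] x[n + (k-1) - off]
// with off = 0 for convolution (y[n] = sum f[k] x[n-(k-1)]) matching the
// R-side filter conventions; `center` shifts the kernel origin.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector img, IntegerVector dim,
                            NumericVector kernel, int axis, bool circular,
                            bool correlate, int center) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  int kl = kernel.size();
  R_xlen_t tot = (R_xlen_t)nx * ny * nz;
  NumericVector out(tot);
  R_xlen_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= n[a];
  R_xlen_t nline = tot / len;
  std::vector<double> line(len), res(len);
  // iterate all 1D lines along `axis`
  for (R_xlen_t l = 0; l < nline; ++l) {
    // decompose l into (pre, post) indices around the axis
    R_xlen_t pre = l % stride;
    R_xlen_t post = l / stride;
    R_xlen_t base = pre + post * stride * len;
    for (int t = 0; t < len; ++t) line[t] = img[base + (R_xlen_t)t * stride];
    for (int t = 0; t < len; ++t) {
      double acc = 0.0;
      for (int k = 0; k < kl; ++k) {
        int offset = correlate ? (k - center) : -(k - center);
        int src = t + offset;
        if (circular) {
          src %= len; if (src < 0) src += len;
        } else {
          if (src < 0) src = 0; else if (src >= len) src = len - 1;
        }
        acc += kernel[k] * line[src];
      }
      res[t] = acc;
    }
    for (int t = 0; t < len; ++t) out[base + (R_xlen_t)t * stride] = res[t];
  }
  out.attr("dim") = dim;
  return out;
}

// Sparse symmetric GLCM: returns triplets (dir 1..13, level_i, level_j,
// count) with both orders of each pair counted.
// [[Rcpp::export]]
List cpp_glcm_sparse(IntegerVector levels, LogicalVector mask,
                     IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> od, oi, oj; std::vector<double> on;
  std::vector<double> dense((size_t)ng * ng);
  std::vector<R_xlen_t> touched;
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    touched.clear();
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (!mask[v]) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (!ingrid(ii, jj, kk, nx, ny, nz)) continue;
          R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (!mask[w]) continue;
          int a = levels[v] - 1, b = levels[w] - 1;
          R_xlen_t c1 = a + (R_xlen_t)ng * b, c2 = b + (R_xlen_t)ng * a;
          if (dense[c1] == 0) touched.push_back(c1);
          dense[c1] += 1.0;
          if (c2 != c1) {
            if (dense[c2] == 0) touched.push_back(c2);
            dense[c2] += 1.0;
          }
        }
    for (R_xlen_t c : touched) {
      od.push_back(d + 1);
      oi.push_back((int)(c % ng) + 1);
      oj.push_back((int)(c / ng) + 1);
      on.push_back(dense[c]);
      dense[c] = 0.0;
    }
  }
  return List::create(_["dir"] = wrap(od), _["i"] = wrap(oi),
                      _["j"] = wrap(oj), _["n"] = wrap(on));
}

// count of eigenvalues of a symmetric tridiagonal matrix < x (Sturm)
static int sturm_count(const std::vector<double> &a,
                       const std::vector<double> &b, double x) {
  int cnt = 0;
  double q = 1.0;
  int k = (int)a.size();
  for (int i = 0; i < k; ++i) {
    double bb = i > 0 ? b[i - 1] * b[i - 1] : 0.0;
    q = a[i] - x - (q != 0 ? bb / q : bb / 1e-300);
    if (q < 0) ++cnt;
  }
  return cnt;
}

// MCC per direction from sparse GLCM triplets: second-largest eigenvalue
// sqrt of Q, computed as the largest eigenvalue of the deflated symmetric
// B B^T via Lanczos on the sparse B.
// [[Rcpp::export]]
NumericVector cpp_glcm_mcc_sparse(IntegerVector dir, IntegerVector li,
                                  IntegerVector lj, NumericVector cnt,
                                  int ng) {
  NumericVector out(13);
  R_xlen_t nt = dir.size();
  std::vector<int> map(ng + 1);
  for (int d = 1; d <= 13; ++d) {
    // gather triplets of this direction
    std::vector<int> ti, tj; std::vector<double> tp;
    double tot = 0.0;
    std::vector<double> pxfull(ng + 1, 0.0);
    for (R_xlen_t t = 0; t < nt; ++t) {
      if (dir[t] != d) continue;
      ti.push_back(li[t]); tj.push_back(lj[t]); tp.push_back(cnt[t]);
      pxfull[li[t]] += cnt[t];
      tot += cnt[t];
    }
    if (tot == 0) { out[d - 1] = 1.0; continue; }
    std::fill(map.begin(), map.end(), -1);
    int m = 0;
    for (int l = 1; l <= ng; ++l) if (pxfull[l] > 0) map[l] = m++;
    if (m <= 1) { out[d - 1] = 1.0; continue; }
    std::vector<double> px(m);
    for (int l = 1; l <= ng; ++l)
      if (map[l] >= 0) px[map[l]] = pxfull[l] / tot;
    size_t nnz = tp.size();
    std::vector<int> bi(nnz), bj(nnz);
    std::vector<double> bv(nnz);
    for (size_t t = 0; t < nnz; ++t) {
      bi[t] = map[ti[t]]; bj[t] = map[tj[t]];
      bv[t] = (tp[t] / tot) / std::sqrt(px[bi[t]] * px[bj[t]]);
    }
    std::vector<double> u(m);
    for (int a = 0; a < m; ++a) u[a] = std::sqrt(px[a]);
    auto matvec = [&](const std::vector<double> &v, std::vector<double> &y) {
      std::fill(y.begin(), y.end(), 0.0);
      for (size_t t = 0; t < nnz; ++t) y[bi[t]] += bv[t] * v[bj[t]];
    };
    int kmax = std::min(m - 1, 60);
    std::vector<std::vector<double>> V;
    std::vector<double> alpha, beta;
    std::vector<double> v(m), w(m), tmp(m);
    for (int a = 0; a < m; ++a) v[a] = ((a * 2654435761u) % 1000) / 1000.0 - 0.5;
    auto orth = [&](std::vector<double> &x) {
      double du = 0.0;
      for (int a = 0; a < m; ++a) du += u[a] * x[a];
      for (int a = 0; a < m; ++a) x[a] -= du * u[a];
      for (const auto &q : V) {
        double dq = 0.0;
        for (int a = 0; a < m; ++a) dq += q[a] * x[a];
        for (int a = 0; a < m; ++a) x[a] -= dq * q[a];
      }
    };
    orth(v);
    double nv = 0.0;
    for (int a = 0; a < m; ++a) nv += v[a] * v[a];
    nv = std::sqrt(nv);
    if (nv < 1e-14) { out[d - 1] = 0.0; continue; }
    for (int a = 0; a < m; ++a) v[a] /= nv;
    for (int k = 0; k < kmax; ++k) {
      matvec(v, tmp);       // tmp = B v
      matvec(tmp, w);       // w = B^2 v = (B B^T) v  (B symmetric)
      double al = 0.0;
      for (int a = 0; a < m; ++a) al += v[a] * w[a];
      alpha.push_back(al);
      for (int a = 0; a < m; ++a) w[a] -= al * v[a];
      if (!V.empty()) {
        const auto &prev = V.back();
        double bprev = beta.empty() ? 0.0 : beta.back();
        for (int a = 0; a < m; ++a) w[a] -= bprev * prev[a];
      }
      V.push_back(v);
      orth(w);
      double bn = 0.0;
      for (int a = 0; a < m; ++a) bn += w[a] * w[a];
      bn = std::sqrt(bn);
      if (bn < 1e-12 || k == kmax - 1) break;
      beta.push_back(bn);
      for (int a = 0; a < m; ++a) v[a] = w[a] / bn;
    }
    // largest eigenvalue of tridiagonal (alpha, beta) by bisection
    int kk = (int)alpha.size();
    double hi = 0.0, lo = 0.0;
    for (int i2 = 0; i2 < kk; ++i2) {
      double r = std::fabs(alpha[i2]);
      if (i2 > 0) r += std::fabs(beta[i2 - 1]);
      if (i2 < kk - 1) r += std::fabs(beta[i2]);
      hi = std::max(hi, r);
    }
    lo = -hi;
    for (int it = 0; it < 200 && hi - lo > 1e-11 * std::max(1.0, hi); ++it) {
      double mid = 0.5 * (lo + hi);
      if (sturm_count(alpha, beta, mid) >= kk) hi = mid; else lo = mid;
    }
    out[d - 1] = std::sqrt(std::max(0.0, 0.5 * (lo + hi)));
  }
  return out;
}

// Maximum pairwise distances of boundary-voxel centres: 3D plus the three
// in-plane diameters (pairs sharing the same z / y / x index).
// coords: n x 3 integer voxel indices; spacing in mm.
// [[Rcpp::export]]
NumericVector cpp_max_diameters(IntegerMatrix coords, NumericVector spacing) {
  int n = coords.nrow();
  double best3 = 0, bz = 0, by = 0, bx = 0;
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int a = 0; a < n; ++a) {
    double ax = coords(a, 0) * sx, ay = coords(a, 1) * sy,
           az = coords(a, 2) * sz;
    for (int b = a + 1; b < n; ++b) {
      double dx = ax - coords(b, 0) * sx;
      double dy = ay - coords(b, 1) * sy;
      double dz = az - coords(b, 2) * sz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best3) best3 = d2;
      if (coords(a, 2) == coords(b, 2)) {
        double p = dx * dx + dy * dy;
        if (p > bz) bz = p;
      }
      if (coords(a, 1) == coords(b, 1)) {
        double p = dx * dx + dz * dz;
        if (p > by) by = p;
      }
      if (coords(a, 0) == coords(b, 0)) {
        double p = dy * dy + dz * dz;
        if (p > bx) bx = p;
      }
    }
  }
  return NumericVector::create(std::sqrt(best3), std::sqrt(bz),
                               std::sqrt(by), std::sqrt(bx));
}

// All 22 non-MCC GLCM features per direction from sparse triplets.
// Returns 13 x 22 matrix; rows with no pairs are filled with NA and skipped
// on the R side. Column order documented in R/features.R.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_feats(IntegerVector dir, IntegerVector li,
                             IntegerVector lj, NumericVector cnt, int ng) {
  NumericMatrix out(13, 22);
  std::fill(out.begin(), out.end(), NA_REAL);
  R_xlen_t nt = dir.size();
  std::vector<double> px(ng + 1);
  std::vector<double> pd(2 * ng + 2), ps(2 * ng + 2);
  for (int d = 1; d <= 13; ++d) {
    double tot = 0.0;
    for (R_xlen_t t = 0; t < nt; ++t) if (dir[t] == d) tot += cnt[t];
    if (tot == 0) continue;
    std::fill(px.begin(), px.end(), 0.0);
    std::fill(pd.begin(), pd.end(), 0.0);
    std::fill(ps.begin(), ps.end(), 0.0);
    for (R_xlen_t t = 0; t < nt; ++t) {
      if (dir[t] != d) continue;
      double p = cnt[t] / tot;
      px[li[t]] += p;
      pd[std::abs(li[t] - lj[t])] += p;
      ps[li[t] + lj[t]] += p;
    }
    double mu = 0.0, hx = 0.0, sig2 = 0.0;
    for (int l = 1; l <= ng; ++l) mu += l * px[l];
    for (int l = 1; l <= ng; ++l) {
      if (px[l] > 0) hx -= px[l] * std::log2(px[l]);
      sig2 += px[l] * (l - mu) * (l - mu);
    }
    double da = 0.0, dent = 0.0, dvar = 0.0, sument = 0.0, sumavg = 0.0;
    for (int k2 = 0; k2 <= ng - 1; ++k2) da += k2 * pd[k2];
    for (int k2 = 0; k2 <= ng - 1; ++k2) {
      if (pd[k2] > 0) dent -= pd[k2] * std::log2(pd[k2]);
      dvar += pd[k2] * (k2 - da) * (k2 - da);
    }
    for (int s = 2; s <= 2 * ng; ++s) {
      sumavg += s * ps[s];
      if (ps[s] > 0) sument -= ps[s] * std::log2(ps[s]);
    }
    double ac = 0, ct2 = 0, ct3 = 0, ct4 = 0, contrast = 0, id = 0, idm = 0,
           idmn = 0, idn = 0, invvar = 0, je = 0, jent = 0, maxprob = 0;
    for (R_xlen_t t = 0; t < nt; ++t) {
      if (dir[t] != d) continue;
      double p = cnt[t] / tot;
      double i = li[t], j = lj[t];
      double dm = i - j, ad = std::fabs(dm), sm = i + j - 2 * mu;
      ac += p * i * j;
      ct2 += p * sm * sm;
      ct3 += p * sm * sm * sm;
      ct4 += p * sm * sm * sm * sm;
      contrast += p * dm * dm;
      id += p / (1 + ad);
      idm += p / (1 + dm * dm);
      idmn += p / (1 + dm * dm / ((double)ng * ng));
      idn += p / (1 + ad / ng);
      if (ad > 0) invvar += p / (dm * dm);
      je += p * p;
      if (p > 0) jent -= p * std::log2(p);
      if (p > maxprob) maxprob = p;
    }
    double corr = sig2 > 1e-30 ? (ac - mu * mu) / sig2 : 1.0;
    double imc1 = hx > 0 ? (jent - 2 * hx) / hx : 0.0;
    double imc2 = std::sqrt(std::max(0.0, 1 - std::exp(-2 * (2 * hx - jent))));
    double vals[22] = {ac, mu, ct4, ct3, ct2, contrast, corr, da, dent, dvar,
                       id, idm, idmn, idn, imc1, imc2, invvar, je, jent,
                       maxprob, sumavg, sument};
    for (int c = 0; c < 22; ++c) out(d - 1, c) = vals[c];
  }
  return out;
}

// companion: per-direction marginal variance (SumSquares) from triplets
// [[Rcpp::export]]
NumericVector cpp_glcm_sumsq(IntegerVector dir, IntegerVector li,
                             IntegerVector lj, NumericVector cnt, int ng) {
  NumericVector out(13, NA_REAL);
  R_xlen_t nt = dir.size();
  std::vector<double> px(ng + 1);
  for (int d = 1; d <= 13; ++d) {
    double tot = 0.0;
    for (R_xlen_t t = 0; t < nt; ++t) if (dir[t] == d) tot += cnt[t];
    if (tot == 0) continue;
    std::fill(px.begin(), px.end(), 0.0);
    for (R_xlen_t t = 0; t < nt; ++t)
      if (dir[t] == d) px[li[t]] += cnt[t] / tot;
    double mu = 0.0, sig2 = 0.0;
    for (int l = 1; l <= ng; ++l) mu += l * px[l];
    for (int l = 1; l <= ng; ++l) sig2 += px[l] * (l - mu) * (l - mu);
    out[d - 1] = sig2;
  }
  return out;
}

// 16 GLRLM features per direction, computed from run counts accumulated in
// a reused sparse scratch. Returns 16 x 13 matrix (columns = directions).
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_feats(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim, int ng, double np) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericMatrix out(16, 13);
  std::vector<double> dense((size_t)ng * maxlen);
  std::vector<size_t> touched;
  std::vector<double> ri(ng + 1), rj(maxlen + 1);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    touched.clear();
    auto add_run = [&](int lev, int len) {
      size_t c = (lev - 1) + (size_t)ng * (len - 1);
      if (dense[c] == 0) touched.push_back(c);
      dense[c] += 1.0;
    };
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (ingrid(i - dx, j - dy, k - dz, nx, ny, nz)) continue;
          int curlev = -1, runlen = 0;
          int ii = i, jj = j, kk = k;
          while (ingrid(ii, jj, kk, nx, ny, nz)) {
            R_xlen_t v = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            int lev = mask[v] ? levels[v] : -1;
            if (lev == curlev && lev > 0) ++runlen;
            else {
              if (curlev > 0) add_run(curlev, runlen);
              curlev = lev; runlen = 1;
            }
            ii += dx; jj += dy; kk += dz;
          }
          if (curlev > 0) add_run(curlev, runlen);
        }
    double nr = 0.0;
    for (size_t c : touched) nr += dense[c];
    if (nr == 0) { for (int f = 0; f < 16; ++f) out(f, d) = 0; continue; }
    std::fill(ri.begin(), ri.end(), 0.0);
    std::fill(rj.begin(), rj.end(), 0.0);
    double sre = 0, lre = 0, lgl = 0, hgl = 0, srlgl = 0, srhgl = 0,
           lrlgl = 0, lrhgl = 0, rent = 0;
    double mu_i = 0, mu_j = 0;
    for (size_t c : touched) {
      double P = dense[c];
      int lev = (int)(c % ng) + 1;
      int len = (int)(c / ng) + 1;
      double p = P / nr;
      double i2 = (double)lev * lev, j2 = (double)len * len;
      ri[lev] += P; rj[len] += P;
      sre += P / j2; lre += P * j2;
      lgl += P / i2; hgl += P * i2;
      srlgl += P / (i2 * j2); srhgl += P * i2 / j2;
      lrlgl += P * j2 / i2; lrhgl += P * i2 * j2;
      rent -= p * std::log2(p);
      mu_i += p * lev; mu_j += p * len;
    }
    double gln = 0, rln = 0, glv = 0, rv = 0;
    for (int l = 1; l <= ng; ++l) {
      gln += ri[l] * ri[l];
      glv += ri[l] / nr * (l - mu_i) * (l - mu_i);
    }
    for (int l = 1; l <= maxlen; ++l) {
      rln += rj[l] * rj[l];
      rv += rj[l] / nr * (l - mu_j) * (l - mu_j);
    }
    double vals[16] = {sre / nr, lre / nr, gln / nr, gln / (nr * nr),
                       rln / nr, rln / (nr * nr), nr / np, glv, rv, rent,
                       lgl / nr, hgl / nr, srlgl / nr, srhgl / nr,
                       lrlgl / nr, lrhgl / nr};
    for (int f = 0; f < 16; ++f) out(f, d) = vals[f];
    for (size_t c : touched) dense[c] = 0.0;
  }
  return out;
}
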