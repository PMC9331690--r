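// Low-level kernels for 3D texture matrices, connected components and
// the marching-tetrahedra lesion surface. Arrays arrive as R arrays in
// column-major order: linear index i + nx*(j + ny*k), zero-based here.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D directions (one per antipodal pair of the 26-neighborhood)
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline bool inb(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// lev: gray levels 1..Ng inside the mask, 0 outside.
// Returns Ng x Ng x 13 pair counts, symmetrized per direction.
// [[Rcpp::export(name = ".cpp_glcm_counts")]]
NumericVector cpp_glcm_counts(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *P = &out[d * ng * ng];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = lev[x + nx * (y + ny * z)];
          if (i == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inb(x2, y2, z2, nx, ny, nz)) continue;
          int j = lev[x2 + nx * (y2 + ny * z2)];
          if (j == 0) continue;
          P[(i - 1) + ng * (j - 1)] += 1.0;
          P[(j - 1) + ng * (i - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts: Ng x maxlen x 13, runs are maximal collinear
// sequences of equal level within the mask.
// [[Rcpp::export(name = ".cpp_glrlm_counts")]]
NumericVector cpp_glrlm_counts(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * lmax * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *P = &out[d * ng * lmax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = lev[x + nx * (y + ny * z)];
          if (i == 0) continue;
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inb(xp, yp, zp, nx, ny, nz) &&
              lev[xp + nx * (yp + ny * zp)] == i) continue; // not a run start
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (inb(xn, yn, zn, nx, ny, nz) &&
                 lev[xn + nx * (yn + ny * zn)] == i) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          P[(i - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, lmax, 13);
  return out;
}

// Dependence counts with tolerance alpha = 0: a neighbor is dependent
// iff it carries the same gray level; j = 1 + number of dependent
// 26-neighbors, so j ranges 1..27.
// [[Rcpp::export(name = ".cpp_gldm_counts")]]
NumericMatrix cpp_gldm_counts(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lev[x + nx * (y + ny * z)];
        if (i == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!inb(x2, y2, z2, nx, ny, nz)) continue;
              if (lev[x2 + nx * (y2 + ny * z2)] == i) ++dep;
            }
        out(i - 1, dep) += 1.0;
      }
  return out;
}

// 26-connected zones of constant gray level; returns two columns
// (level, size), one row per zone.
// [[Rcpp::export(name = ".cpp_glszm_zones")]]
IntegerMatrix cpp_glszm_zones(IntegerVector lev, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int s = 0; s < n; ++s) {
    if (lev[s] == 0 || seen[s]) continue;
    int val = lev[s], size = 0;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (!inb(x2, y2, z2, nx, ny, nz)) continue;
            int w = x2 + nx * (y2 + ny * z2);
            if (!seen[w] && lev[w] == val) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zl.push_back(val); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t r = 0; r < zl.size(); ++r) { out(r, 0) = zl[r]; out(r, 1) = zs[r]; }
  return out;
}

// Binary connected-component labels, connectivity 6 or 26.
// [[Rcpp::export(name = ".cpp_cc_label")]]
IntegerVector cpp_cc_label(IntegerVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear(); stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (manh == 0) continue;
            if (connectivity == 6 && manh != 1) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (!inb(x2, y2, z2, nx, ny, nz)) continue;
            int w = x2 + nx * (y2 + ny * z2);
            if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Marching tetrahedra over the half-voxel iso-surface of a binary mask
// sampled at voxel centers (caller pads by one zero layer). Each lattice
// cube is split into six tetrahedra sharing the main diagonal; with
// binary corner values all iso crossings sit at edge midpoints, so the
// clipped-volume fractions are exactly 0, 1/8, 1/2, 7/8, 1 for 0..4
// inside corners. Returns c(volume, area) in voxel units.
// [[Rcpp::export(name = ".cpp_march_tets")]]
NumericVector cpp_march_tets(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int CORNER[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  static const int TETS[6][4] = {
    {0,5,1,7},{0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7}
  };
  double volume = 0.0, area = 0.0;
  double P[4][3], M[4][3]; // tet corner coords; edge-midpoint scratch
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        int cv[8];
        int any = 0, all = 1;
        for (int c = 0; c < 8; ++c) {
          cv[c] = mask[(x + CORNER[c][0]) + nx * ((y + CORNER[c][1]) + ny * (z + CORNER[c][2]))] != 0;
          any |= cv[c]; all &= cv[c];
        }
        if (all) { volume += 1.0; continue; }
        if (!any) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], nin = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = TETS[t][c];
            in[c] = cv[cc]; nin += in[c];
            P[c][0] = x + CORNER[cc][0];
            P[c][1] = y + CORNER[cc][1];
            P[c][2] = z + CORNER[cc][2];
          }
          const double tv = 1.0 / 6.0;
          if (nin == 0) continue;
          if (nin == 4) { volume += tv; continue; }
          if (nin == 1 || nin == 3) {
            volume += (nin == 1) ? tv / 8.0 : tv * 7.0 / 8.0;
            // triangle through midpoints of the three edges at the lone vertex
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if ((nin == 1 && in[c]) || (nin == 3 && !in[c])) lone = c;
            int k = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == lone) continue;
              for (int a = 0; a < 3; ++a)
                M[k][a] = 0.5 * (P[lone][a] + P[c][a]);
              ++k;
            }
            double u[3], v[3], w[3];
            for (int a = 0; a < 3; ++a) { u[a] = M[1][a] - M[0][a]; v[a] = M[2][a] - M[0][a]; }
            w[0] = u[1]*v[2] - u[2]*v[1];
            w[1] = u[2]*v[0] - u[0]*v[2];
            w[2] = u[0]*v[1] - u[1]*v[0];
            area += 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
          } else { // nin == 2: quad section, half the tet inside
            volume += tv * 0.5;
            int ia[2], oa[2], ki = 0, ko = 0;
            for (int c = 0; c < 4; ++c) { if (in[c]) ia[ki++] = c; else oa[ko++] = c; }
            // quad m(ia0,oa0), m(ia0,oa1), m(ia1,oa1), m(ia1,oa0)
            int pairs[4][2] = {
              {ia[0], oa[0]}, {ia[0], oa[1]}, {ia[1], oa[1]}, {ia[1], oa[0]}
            };
            for (int q = 0; q < 4; ++q)
              for (int a = 0; a < 3; ++a)
                M[q][a] = 0.5 * (P[pairs[q][0]][a] + P[pairs[q][1]][a]);
            for (int half = 0; half < 2; ++half) {
              int i0 = 0, i1 = half ? 2 : 1, i2 = half ? 3 : 2;
              double u[3], v[3], w[3];
              for (int a = 0; a < 3; ++a) {
                u[a] = M[i1][a] - M[i0][a];
                v[a] = M[i2][a] - M[i0][a];
              }
              w[0] = u[1]*v[2] - u[2]*v[1];
              w[1] = u[2]*v[0] - u[0]*v[2];
              w[2] = u[0]*v[1] - u[1]*v[0];
              area += 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
            }
          }
        }
      }
  return NumericVector::create(volume, area);
}
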