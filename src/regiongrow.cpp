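// Greedy best-first region growing: starting from a seed voxel, grow a
// 26-connected region by repeatedly annexing the admissible frontier
// voxel with the highest score, until the region holds k voxels.
// Voxels with score = -Inf are never annexed. Returns a 0/1 array.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_region_grow")]]
IntegerVector cpp_region_grow(NumericVector score, IntegerVector dim,
                              int start, int k) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector out(n);
  std::vector<char> queued(n, 0);
  typedef std::pair<double, int> PQE;
  std::priority_queue<PQE> pq;
  pq.push(PQE(score[start], start));
  queued[start] = 1;
  int taken = 0;
  while (taken < k && !pq.empty()) {
    int v = pq.top().second; pq.pop();
    if (!R_finite(score[v])) break;
    out[v] = 1; ++taken;
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int w = x2 + nx * (y2 + ny * z2);
          if (!queued[w] && R_finite(score[w])) {
            queued[w] = 1;
            pq.push(PQE(score[w], w));
          }
        }
  }
  if (taken < k) return IntegerVector(0); // could not fit the request
  out.attr("dim") = dim;
  return out;
}
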