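#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Guo-Hall two-subiteration homotopic thinning, 8-connected foreground.
// Neighbour labels follow the usual clockwise convention:
//   p9 p2 p3
//   p8 p1 p4
//   p7 p6 p5
// with p2 one row up (smaller row index) and p4 one column right.
// [[Rcpp::export]]
LogicalMatrix thin_guo_hall(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = nr + 2, pc = nc + 2; // zero padding
  std::vector<unsigned char> a((size_t)pr * pc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      a[(size_t)(j + 1) * pr + (i + 1)] = img(i, j) ? 1 : 0;

  std::vector<size_t> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int j = 1; j <= nc; ++j) {
        for (int i = 1; i <= nr; ++i) {
          const size_t idx = (size_t)j * pr + i;
          if (!a[idx]) continue;
          const int p2 = a[idx - 1];
          const int p3 = a[idx + pr - 1];
          const int p4 = a[idx + pr];
          const int p5 = a[idx + pr + 1];
          const int p6 = a[idx + 1];
          const int p7 = a[idx - pr + 1];
          const int p8 = a[idx - pr];
          const int p9 = a[idx - pr - 1];
          const int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                        ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          if (C != 1) continue;
          const int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          const int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          const int N = std::min(N1, N2);
          if (N < 2 || N > 3) continue;
          const int m = (sub == 0) ? ((p6 | p7 | (!p9)) & p8)
                                   : ((p2 | p3 | (!p5)) & p4);
          if (m != 0) continue;
          del.push_back(idx);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) a[del[k]] = 0;
      }
    }
  }

  // cleanup: Guo-Hall can leave filled 2x2 blocks (e.g. at blob centres);
  // remove block pixels whose deletion keeps local connectivity (C == 1)
  // and which are not endpoints
  changed = true;
  while (changed) {
    changed = false;
    for (int j = 1; j <= nc; ++j) {
      for (int i = 1; i <= nr; ++i) {
        const size_t idx = (size_t)j * pr + i;
        if (!a[idx]) continue;
        bool in_block = false;
        for (int dj = -1; dj <= 0 && !in_block; ++dj)
          for (int di = -1; di <= 0 && !in_block; ++di) {
            const size_t b = idx + (size_t)dj * pr + di;
            if (a[b] && a[b + 1] && a[b + pr] && a[b + pr + 1]) in_block = true;
          }
        if (!in_block) continue;
        const int p2 = a[idx - 1], p3 = a[idx + pr - 1], p4 = a[idx + pr];
        const int p5 = a[idx + pr + 1], p6 = a[idx + 1], p7 = a[idx - pr + 1];
        const int p8 = a[idx - pr], p9 = a[idx - pr - 1];
        const int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                      ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
        const int n_nb = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (C == 1 && n_nb >= 2) { a[idx] = 0; changed = true; }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = a[(size_t)(j + 1) * pr + (i + 1)] != 0;
  return out;
}

// 3x3 median filter with replicate (edge-clamped) padding.
// [[Rcpp::export]]
NumericMatrix median_filter_3x3(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj; jj = jj < 0 ? 0 : (jj >= nc ? nc - 1 : jj);
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di; ii = ii < 0 ? 0 : (ii >= nr ? nr - 1 : ii);
          w[k++] = img(ii, jj);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}

// Connected-component labelling of a 3D logical array (ny, nx, nz),
// 26-connectivity (8-connectivity when nz == 1). Labels are 1..k in
// first-encounter order of the column-major scan, so the output is
// deterministic.
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, int ny, int nx, int nz) {
  const size_t n = (size_t)ny * nx * nz;
  if ((size_t)mask.size() != n) stop("mask length does not match dimensions");
  IntegerVector lab(mask.size(), 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back(); stack.pop_back();
      const int z = (int)(cur / ((size_t)ny * nx));
      const size_t r = cur % ((size_t)ny * nx);
      const int x = (int)(r / ny);
      const int y = (int)(r % ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dz && !dx && !dy) continue;
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            const size_t nb = (size_t)zz * ny * nx + (size_t)xx * ny + yy;
            if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
          }
        }
      }
    }
  }
  return lab;
}

// Count of 8-connected skeleton neighbours for every pixel of a logical
// matrix (zero outside).
// [[Rcpp::export]]
IntegerMatrix neighbour_count_8(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!img(i, j)) { out(i, j) = 0; continue; }
      int cnt = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj) continue;
          const int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          if (img(ii, jj)) ++cnt;
        }
      }
      out(i, j) = cnt;
    }
  }
  return out;
}

// splitmix64 finaliser; used to derive independent child seeds from one
// master seed so per-object draws do not depend on iteration order.
// [[Rcpp::export]]
double rng_child_seed(double seed, double stream) {
  uint64_t z = (uint64_t)seed * 0x9E3779B97F4A7C15ULL +
               (uint64_t)stream * 0xBF58476D1CE4E5B9ULL +
               0x94D049BB133111EBULL;
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return (double)(z % 2147483629ULL) + 1.0; // strictly below 2^31
}
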