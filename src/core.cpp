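#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Box counting: tile the grid from the top-left corner into e x e boxes
// (trailing boxes may be partial) and count boxes holding >= 1 foreground px.
// [[Rcpp::export]]
IntegerVector cpp_box_count(const LogicalMatrix& mask, const IntegerVector& sizes) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerVector out(sizes.size());
  for (int s = 0; s < sizes.size(); ++s) {
    const int e = sizes[s];
    if (e < 1) stop("box size must be >= 1");
    const int gc = (nc + e - 1) / e;
    std::vector<char> occ((size_t)((nr + e - 1) / e) * gc, 0);
    int count = 0;
    for (int j = 0; j < nc; ++j) {
      const int bj = j / e;
      for (int i = 0; i < nr; ++i) {
        if (mask(i, j)) {
          const size_t idx = (size_t)(i / e) * gc + bj;
          if (!occ[idx]) { occ[idx] = 1; ++count; }
        }
      }
    }
    out[s] = count;
  }
  return out;
}

// Nonlocal-means denoising, translation formulation: for every offset in the
// search window the per-pixel patch SSD is computed with an integral image,
// giving O(n_pixels * search^2) independent of patch size. Borders handled by
// edge replication. Weights w = exp(-SSD / (h^2 * patch^2)); the reference
// pixel itself contributes weight 1.
// [[Rcpp::export]]
NumericMatrix cpp_nlm_denoise(const NumericMatrix& img, double h, int patch, int search) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = patch / 2, sr = search / 2;
  const int pad = pr + sr;
  const int Pr = nr + 2 * pad, Pc = nc + 2 * pad;
  std::vector<double> P((size_t)Pr * Pc);
  for (int j = 0; j < Pc; ++j) {
    const int cj = std::min(std::max(j - pad, 0), nc - 1);
    for (int i = 0; i < Pr; ++i) {
      const int ci = std::min(std::max(i - pad, 0), nr - 1);
      P[(size_t)j * Pr + i] = img(ci, cj);
    }
  }
  std::vector<double> wsum((size_t)nr * nc, 1.0), acc((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      acc[(size_t)j * nr + i] = img(i, j);
  const double denom = h * h * (double)(patch * patch);
  // integral image of squared differences, (Pr+1) x (Pc+1)
  std::vector<double> S((size_t)(Pr + 1) * (Pc + 1));
  for (int dy = -sr; dy <= sr; ++dy) {
    for (int dx = -sr; dx <= sr; ++dx) {
      if (dx == 0 && dy == 0) continue;
      for (int j = 0; j <= Pc; ++j) S[(size_t)j * (Pr + 1)] = 0.0;
      for (int i = 0; i <= Pr; ++i) S[i] = 0.0;
      for (int j = 1; j <= Pc; ++j) {
        const size_t col = (size_t)j * (Pr + 1), colm = (size_t)(j - 1) * (Pr + 1);
        for (int i = 1; i <= Pr; ++i) {
          const int si = i - 1 + dy, sj = j - 1 + dx;
          double d = 0.0;
          if (si >= 0 && si < Pr && sj >= 0 && sj < Pc) {
            d = P[(size_t)(j - 1) * Pr + (i - 1)] - P[(size_t)sj * Pr + si];
            d *= d;
          }
          S[col + i] = d + S[colm + i] + S[col + i - 1] - S[colm + i - 1];
        }
      }
      for (int j0 = 0; j0 < nc; ++j0) {
        const int jp = j0 + pad;
        for (int i0 = 0; i0 < nr; ++i0) {
          const int ip = i0 + pad;
          const double ssd =
            S[(size_t)(jp + pr + 1) * (Pr + 1) + (ip + pr + 1)]
            - S[(size_t)(jp - pr) * (Pr + 1) + (ip + pr + 1)]
            - S[(size_t)(jp + pr + 1) * (Pr + 1) + (ip - pr)]
            + S[(size_t)(jp - pr) * (Pr + 1) + (ip - pr)];
          const double w = std::exp(-std::max(ssd, 0.0) / denom);
          const size_t k = (size_t)j0 * nr + i0;
          wsum[k] += w;
          acc[k] += w * P[(size_t)(jp + dx) * Pr + (ip + dy)];
        }
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = acc[(size_t)j * nr + i] / wsum[(size_t)j * nr + i];
  return out;
}

// Guo-Hall thinning to a 1-px skeleton (two-subiteration scheme).
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> M((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      M[(size_t)j * nr + i] = mask(i, j) ? 1 : 0;
  auto get = [&](int i, int j) -> int {
    return (i < 0 || i >= nr || j < 0 || j >= nc) ? 0 : M[(size_t)j * nr + i];
  };
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!M[(size_t)j * nr + i]) continue;
          const int p2 = get(i - 1, j),     p3 = get(i - 1, j + 1);
          const int p4 = get(i, j + 1),     p5 = get(i + 1, j + 1);
          const int p6 = get(i + 1, j),     p7 = get(i + 1, j - 1);
          const int p8 = get(i, j - 1),     p9 = get(i - 1, j - 1);
          const int C = ((!p2 && (p3 || p4)) + (!p4 && (p5 || p6)) +
                         (!p6 && (p7 || p8)) + (!p8 && (p9 || p2)));
          const int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          const int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          const int N = N1 < N2 ? N1 : N2;
          const int m = (iter == 0) ? ((p6 || p7 || !p9) && p8)
                                    : ((p2 || p3 || !p5) && p4);
          if (C == 1 && N >= 2 && N <= 3 && !m) del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k)
          M[(size_t)del[k].second * nr + del[k].first] = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = M[(size_t)j * nr + i] != 0;
  return out;
}

// 8-connected component labelling (BFS, labels 1..k in scan order).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Count of set 8-neighbours for each pixel of a binary image.
// [[Rcpp::export]]
IntegerMatrix cpp_count8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ni = i + di, nj = j + dj;
          if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && mask(ni, nj)) ++n;
        }
      out(i, j) = n;
    }
  }
  return out;
}

// Multi-source BFS label propagation inside a binary mask (8-connectivity).
// Seeds carry positive labels; every reachable mask pixel takes the label of
// the first seed front to arrive (FIFO; scan-order initialisation makes ties
// deterministic). Unreachable mask pixels stay 0.
// [[Rcpp::export]]
IntegerMatrix cpp_propagate_labels(const IntegerMatrix& seeds, const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc) stop("seed/mask shape mismatch");
  IntegerMatrix lab(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        q.push(std::make_pair(i, j));
      }
  while (!q.empty()) {
    const std::pair<int, int> p = q.front(); q.pop();
    const int l = lab(p.first, p.second);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int ni = p.first + di, nj = p.second + dj;
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (mask(ni, nj) && !lab(ni, nj)) {
          lab(ni, nj) = l;
          q.push(std::make_pair(ni, nj));
        }
      }
    }
  }
  return lab;
}

// Separable Gaussian blur, kernel truncated at 3 sigma, edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_gblur(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * h + 1);
  double ksum = 0.0;
  for (int i = -h; i <= h; ++i) {
    k[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + h];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= ksum;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0.0;
      for (int d = -h; d <= h; ++d) {
        int ii = std::min(std::max(i + d, 0), nr - 1);
        a += k[d + h] * img(ii, j);
      }
      tmp(i, j) = a;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0.0;
      for (int d = -h; d <= h; ++d) {
        int jj = std::min(std::max(j + d, 0), nc - 1);
        a += k[d + h] * tmp(i, jj);
      }
      out(i, j) = a;
    }
  return out;
}

// Rasterize capsule segments (thick line segments with round caps) onto a
// canvas by max-blending. segs columns: r0, c0, r1, c1, half_width, intensity
// (all in pixel units, 0-based).
// [[Rcpp::export]]
NumericMatrix cpp_draw_capsules(int nr, int nc, const NumericMatrix& segs) {
  NumericMatrix out(nr, nc);
  for (int s = 0; s < segs.nrow(); ++s) {
    const double r0 = segs(s, 0), c0 = segs(s, 1);
    const double r1 = segs(s, 2), c1 = segs(s, 3);
    const double hw = segs(s, 4), val = segs(s, 5);
    const int rlo = std::max(0, (int)std::floor(std::min(r0, r1) - hw - 1.0));
    const int rhi = std::min(nr - 1, (int)std::ceil(std::max(r0, r1) + hw + 1.0));
    const int clo = std::max(0, (int)std::floor(std::min(c0, c1) - hw - 1.0));
    const int chi = std::min(nc - 1, (int)std::ceil(std::max(c0, c1) + hw + 1.0));
    const double dr = r1 - r0, dc = c1 - c0;
    const double L2 = dr * dr + dc * dc;
    const double hw2 = hw * hw;
    for (int j = clo; j <= chi; ++j) {
      for (int i = rlo; i <= rhi; ++i) {
        double t = (L2 > 0.0) ? (((double)i - r0) * dr + ((double)j - c0) * dc) / L2 : 0.0;
        t = std::min(1.0, std::max(0.0, t));
        const double pr = r0 + t * dr - (double)i;
        const double pc = c0 + t * dc - (double)j;
        if (pr * pr + pc * pc <= hw2 && val > out(i, j)) out(i, j) = val;
      }
    }
  }
  return out;
}
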