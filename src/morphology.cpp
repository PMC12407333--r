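#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Grayscale background estimation by "rolling" a ball of the given radius
// under the image surface: a non-flat erosion followed by a non-flat
// dilation with the ball height profile. The returned matrix is the
// background; subtracting it preserves features narrower than the ball.
// [[Rcpp::export(name = ".rolling_ball_background")]]
NumericMatrix rolling_ball_background(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  int r = (int)std::floor(radius);
  // precompute ball height offsets (depth below the ball top)
  std::vector<int> dr, dc;
  std::vector<double> h;
  for (int i = -r; i <= r; ++i) {
    for (int j = -r; j <= r; ++j) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        dr.push_back(i);
        dc.push_back(j);
        h.push_back(radius - std::sqrt(radius * radius - d2));
      }
    }
  }
  int m = (int)h.size();
  NumericMatrix ero(nr, nc), bg(nr, nc);
  // erosion: ero(p) = min over ball of img(p+q) + h(q)
  for (int c = 0; c < nc; ++c) {
    for (int rI = 0; rI < nr; ++rI) {
      double best = std::numeric_limits<double>::infinity();
      for (int k = 0; k < m; ++k) {
        int rr = rI + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc) + h[k];
        if (v < best) best = v;
      }
      ero(rI, c) = best;
    }
  }
  // dilation: bg(p) = max over ball of ero(p+q) - h(q)
  for (int c = 0; c < nc; ++c) {
    for (int rI = 0; rI < nr; ++rI) {
      double best = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < m; ++k) {
        int rr = rI + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = ero(rr, cc) - h[k];
        if (v > best) best = v;
      }
      bg(rI, c) = best;
    }
  }
  return bg;
}

// Connected-component labelling of a logical mask with 4- or 8-connectivity
// (two-pass union-find). Labels are contiguous from 1 in raster order.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already visited in column-major order
      int nb[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int nnb = (connectivity == 8) ? 4 : 2;
      int lmin = 0;
      for (int k = 0; k < nnb; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (lmin == 0) lmin = l;
          else unite(lmin, l);
          if (l < lmin) lmin = l;
        }
      }
      if (lmin == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        lab(r, c) = lmin;
      }
    }
  }
  // flatten and relabel contiguously
  std::vector<int> newlab(next + 1, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find(l);
      if (newlab[root] == 0) newlab[root] = ++out;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}
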