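#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Euclidean distance from every TRUE pixel to the nearest FALSE pixel
// (pixel-centre to pixel-centre); Inf if the image has no FALSE pixel.
// A large finite sentinel replaces Inf inside dt1d: infinite parabola
// heights make the intersection abscissa -Inf and walk k out of bounds.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  const double BIG = 1e12;
  std::vector<double> g((size_t)nr * nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = img(i, j) ? BIG : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i)
      g[(size_t)i + (size_t)nr * j] = std::min(d[i], BIG);
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g[(size_t)i + (size_t)nr * j];
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j)
      out(i, j) = d[j] >= BIG / 2 ? R_PosInf : std::sqrt(d[j]);
  }
  return out;
}

// ---- Zhang-Suen thinning (topology-preserving skeleton) ----

// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<char> p((size_t)(nr + 2) * (nc + 2), 0);
  auto at = [&](int i, int j) -> char & {
    return p[(size_t)(i + 1) + (size_t)(nr + 2) * (j + 1)];
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) at(i, j) = img(i, j) ? 1 : 0;

  std::vector<std::pair<int, int>> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!at(i, j)) continue;
          // neighbours clockwise from north (p2..p9)
          char n[8] = {at(i - 1, j),     at(i - 1, j + 1), at(i, j + 1),
                       at(i + 1, j + 1), at(i + 1, j),     at(i + 1, j - 1),
                       at(i, j - 1),     at(i - 1, j - 1)};
          int B = 0;
          for (int q = 0; q < 8; ++q) B += n[q];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int q = 0; q < 8; ++q)
            if (!n[q] && n[(q + 1) % 8]) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (n[0] && n[2] && n[4]) continue;
            if (n[2] && n[4] && n[6]) continue;
          } else {
            if (n[0] && n[2] && n[6]) continue;
            if (n[0] && n[4] && n[6]) continue;
          }
          kill.push_back({i, j});
        }
      for (auto &ij : kill) at(ij.first, ij.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = at(i, j) != 0;
  return out;
}

// ---- connected-component labelling (BFS, 4- or 8-connectivity) ----

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx4[] = {-1, 1, 0, 0}, dy4[] = {0, 0, -1, 1};
  const int dx8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dy8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dx = connectivity == 4 ? dx4 : dx8;
  const int *dy = connectivity == 4 ? dy4 : dy8;
  int nd = connectivity;
  std::vector<int> qi, qj;
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = next;
      size_t head = 0;
      while (head < qi.size()) {
        int ci = qi[head], cj = qj[head];
        ++head;
        for (int q = 0; q < nd; ++q) {
          int ni = ci + dx[q], nj = cj + dy[q];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  return lab;
}
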