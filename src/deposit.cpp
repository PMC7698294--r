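#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static inline int wrapi(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// Sequential voxel deposition of ribbon fibers with flexibility-limited
// draping.  A fiber's bottom surface b is the minimal F-Lipschitz surface
// (4-neighbour graph distance within the footprint) lying on or above the
// current height map; F = 0 gives rigid bridging, large F full conformance.
//
// fibers: one row per candidate fiber, columns
//   0 w_vox, 1 l_vox, 2 t_vox, 3 flex, 4 cx, 5 cy, 6 angle
// Deposition stops once cumulative footprint coverage reaches target_cov
// (Inf places every candidate).  Existing state may be passed in via
// height_in/occ_in (occ_in of length 0 means an empty structure).
// [[Rcpp::export]]
List cpp_deposit(int nx, int ny,
                 IntegerVector height_in,
                 RawVector occ_in, int nz_in,
                 NumericMatrix fibers,
                 bool periodic,
                 double target_cov, double cov0) {
  const R_xlen_t ncol = (R_xlen_t)nx * ny;
  std::vector<int> height(ncol, 0);
  if (height_in.size() == ncol)
    for (R_xlen_t i = 0; i < ncol; ++i) height[i] = height_in[i];

  int nz = nz_in > 0 ? nz_in : 8;
  std::vector<uint8_t> occ((size_t)ncol * nz, 0);
  if (occ_in.size() > 0) {
    if ((int)(occ_in.size() / ncol) != nz_in)
      stop("occupancy length inconsistent with nz");
    for (R_xlen_t i = 0; i < occ_in.size(); ++i) occ[i] = occ_in[i] ? 1 : 0;
  }

  int nf = fibers.nrow();
  LogicalVector placed(nf, false);
  IntegerVector voxels(nf, 0), footprint(nf, 0), b_min(nf, NA_INTEGER),
      b_max(nf, NA_INTEGER);
  CharacterVector reason(nf, "");
  double cov = cov0;
  int n_attempted = 0;
  bool overlap_error = false;

  for (int k = 0; k < nf; ++k) {
    if (cov >= target_cov) break;
    n_attempted = k + 1;
    double w = fibers(k, 0), L = fibers(k, 1);
    int t = (int)fibers(k, 2);
    int F = (int)fibers(k, 3);
    double cx = fibers(k, 4), cy = fibers(k, 5), a = fibers(k, 6);
    double c = std::cos(a), s = std::sin(a);
    double ex = std::fabs(c) * L / 2 + std::fabs(s) * w / 2 + 1.5;
    double ey = std::fabs(s) * L / 2 + std::fabs(c) * w / 2 + 1.5;
    int x0 = (int)std::floor(cx - ex), x1 = (int)std::ceil(cx + ex);
    int y0 = (int)std::floor(cy - ey), y1 = (int)std::ceil(cy + ey);
    int bw = x1 - x0 + 1, bh = y1 - y0 + 1;
    std::vector<char> inF((size_t)bw * bh, 0);
    std::vector<int> bb((size_t)bw * bh, 0);
    std::vector<R_xlen_t> colv((size_t)bw * bh, -1);
    int ncell = 0;
    for (int iy = y0; iy <= y1; ++iy) {
      for (int ix = x0; ix <= x1; ++ix) {
        double u = (ix - cx) * c + (iy - cy) * s;
        double v = -(ix - cx) * s + (iy - cy) * c;
        if (u >= -L / 2 && u < L / 2 && v >= -w / 2 && v < w / 2) {
          int gx = ix, gy = iy;
          if (periodic) {
            gx = wrapi(ix, nx);
            gy = wrapi(iy, ny);
          } else if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) {
            continue;
          }
          size_t li = (size_t)(ix - x0) + (size_t)bw * (iy - y0);
          inF[li] = 1;
          colv[li] = (R_xlen_t)gx + (R_xlen_t)nx * gy;
          ++ncell;
        }
      }
    }
    if (ncell == 0 && periodic) {
      // sub-voxel fiber: occupy the voxel nearest the centre
      int gx = wrapi((int)std::lround(cx), nx);
      int gy = wrapi((int)std::lround(cy), ny);
      int lx = (int)std::lround(cx) - x0, ly = (int)std::lround(cy) - y0;
      if (lx >= 0 && lx < bw && ly >= 0 && ly < bh) {
        size_t li = (size_t)lx + (size_t)bw * ly;
        inF[li] = 1;
        colv[li] = (R_xlen_t)gx + (R_xlen_t)nx * gy;
        ncell = 1;
      }
    }
    if (ncell == 0) {
      reason[k] = "empty footprint after clipping";
      continue;
    }
    // rigid-to-rest drape: start at the support heights, propagate the
    // F-Lipschitz lower bound until the fixed point
    for (size_t li = 0; li < inF.size(); ++li)
      if (inF[li]) bb[li] = height[colv[li]];
    bool changed = true;
    int iter = 0, maxit = 4 * (bw + bh) + 8;
    while (changed && iter++ < maxit) {
      changed = false;
      for (int iy = 0; iy < bh; ++iy)
        for (int ix = 0; ix < bw; ++ix) {
          size_t li = (size_t)ix + (size_t)bw * iy;
          if (!inF[li]) continue;
          if (ix > 0 && inF[li - 1] && bb[li - 1] - F > bb[li]) {
            bb[li] = bb[li - 1] - F;
            changed = true;
          }
          if (iy > 0 && inF[li - bw] && bb[li - bw] - F > bb[li]) {
            bb[li] = bb[li - bw] - F;
            changed = true;
          }
        }
      for (int iy = bh - 1; iy >= 0; --iy)
        for (int ix = bw - 1; ix >= 0; --ix) {
          size_t li = (size_t)ix + (size_t)bw * iy;
          if (!inF[li]) continue;
          if (ix < bw - 1 && inF[li + 1] && bb[li + 1] - F > bb[li]) {
            bb[li] = bb[li + 1] - F;
            changed = true;
          }
          if (iy < bh - 1 && inF[li + bw] && bb[li + bw] - F > bb[li]) {
            bb[li] = bb[li + bw] - F;
            changed = true;
          }
        }
    }
    int btop = 0, blo = INT_MAX;
    for (size_t li = 0; li < inF.size(); ++li)
      if (inF[li]) {
        if (bb[li] > btop) btop = bb[li];
        if (bb[li] < blo) blo = bb[li];
      }
    if (btop + t > nz) {
      int newnz = nz;
      while (btop + t > newnz) newnz *= 2;
      occ.resize((size_t)ncol * newnz, 0);
      nz = newnz;
    }
    for (size_t li = 0; li < inF.size(); ++li) {
      if (!inF[li]) continue;
      R_xlen_t col = colv[li];
      for (int z = bb[li]; z < bb[li] + t; ++z) {
        size_t idx = (size_t)col + (size_t)ncol * z;
        if (occ[idx]) overlap_error = true;
        occ[idx] = 1;
      }
      if (bb[li] + t > height[col]) height[col] = bb[li] + t;
    }
    placed[k] = true;
    voxels[k] = ncell * t;
    footprint[k] = ncell;
    b_min[k] = blo;
    b_max[k] = btop;
    cov += (double)ncell / (double)ncol;
  }
  if (overlap_error)
    stop("internal error: fiber deposition overwrote a solid voxel");

  int hmax = 0;
  for (R_xlen_t i = 0; i < ncol; ++i)
    if (height[i] > hmax) hmax = height[i];
  int nz_out = hmax > 0 ? hmax : 1;
  RawVector occ_out((R_xlen_t)ncol * nz_out);
  for (R_xlen_t i = 0; i < occ_out.size(); ++i) occ_out[i] = occ[i];
  IntegerVector height_out(ncol);
  for (R_xlen_t i = 0; i < ncol; ++i) height_out[i] = height[i];

  return List::create(
      _["occ"] = occ_out, _["nz"] = nz_out, _["height"] = height_out,
      _["placed"] = placed, _["voxels"] = voxels, _["footprint"] = footprint,
      _["b_min"] = b_min, _["b_max"] = b_max, _["reason"] = reason,
      _["coverage"] = cov, _["n_attempted"] = n_attempted);
}
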