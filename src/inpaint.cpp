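// Fast-marching inpainting in the style of Telea (2004): masked pixels are
// filled in order of increasing distance T from the mask boundary (T solved by
// the eikonal update of the fast marching method). Each pixel is a normalized
// weighted average of already-known pixels inside a disk, the weight being the
// product of a direction factor (alignment with grad T), a geometric distance
// factor and a level-set proximity factor. Heap ties break by insertion order,
// so the fill is fully deterministic.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

namespace {

const int KNOWN = 0, BAND = 1, INSIDE = 2;

struct Node {
  double t; long serial; int idx;
};
struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.t != b.t) return a.t > b.t;          // min-heap on T
    return a.serial > b.serial;                // FIFO on ties
  }
};

inline double solve_pair(double t1, double t2) {
  // eikonal quadrant update with unit speed
  if (!R_FINITE(t1) && !R_FINITE(t2)) return R_PosInf;
  if (!R_FINITE(t2)) return t1 + 1.0;
  if (!R_FINITE(t1)) return t2 + 1.0;
  const double d = t1 - t2;
  if (std::fabs(d) >= 1.0) return std::min(t1, t2) + 1.0;
  return 0.5 * (t1 + t2 + std::sqrt(2.0 - d * d));
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_inpaint_telea(NumericVector img, IntegerMatrix mask,
                                int radius) {
  IntegerVector dim = img.attr("dim");
  const int H = dim[0], W = dim[1], C = dim[2];
  if (mask.nrow() != H || mask.ncol() != W) stop("mask/image shape mismatch");
  NumericVector out = clone(img);
  out.attr("dim") = img.attr("dim");

  std::vector<int> flag((size_t)H * W);
  std::vector<double> T((size_t)H * W);
  long n_inside = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const size_t k = (size_t)j * H + i;
      if (mask(i, j) != 0) { flag[k] = INSIDE; T[k] = R_PosInf; ++n_inside; }
      else { flag[k] = KNOWN; T[k] = 0.0; }
    }
  if (n_inside == 0) return out;
  if (n_inside == (long)H * W) stop("mask covers the whole image: nothing to inpaint from");

  std::priority_queue<Node, std::vector<Node>, NodeCmp> heap;
  long serial = 0;
  const int dn[4][2] = {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};

  auto solve_T = [&](int i, int j) -> double {
    auto tat = [&](int ii, int jj) -> double {
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) return R_PosInf;
      const size_t k = (size_t)jj * H + ii;
      return flag[k] == KNOWN ? T[k] : R_PosInf;
    };
    double best = R_PosInf;
    const double tu = tat(i - 1, j), td = tat(i + 1, j);
    const double tl = tat(i, j - 1), tr = tat(i, j + 1);
    best = std::min(best, solve_pair(tu, tl));
    best = std::min(best, solve_pair(tu, tr));
    best = std::min(best, solve_pair(td, tl));
    best = std::min(best, solve_pair(td, tr));
    return best;
  };

  // seed the narrow band with masked pixels bordering known ones
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const size_t k = (size_t)j * H + i;
      if (flag[k] != INSIDE) continue;
      bool border = false;
      for (int q = 0; q < 4 && !border; ++q) {
        const int ii = i + dn[q][0], jj = j + dn[q][1];
        if (ii >= 0 && ii < H && jj >= 0 && jj < W &&
            flag[(size_t)jj * H + ii] == KNOWN)
          border = true;
      }
      if (border) {
        const double t = solve_T(i, j);
        T[k] = t; flag[k] = BAND;
        heap.push({t, serial++, (int)k});
      }
    }

  auto inpaint_pixel = [&](int i, int j) {
    const size_t k = (size_t)j * H + i;
    // grad T at (i, j), one-sided where a neighbor is unknown
    auto tval = [&](int ii, int jj) -> double {
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) return R_PosInf;
      const size_t kk = (size_t)jj * H + ii;
      return flag[kk] == KNOWN ? T[kk] : R_PosInf;
    };
    const double t0 = T[k];
    double gx, gy;
    double ta = tval(i + 1, j), tb = tval(i - 1, j);
    if (R_FINITE(ta) && R_FINITE(tb)) gx = (ta - tb) * 0.5;
    else if (R_FINITE(ta)) gx = ta - t0;
    else if (R_FINITE(tb)) gx = t0 - tb;
    else gx = 0.0;
    ta = tval(i, j + 1); tb = tval(i, j - 1);
    if (R_FINITE(ta) && R_FINITE(tb)) gy = (ta - tb) * 0.5;
    else if (R_FINITE(ta)) gy = ta - t0;
    else if (R_FINITE(tb)) gy = t0 - tb;
    else gy = 0.0;

    std::vector<double> acc(C, 0.0);
    double wsum = 0.0;
    int rad = radius;
    while (true) {
      const int i0 = std::max(0, i - rad), i1 = std::min(H - 1, i + rad);
      const int j0 = std::max(0, j - rad), j1 = std::min(W - 1, j + rad);
      for (int jj = j0; jj <= j1; ++jj) {
        for (int ii = i0; ii <= i1; ++ii) {
          const size_t kk = (size_t)jj * H + ii;
          if (flag[kk] != KNOWN) continue;
          const double rx = (double)(i - ii), ry = (double)(j - jj);
          const double d2 = rx * rx + ry * ry;
          if (d2 > (double)rad * rad || d2 == 0.0) continue;
          const double d = std::sqrt(d2);
          double dirf = std::fabs(rx * gx + ry * gy) / d;
          if (dirf < 1e-6) dirf = 1e-6;
          const double dst = 1.0 / d2;
          const double lev = 1.0 / (1.0 + std::fabs(T[kk] - t0));
          const double w = dirf * dst * lev;
          wsum += w;
          for (int c = 0; c < C; ++c)
            acc[c] += w * out[(size_t)c * H * W + kk];
        }
      }
      if (wsum > 0.0 || rad >= std::max(H, W)) break;
      rad *= 2;  // isolated pixel: widen its neighborhood until someone is known
    }
    for (int c = 0; c < C; ++c) {
      double v = wsum > 0 ? acc[c] / wsum : out[(size_t)c * H * W + k];
      if (v < 0) v = 0; else if (v > 255) v = 255;
      out[(size_t)c * H * W + k] = v;
    }
  };

  while (!heap.empty()) {
    const Node nd = heap.top(); heap.pop();
    const size_t k = (size_t)nd.idx;
    if (flag[k] != BAND || nd.t != T[k]) continue;  // stale entry
    const int i = (int)(k % H), j = (int)(k / H);
    flag[k] = KNOWN;
    inpaint_pixel(i, j);
    for (int q = 0; q < 4; ++q) {
      const int ii = i + dn[q][0], jj = j + dn[q][1];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      const size_t kk = (size_t)jj * H + ii;
      if (flag[kk] == KNOWN) continue;
      const double t = solve_T(ii, jj);
      if (t < T[kk]) {
        T[kk] = t;
        flag[kk] = BAND;
        heap.push({t, serial++, (int)kk});
      } else if (flag[kk] == INSIDE) {
        T[kk] = t;
        flag[kk] = BAND;
        heap.push({t, serial++, (int)kk});
      }
    }
  }
  return out;
}
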