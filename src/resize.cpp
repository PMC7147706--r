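// Image resizing: bilinear with half-pixel centers for intensity images,
// nearest neighbor for label masks. Identity when the size is unchanged.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int oh, int ow) {
  IntegerVector dim = img.attr("dim");
  const int H = dim[0], W = dim[1], C = dim[2];
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)oh * ow * C));
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    const double* src = img.begin() + (size_t)c * H * W;
    double* dst = out.begin() + (size_t)c * oh * ow;
    for (int j = 0; j < ow; ++j) {
      double x = (j + 0.5) * sx - 0.5;
      if (x < 0) x = 0; if (x > W - 1) x = W - 1;
      const int x0 = (int)x, x1 = std::min(x0 + 1, W - 1);
      const double fx = x - x0;
      for (int i = 0; i < oh; ++i) {
        double y = (i + 0.5) * sy - 0.5;
        if (y < 0) y = 0; if (y > H - 1) y = H - 1;
        const int y0 = (int)y, y1 = std::min(y0 + 1, H - 1);
        const double fy = y - y0;
        const double v =
            (1 - fx) * ((1 - fy) * src[(size_t)x0 * H + y0] +
                        fy * src[(size_t)x0 * H + y1]) +
            fx * ((1 - fy) * src[(size_t)x1 * H + y0] +
                  fy * src[(size_t)x1 * H + y1]);
        dst[(size_t)j * oh + i] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_resize_nearest(IntegerMatrix m, int oh, int ow) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix out(oh, ow);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    int x = (int)((j + 0.5) * sx);
    if (x >= W) x = W - 1;
    for (int i = 0; i < oh; ++i) {
      int y = (int)((i + 0.5) * sy);
      if (y >= H) y = H - 1;
      out(i, j) = m(y, x);
    }
  }
  return out;
}
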