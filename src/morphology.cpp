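// Grayscale morphology over an arbitrary binary footprint with edge
// replication (out-of-image samples take the nearest border pixel), so the
// black top-hat gives no spurious response along image borders.
#include <Rcpp.h>
using namespace Rcpp;

static NumericMatrix morpho(const NumericMatrix& img, const IntegerMatrix& fp,
                            bool dilate) {
  const int H = img.nrow(), W = img.ncol();
  const int fh = fp.nrow(), fw = fp.ncol();
  if (fh % 2 == 0 || fw % 2 == 0) stop("footprint must have odd dimensions");
  const int ch = fh / 2, cw = fw / 2;
  std::vector<int> di, dj;
  for (int j = 0; j < fw; ++j)
    for (int i = 0; i < fh; ++i)
      if (fp(i, j) != 0) { di.push_back(i - ch); dj.push_back(j - cw); }
  if (di.empty()) stop("footprint has no foreground pixel");
  NumericMatrix out(H, W);
  const int K = (int)di.size();
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = dilate ? R_NegInf : R_PosInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
        if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
        const double p = img(ii, jj);
        if (dilate) { if (p > v) v = p; } else { if (p < v) v = p; }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(NumericMatrix img, IntegerMatrix fp) {
  return morpho(img, fp, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(NumericMatrix img, IntegerMatrix fp) {
  return morpho(img, fp, false);
}
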