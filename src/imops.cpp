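// Image primitives: 4-connected component labeling (union-find) and a
// separable convolution with edge clamping (used for Gaussian blur and
// box means).
#include <Rcpp.h>
using namespace Rcpp;

static int uf_find(std::vector<int> &par, int i) {
  while (par[i] != i) {
    par[i] = par[par[i]];
    i = par[i];
  }
  return i;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 4) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> par(1, 0);  // par[0] unused (background)
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x)) continue;
      // previously-scanned neighbors (column-major scan)
      int nbr[4];
      int nn = 0;
      if (y > 0 && mask(y - 1, x)) nbr[nn++] = lab(y - 1, x);
      if (x > 0 && mask(y, x - 1)) nbr[nn++] = lab(y, x - 1);
      if (connectivity == 8 && x > 0) {
        if (y > 0 && mask(y - 1, x - 1)) nbr[nn++] = lab(y - 1, x - 1);
        if (y < H - 1 && mask(y + 1, x - 1)) nbr[nn++] = lab(y + 1, x - 1);
      }
      if (nn == 0) {
        int nl = (int)par.size();
        par.push_back(nl);
        lab(y, x) = nl;
      } else {
        int r = uf_find(par, nbr[0]);
        for (int i = 1; i < nn; ++i) {
          int ri = uf_find(par, nbr[i]);
          if (ri != r) {
            par[std::max(r, ri)] = std::min(r, ri);
            r = std::min(r, ri);
          }
        }
        lab(y, x) = r;
      }
    }
  }
  // flatten + renumber 1..k in first-appearance order (column-major scan)
  std::vector<int> remap(par.size(), 0);
  int k = 0;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int l = lab(y, x);
      if (!l) continue;
      int r = uf_find(par, l);
      if (!remap[r]) remap[r] = ++k;
      lab(y, x) = remap[r];
    }
  return lab;
}

// [[Rcpp::export(name = ".conv_sep")]]
NumericMatrix conv_sep(NumericMatrix img, NumericVector kernel) {
  int H = img.nrow(), W = img.ncol(), K = kernel.size();
  int r = K / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int x = 0; x < W; ++x)  // vertical pass
    for (int y = 0; y < H; ++y) {
      double s = 0;
      for (int k = 0; k < K; ++k) {
        int yy = y + k - r;
        if (yy < 0) yy = 0;
        if (yy >= H) yy = H - 1;
        s += img(yy, x) * kernel[k];
      }
      tmp(y, x) = s;
    }
  for (int y = 0; y < H; ++y)  // horizontal pass
    for (int x = 0; x < W; ++x) {
      double s = 0;
      for (int k = 0; k < K; ++k) {
        int xx = x + k - r;
        if (xx < 0) xx = 0;
        if (xx >= W) xx = W - 1;
        s += tmp(y, xx) * kernel[k];
      }
      out(y, x) = s;
    }
  return out;
}
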