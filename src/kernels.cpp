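#include <Rcpp.h>
using namespace Rcpp;

// Dense-array kernels for the CNN-LSTM engine. Batches are column-major
// arrays (B, L, C); im2col rows are ordered batch-fastest (row = b + t*B),
// columns filter-offset-fastest (col = u + c*fw), matching the R-side layout.

// [[Rcpp::export(name = ".im2colC")]]
NumericMatrix im2colC(NumericVector X, int B, int L, int C, int fw) {
  int Lout = L - fw + 1;
  NumericMatrix XC(B * Lout, fw * C);
  double *x = X.begin(), *xc = XC.begin();
  for (int c = 0; c < C; ++c) {
    for (int u = 0; u < fw; ++u) {
      double *col = xc + (size_t)(u + c * fw) * B * Lout;
      for (int t = 0; t < Lout; ++t) {
        double *src = x + (size_t)c * B * L + (size_t)(t + u) * B;
        std::copy(src, src + B, col + (size_t)t * B);
      }
    }
  }
  return XC;
}

// [[Rcpp::export(name = ".col2imC")]]
NumericVector col2imC(NumericMatrix dXC, int B, int L, int C, int fw) {
  int Lout = L - fw + 1;
  NumericVector dX((size_t)B * L * C);
  double *dx = dX.begin(), *dxc = dXC.begin();
  for (int c = 0; c < C; ++c) {
    for (int u = 0; u < fw; ++u) {
      double *col = dxc + (size_t)(u + c * fw) * B * Lout;
      for (int t = 0; t < Lout; ++t) {
        double *dst = dx + (size_t)c * B * L + (size_t)(t + u) * B;
        double *src = col + (size_t)t * B;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(B, L, C);
  return dX;
}

// [[Rcpp::export(name = ".maxpoolFwdC")]]
List maxpoolFwdC(NumericVector X, int B, int L, int F, int p) {
  int Tn = L / p;
  NumericVector M((size_t)B * Tn * F);
  IntegerVector argm((size_t)B * Tn * F);
  double *x = X.begin(), *m = M.begin();
  int *am = argm.begin();
  for (int f = 0; f < F; ++f) {
    for (int t = 0; t < Tn; ++t) {
      size_t oBase = (size_t)f * B * Tn + (size_t)t * B;
      for (int b = 0; b < B; ++b) {
        double best = x[(size_t)f * B * L + (size_t)(t * p) * B + b];
        int bestU = 0;
        for (int u = 1; u < p; ++u) {
          double v = x[(size_t)f * B * L + (size_t)(t * p + u) * B + b];
          if (v > best) { best = v; bestU = u; }
        }
        m[oBase + b] = best;
        am[oBase + b] = bestU + 1;
      }
    }
  }
  M.attr("dim") = IntegerVector::create(B, Tn, F);
  argm.attr("dim") = IntegerVector::create(B, Tn, F);
  return List::create(_["out"] = M, _["argm"] = argm);
}

// [[Rcpp::export(name = ".maxpoolBwdC")]]
NumericVector maxpoolBwdC(NumericVector dOut, IntegerVector argm,
                          int B, int L, int F, int p) {
  int Tn = L / p;
  NumericVector dX((size_t)B * L * F);
  double *dx = dX.begin(), *dout = dOut.begin();
  int *am = argm.begin();
  for (int f = 0; f < F; ++f) {
    for (int t = 0; t < Tn; ++t) {
      size_t oBase = (size_t)f * B * Tn + (size_t)t * B;
      for (int b = 0; b < B; ++b) {
        int u = am[oBase + b] - 1;
        dx[(size_t)f * B * L + (size_t)(t * p + u) * B + b] = dout[oBase + b];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(B, L, F);
  return dX;
}
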