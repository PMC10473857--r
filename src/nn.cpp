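// Native convolution and max-pooling kernels for the grain classifiers.
// Layout conventions (match R's column-major array flattening):
//   activations: 4-D array (H, W, C, N)
//   conv weights: matrix (k*k*C, F), column f = filter f flattened from a
//                 (k, k, C) array; spatial offset ky fastest, then kx, then c.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector dim4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline int outSize(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col for one sample: X (H x W x C) contiguous, zero padding.
static void im2col(const double* X, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& M) {
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  // M: (k*k*C) x (Ho*Wo), output pixel (ho, wo) -> column wo*Ho + ho
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* col = M.colptr(wo * Ho + ho);
      const int r0 = ho * stride - pad, c0 = wo * stride - pad;
      int t = 0;
      for (int c = 0; c < C; ++c) {
        const double* plane = X + (size_t)c * H * W;
        for (int kx = 0; kx < k; ++kx) {
          const int cc = c0 + kx;
          if (cc < 0 || cc >= W) {
            for (int ky = 0; ky < k; ++ky) col[t++] = 0.0;
          } else {
            const double* colX = plane + (size_t)cc * H;
            for (int ky = 0; ky < k; ++ky) {
              const int rr = r0 + ky;
              col[t++] = (rr < 0 || rr >= H) ? 0.0 : colX[rr];
            }
          }
        }
      }
    }
  }
}

// scatter-add of column gradients back to input layout
static void col2im(const arma::mat& dM, int H, int W, int C,
                   int k, int stride, int pad, double* dX) {
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* col = dM.colptr(wo * Ho + ho);
      const int r0 = ho * stride - pad, c0 = wo * stride - pad;
      int t = 0;
      for (int c = 0; c < C; ++c) {
        double* plane = dX + (size_t)c * H * W;
        for (int kx = 0; kx < k; ++kx) {
          const int cc = c0 + kx;
          if (cc < 0 || cc >= W) { t += k; continue; }
          double* colX = plane + (size_t)cc * H;
          for (int ky = 0; ky < k; ++ky) {
            const int rr = r0 + ky;
            if (rr >= 0 && rr < H) colX[rr] += col[t];
            ++t;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(const NumericVector& X, const NumericMatrix& Wm,
                       const NumericVector& b, int k, int stride, int pad) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = Wm.ncol();
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  arma::mat Wmat(const_cast<double*>(&Wm[0]), Wm.nrow(), F, false, true);
  arma::rowvec bias(const_cast<double*>(&b[0]), F, false, true);
  NumericVector Y = dim4(Ho, Wo, F, N);
  arma::mat M(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(&X[0] + (size_t)n * H * W * C, H, W, C, k, stride, pad, M);
    arma::mat Yn = M.t() * Wmat; // (Ho*Wo) x F
    Yn.each_row() += bias;
    std::copy(Yn.memptr(), Yn.memptr() + Yn.n_elem,
              &Y[0] + (size_t)n * Ho * Wo * F);
  }
  return Y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const NumericVector& X, const NumericMatrix& Wm,
              const NumericVector& dY, int k, int stride, int pad) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = Wm.ncol();
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  arma::mat Wmat(const_cast<double*>(&Wm[0]), Wm.nrow(), F, false, true);
  NumericVector dX = dim4(H, W, C, N);
  NumericMatrix dWout(k * k * C, F);
  NumericVector dbout(F);
  arma::mat dW(&dWout[0], k * k * C, F, false, true);
  arma::rowvec db(&dbout[0], F, false, true);
  arma::mat M(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(&X[0] + (size_t)n * H * W * C, H, W, C, k, stride, pad, M);
    arma::mat dYn(const_cast<double*>(&dY[0]) + (size_t)n * Ho * Wo * F,
                  Ho * Wo, F, false, true);
    dW += M * dYn;
    db += arma::sum(dYn, 0);
    arma::mat dM = Wmat * dYn.t(); // (k*k*C) x (Ho*Wo)
    col2im(dM, H, W, C, k, stride, pad, &dX[0] + (size_t)n * H * W * C);
  }
  return List::create(_["dX"] = dX, _["dW"] = dWout, _["db"] = dbout);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(const NumericVector& X, int k, int stride, int pad) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = outSize(H, k, stride, pad), Wo = outSize(W, k, stride, pad);
  NumericVector Y = dim4(Ho, Wo, C, N);
  IntegerVector amax(Y.size()); // 0-based linear index into X
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* Xn = &X[0] + (size_t)n * H * W * C;
    const size_t base = (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* plane = Xn + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int r0 = ho * stride - pad, c0 = wo * stride - pad;
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kx = 0; kx < k; ++kx) {
            const int cc = c0 + kx;
            if (cc < 0 || cc >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int rr = r0 + ky;
              if (rr < 0 || rr >= H) continue;
              double v = plane[(size_t)cc * H + rr];
              if (v > best) { best = v; bi = c * H * W + cc * H + rr; }
            }
          }
          // column-major output order is (ho, wo, c, n); we iterate c outer,
          // so index explicitly
          size_t oi = (size_t)n * Ho * Wo * C + (size_t)c * Ho * Wo +
                      (size_t)wo * Ho + ho;
          Y[oi] = best;
          amax[oi] = (int)(base + bi);
          (void)o;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(const NumericVector& dY, const IntegerVector& amax,
                          const IntegerVector& xdim) {
  NumericVector dX = dim4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < dY.size(); ++i) dX[amax[i]] += dY[i];
  return dX;
}
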