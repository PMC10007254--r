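// Dense compute kernels for the 1D-CNN engine.
//
// Layout conventions (column-major, matching R arrays):
//   signal arrays X : dim (length, channels, batch)
//   conv weights W  : (out_channels, kernel * in_channels); the column block
//                     for input channel c occupies columns [c*k, (c+1)*k).
// Convolutions and poolings are "valid" (unpadded); out_len =
// floor((in_len - k) / stride) + 1. Arrays are accessed through borrowed
// pointers (no conversion copies); matrix products go through BLAS via
// Armadillo views on the same memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::List;

static inline int out_length(int in_len, int k, int stride) {
  return (in_len - k) / stride + 1;
}

static void get_dim3(const NumericVector& X, int& L, int& C, int& B) {
  IntegerVector d = X.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array");
  L = d[0]; C = d[1]; B = d[2];
}

static NumericVector alloc3(int L, int C, int B) {
  NumericVector out(Rcpp::no_init((R_xlen_t)L * C * B));
  out.attr("dim") = IntegerVector::create(L, C, B);
  return out;
}

// im2col for one sample (x: L x C block) into col-major C (k*ci x len_out)
static void im2col_ptr(const double* x, int L, int C, int k, int stride,
                       int len_out, double* dst) {
  for (int j = 0; j < len_out; ++j) {
    const int t0 = j * stride;
    double* col = dst + (size_t)j * k * C;
    for (int c = 0; c < C; ++c) {
      const double* src = x + (size_t)c * L + t0;
      std::copy(src, src + k, col + (size_t)c * k);
    }
  }
}

static int pick_chunk(int batch, size_t per_sample) {
  int c = (int)(4000000 / per_sample + 1);
  if (c < 1) c = 1;
  if (c > batch) c = batch;
  return c;
}

// [[Rcpp::export]]
NumericVector nn_conv1d_fwd(const NumericVector& X, const NumericMatrix& W,
                            const NumericVector& b, int k, int stride) {
  int L, C, B;
  get_dim3(X, L, C, B);
  const int co = W.nrow();
  if (W.ncol() != k * C)
    Rcpp::stop("weight shape does not match kernel size and input channels");
  const int Lo = out_length(L, k, stride);
  if (Lo < 1) Rcpp::stop("input shorter than kernel");
  NumericVector Yout = alloc3(Lo, co, B);
  const arma::mat Wm(const_cast<double*>(W.begin()), co, k * C, false, true);
  const int chunk = pick_chunk(B, (size_t)k * C * Lo);
  arma::mat Cm(k * C, (size_t)Lo * chunk);
  for (int s0 = 0; s0 < B; s0 += chunk) {
    const int nc = std::min(chunk, B - s0);
    for (int s = 0; s < nc; ++s)
      im2col_ptr(X.begin() + (size_t)(s0 + s) * L * C, L, C, k, stride, Lo,
                 Cm.colptr((size_t)s * Lo));
    arma::mat Ym = Wm * Cm.cols(0, (size_t)nc * Lo - 1);  // co x (Lo*nc)
    // scatter into (Lo, co, batch) with bias
    for (int s = 0; s < nc; ++s) {
      double* yb = Yout.begin() + (size_t)(s0 + s) * Lo * co;
      for (int c = 0; c < co; ++c) {
        const double bc = b[c];
        double* dst = yb + (size_t)c * Lo;
        for (int j = 0; j < Lo; ++j)
          dst[j] = Ym(c, (size_t)s * Lo + j) + bc;
      }
    }
  }
  return Yout;
}

// [[Rcpp::export]]
List nn_conv1d_bwd(const NumericVector& X, const NumericMatrix& W,
                   const NumericVector& dY, int k, int stride,
                   bool need_dx = true) {
  int L, C, B;
  get_dim3(X, L, C, B);
  int Lo, co, B2;
  get_dim3(dY, Lo, co, B2);
  NumericVector dXout = need_dx ? alloc3(L, C, B) : alloc3(1, 1, 1);
  std::fill(dXout.begin(), dXout.end(), 0.0);
  const arma::mat Wm(const_cast<double*>(W.begin()), co, k * C, false, true);
  arma::mat dW(co, k * C, arma::fill::zeros);
  arma::vec db(co, arma::fill::zeros);
  const int chunk = pick_chunk(B, (size_t)k * C * Lo);
  arma::mat Cm(k * C, (size_t)Lo * chunk);
  arma::mat dYm(co, (size_t)Lo * chunk);
  for (int s0 = 0; s0 < B; s0 += chunk) {
    const int nc = std::min(chunk, B - s0);
    for (int s = 0; s < nc; ++s) {
      im2col_ptr(X.begin() + (size_t)(s0 + s) * L * C, L, C, k, stride, Lo,
                 Cm.colptr((size_t)s * Lo));
      const double* dyb = dY.begin() + (size_t)(s0 + s) * Lo * co;
      for (int c = 0; c < co; ++c)
        for (int j = 0; j < Lo; ++j)
          dYm(c, (size_t)s * Lo + j) = dyb[(size_t)c * Lo + j];
    }
    const arma::uword last = (size_t)nc * Lo - 1;
    dW += dYm.cols(0, last) * Cm.cols(0, last).t();
    db += arma::sum(dYm.cols(0, last), 1);
    if (need_dx) {
      arma::mat Cg = Wm.t() * dYm.cols(0, last);   // (k*C) x (Lo*nc)
      for (int s = 0; s < nc; ++s) {
        double* dxb = dXout.begin() + (size_t)(s0 + s) * L * C;
        for (int j = 0; j < Lo; ++j) {
          const double* col = Cg.colptr((size_t)s * Lo + j);
          const int t0 = j * stride;
          for (int c = 0; c < C; ++c) {
            double* dst = dxb + (size_t)c * L + t0;
            const double* srcp = col + (size_t)c * k;
            for (int kk = 0; kk < k; ++kk) dst[kk] += srcp[kk];
          }
        }
      }
    }
  }
  return List::create(Rcpp::Named("dX") = dXout,
                      Rcpp::Named("dW") = dW,
                      Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
List nn_maxpool1d_fwd(const NumericVector& X, int k, int stride) {
  int L, C, B;
  get_dim3(X, L, C, B);
  const int Lo = out_length(L, k, stride);
  if (Lo < 1) Rcpp::stop("input shorter than pool size");
  NumericVector Y = alloc3(Lo, C, B);
  IntegerVector amax(Rcpp::no_init((R_xlen_t)Lo * C * B));
  amax.attr("dim") = IntegerVector::create(Lo, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* x = X.begin() + ((size_t)s * C + c) * L;
      double* y = Y.begin() + ((size_t)s * C + c) * Lo;
      int* am = amax.begin() + ((size_t)s * C + c) * Lo;
      for (int j = 0; j < Lo; ++j) {
        const int t0 = j * stride;
        double best = x[t0];
        int bi = t0;
        for (int kk = 1; kk < k; ++kk)
          if (x[t0 + kk] > best) { best = x[t0 + kk]; bi = t0 + kk; }
        y[j] = best;
        am[j] = bi;                       // 0-based input index
      }
    }
  return List::create(Rcpp::Named("Y") = Y, Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export]]
NumericVector nn_maxpool1d_bwd(const NumericVector& dY,
                               const IntegerVector& amax, int len_in) {
  IntegerVector d = dY.attr("dim");
  const int Lo = d[0], C = d[1], B = d[2];
  NumericVector dX = alloc3(len_in, C, B);
  std::fill(dX.begin(), dX.end(), 0.0);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* dy = dY.begin() + ((size_t)s * C + c) * Lo;
      const int* am = amax.begin() + ((size_t)s * C + c) * Lo;
      double* dx = dX.begin() + ((size_t)s * C + c) * len_in;
      for (int j = 0; j < Lo; ++j) dx[am[j]] += dy[j];
    }
  return dX;
}

// [[Rcpp::export]]
NumericVector nn_avgpool1d_fwd(const NumericVector& X, int k, int stride) {
  int L, C, B;
  get_dim3(X, L, C, B);
  const int Lo = out_length(L, k, stride);
  if (Lo < 1) Rcpp::stop("input shorter than pool size");
  NumericVector Y = alloc3(Lo, C, B);
  const double inv = 1.0 / k;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* x = X.begin() + ((size_t)s * C + c) * L;
      double* y = Y.begin() + ((size_t)s * C + c) * Lo;
      for (int j = 0; j < Lo; ++j) {
        double acc = 0.0;
        const int t0 = j * stride;
        for (int kk = 0; kk < k; ++kk) acc += x[t0 + kk];
        y[j] = acc * inv;
      }
    }
  return Y;
}

// [[Rcpp::export]]
NumericVector nn_avgpool1d_bwd(const NumericVector& dY, int k, int stride,
                               int len_in) {
  IntegerVector d = dY.attr("dim");
  const int Lo = d[0], C = d[1], B = d[2];
  NumericVector dX = alloc3(len_in, C, B);
  std::fill(dX.begin(), dX.end(), 0.0);
  const double inv = 1.0 / k;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* dy = dY.begin() + ((size_t)s * C + c) * Lo;
      double* dx = dX.begin() + ((size_t)s * C + c) * len_in;
      for (int j = 0; j < Lo; ++j) {
        const double g = dy[j] * inv;
        const int t0 = j * stride;
        for (int kk = 0; kk < k; ++kk) dx[t0 + kk] += g;
      }
    }
  return dX;
}

// Per-channel mean and population variance over (length, batch).
// [[Rcpp::export]]
List nn_channel_stats(const NumericVector& X) {
  int L, C, B;
  get_dim3(X, L, C, B);
  NumericVector mu(C), v(C);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* x = X.begin() + ((size_t)s * C + c) * L;
      double acc = 0.0, acc2 = 0.0;
      for (int i = 0; i < L; ++i) { acc += x[i]; acc2 += x[i] * x[i]; }
      mu[c] += acc;
      v[c] += acc2;
    }
  const double m = (double)L * B;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    v[c] = v[c] / m - mu[c] * mu[c];
  }
  return List::create(Rcpp::Named("mean") = mu, Rcpp::Named("var") = v);
}

// Batch norm + optional fused ReLU. Returns post-activation Y and Xhat.
// [[Rcpp::export]]
List nn_bn_fwd(const NumericVector& X, const NumericVector& gamma,
               const NumericVector& beta, const NumericVector& mu,
               const NumericVector& invstd, bool relu) {
  int L, C, B;
  get_dim3(X, L, C, B);
  NumericVector Y = alloc3(L, C, B), Xhat = alloc3(L, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)s * C + c) * L;
      const double* x = X.begin() + off;
      double* xh = Xhat.begin() + off;
      double* y = Y.begin() + off;
      const double m0 = mu[c], is = invstd[c], g = gamma[c], bt = beta[c];
      for (int i = 0; i < L; ++i) {
        xh[i] = (x[i] - m0) * is;
        const double val = g * xh[i] + bt;
        y[i] = (relu && val < 0) ? 0.0 : val;
      }
    }
  return List::create(Rcpp::Named("Y") = Y, Rcpp::Named("Xhat") = Xhat);
}

// Backward through (optional ReLU +) batch norm. The ReLU mask is recovered
// from the post-activation output Y. With batch statistics the full
// normalization Jacobian applies; with running statistics only the scale.
// [[Rcpp::export]]
List nn_bn_bwd(const NumericVector& dYin, const NumericVector& Y,
               const NumericVector& Xhat, const NumericVector& gamma,
               const NumericVector& invstd, bool relu, bool batch_stats) {
  int L, C, B;
  get_dim3(dYin, L, C, B);
  NumericVector s_d(C), s_dx(C);
  NumericVector dX = alloc3(L, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)s * C + c) * L;
      const double* d0 = dYin.begin() + off;
      const double* y = Y.begin() + off;
      const double* xh = Xhat.begin() + off;
      double* d = dX.begin() + off;        // reuse as masked dY buffer
      double a1 = 0.0, a2 = 0.0;
      for (int i = 0; i < L; ++i) {
        const double g = (relu && y[i] <= 0) ? 0.0 : d0[i];
        d[i] = g;
        a1 += g;
        a2 += g * xh[i];
      }
      s_d[c] += a1;
      s_dx[c] += a2;
    }
  const double m = (double)L * B;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)s * C + c) * L;
      const double* xh = Xhat.begin() + off;
      double* d = dX.begin() + off;
      const double g = gamma[c], is = invstd[c];
      if (batch_stats) {
        const double c1 = s_d[c] / m, c2 = s_dx[c] / m;
        for (int i = 0; i < L; ++i)
          d[i] = g * is * (d[i] - c1 - xh[i] * c2);
      } else {
        for (int i = 0; i < L; ++i) d[i] = g * is * d[i];
      }
    }
  return List::create(Rcpp::Named("dX") = dX,
                      Rcpp::Named("dgamma") = s_dx,
                      Rcpp::Named("dbeta") = s_d);
}

// Direct-form-II-transposed IIR filter; coefficients normalized so a[0]=1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(const NumericVector& b, const NumericVector& a,
                             const NumericVector& x) {
  const int n = x.size(), nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(Rcpp::no_init(n));
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
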