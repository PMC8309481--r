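// Strided 2-D convolution / transposed convolution kernels used by the
// Rebuilder and Discriminator. Implemented as im2col / col2im around a
// single GEMM so that one CPU core gets BLAS-level throughput.
//
// Array layout (column-major, as R stores it):
//   images  x : dim (H, W, C, N)
//   conv W    : dim (k, k, Cin, Cout)   flattened to (k*k*Cin) x Cout
//   tconv W   : dim (k, k, Cout, Cin)   flattened to (k*k*Cout) x Cin
//
// im2col column index = ho + Ho*(wo + Wo*n); row index = i + k*(j + k*c)
// with input position h = ho*stride - pad + i (zero outside the image).
//
// Both a double and a single precision path are compiled; the single path
// converts at the interface and accumulates in float (the usual deep
// learning training precision), the double path is used for gradient
// checks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::List;

template <typename MT>
static void im2col_t(const MT& x, int H, int W, int C, int N,
                     int k, int stride, int pad, int Ho, int Wo, MT& cols) {
  typedef typename MT::elem_type T;
  cols.zeros(k * k * C, (arma::uword)Ho * Wo * N);
  const T* xp = x.memptr();
  T* cp = cols.memptr();
  const arma::uword nrow = cols.n_rows;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wo * stride - pad;
      int jlo = w0 < 0 ? -w0 : 0;
      int jhi = w0 + k > W ? W - w0 : k;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * stride - pad;
        int ilo = h0 < 0 ? -h0 : 0;
        int ihi = h0 + k > H ? H - h0 : k;
        arma::uword col = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        T* dst = cp + col * nrow;
        for (int c = 0; c < C; ++c) {
          const T* xc = xp + ((arma::uword)n * C + c) * H * W;
          for (int j = jlo; j < jhi; ++j) {
            const T* src = xc + (arma::uword)(w0 + j) * H + h0;
            T* d2 = dst + k * (j + k * c);
            for (int i = ilo; i < ihi; ++i) d2[i] = src[i];
          }
        }
      }
    }
  }
}

template <typename MT>
static void col2im_t(const MT& cols, int H, int W, int C, int N,
                     int k, int stride, int pad, int Ho, int Wo, MT& x) {
  typedef typename MT::elem_type T;
  x.zeros((arma::uword)H * W * C * N, 1);
  T* xp = x.memptr();
  const T* cp = cols.memptr();
  const arma::uword nrow = cols.n_rows;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wo * stride - pad;
      int jlo = w0 < 0 ? -w0 : 0;
      int jhi = w0 + k > W ? W - w0 : k;
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = ho * stride - pad;
        int ilo = h0 < 0 ? -h0 : 0;
        int ihi = h0 + k > H ? H - h0 : k;
        arma::uword col = (arma::uword)ho + (arma::uword)Ho * (wo + (arma::uword)Wo * n);
        const T* src = cp + col * nrow;
        for (int c = 0; c < C; ++c) {
          T* xc = xp + ((arma::uword)n * C + c) * H * W;
          for (int j = jlo; j < jhi; ++j) {
            T* dst = xc + (arma::uword)(w0 + j) * H + h0;
            const T* s2 = src + k * (j + k * c);
            for (int i = ilo; i < ihi; ++i) dst[i] += s2[i];
          }
        }
      }
    }
  }
}

// reorder (Ho,Wo,Co,N) array <-> (Co x Ho*Wo*N) matrix whose column index
// is ho + Ho*(wo + Wo*n)
template <typename MT>
static void chan_first_t(const MT& arr, int Ho, int Wo, int Co, int N, MT& out) {
  typedef typename MT::elem_type T;
  out.set_size(Co, (arma::uword)Ho * Wo * N);
  const T* a = arr.memptr();
  T* o = out.memptr();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c) {
      const T* src = a + ((arma::uword)n * Co + c) * Ho * Wo;
      for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p)
        o[c + Co * (p + (arma::uword)Ho * Wo * n)] = src[p];
    }
}

template <typename MT>
static void chan_last_t(const MT& m, int Ho, int Wo, int Co, int N, MT& out) {
  typedef typename MT::elem_type T;
  out.set_size((arma::uword)Ho * Wo * Co * N, 1);
  const T* a = m.memptr();
  T* o = out.memptr();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Co; ++c) {
      T* dst = o + ((arma::uword)n * Co + c) * Ho * Wo;
      for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p)
        dst[p] = a[c + Co * (p + (arma::uword)Ho * Wo * n)];
    }
}

static int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

template <typename MT>
static NumericVector conv_fwd_t(const NumericVector& x, const NumericVector& w,
                                const NumericVector& b, int stride, int pad) {
  typedef typename MT::elem_type T;
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) Rcpp::stop("channel mismatch in conv_fwd");
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);

  MT xm(x.size(), 1), wm((arma::uword)k * k * Cin, Cout), cols;
  std::copy(x.begin(), x.end(), xm.memptr());
  std::copy(w.begin(), w.end(), wm.memptr());
  im2col_t<MT>(xm, H, W, C, N, k, stride, pad, Ho, Wo, cols);
  MT om = wm.t() * cols;             // Cout x (Ho*Wo*N)
  for (arma::uword c = 0; c < (arma::uword)Cout; ++c)
    om.row(c) += (T)b[c];
  MT out;
  chan_last_t<MT>(om, Ho, Wo, Cout, N, out);
  NumericVector res(out.n_elem);
  std::copy(out.memptr(), out.memptr() + out.n_elem, res.begin());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return res;
}

template <typename MT>
static List conv_bwd_t(const NumericVector& x, const NumericVector& w,
                       const NumericVector& dout, int stride, int pad,
                       bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), dd = dout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = dd[0], Wo = dd[1];

  MT xm(x.size(), 1), wm((arma::uword)k * k * C, Cout), dm(dout.size(), 1), cols;
  std::copy(x.begin(), x.end(), xm.memptr());
  std::copy(w.begin(), w.end(), wm.memptr());
  std::copy(dout.begin(), dout.end(), dm.memptr());
  MT dmat;
  chan_first_t<MT>(dm, Ho, Wo, Cout, N, dmat);   // Cout x (Ho*Wo*N)
  im2col_t<MT>(xm, H, W, C, N, k, stride, pad, Ho, Wo, cols);

  MT dW = cols * dmat.t();                       // (k*k*C) x Cout
  arma::Col<typename MT::elem_type> db = arma::sum(dmat, 1);

  NumericVector dWr(dW.n_elem);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWr.begin());
  dWr.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector dbr(Cout);
  std::copy(db.memptr(), db.memptr() + Cout, dbr.begin());

  NumericVector dxr;
  if (need_dx) {
    MT dcols = wm * dmat, dx;
    col2im_t<MT>(dcols, H, W, C, N, k, stride, pad, Ho, Wo, dx);
    dxr = NumericVector(dx.n_elem);
    std::copy(dx.memptr(), dx.memptr() + dx.n_elem, dxr.begin());
    dxr.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  return List::create(Rcpp::Named("dW") = dWr, Rcpp::Named("db") = dbr,
                      Rcpp::Named("dx") = dxr);
}

template <typename MT>
static NumericVector tconv_fwd_t(const NumericVector& x, const NumericVector& w,
                                 const NumericVector& b, int stride, int pad,
                                 int opad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[2];
  int Ho = (H - 1) * stride - 2 * pad + k + opad;
  int Wo = (W - 1) * stride - 2 * pad + k + opad;

  MT xm(x.size(), 1), wm((arma::uword)k * k * Cout, Ci);
  std::copy(x.begin(), x.end(), xm.memptr());
  std::copy(w.begin(), w.end(), wm.memptr());
  MT xmat;
  chan_first_t<MT>(xm, H, W, Ci, N, xmat);       // Ci x (H*W*N)
  MT cols = wm * xmat;                           // (k*k*Cout) x (H*W*N)
  MT out;
  col2im_t<MT>(cols, Ho, Wo, Cout, N, k, stride, pad, H, W, out);
  NumericVector res(out.n_elem);
  std::copy(out.memptr(), out.memptr() + out.n_elem, res.begin());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  // bias per output channel
  double* rp = res.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double* dst = rp + ((arma::uword)n * Cout + c) * Ho * Wo;
      for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p) dst[p] += b[c];
    }
  return res;
}

template <typename MT>
static List tconv_bwd_t(const NumericVector& x, const NumericVector& w,
                        const NumericVector& dout, int stride, int pad,
                        bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), dd = dout.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[2];
  int Ho = dd[0], Wo = dd[1];

  MT wm((arma::uword)k * k * Cout, Ci), dm(dout.size(), 1), xm(x.size(), 1);
  std::copy(w.begin(), w.end(), wm.memptr());
  std::copy(dout.begin(), dout.end(), dm.memptr());
  std::copy(x.begin(), x.end(), xm.memptr());

  MT colsg;
  im2col_t<MT>(dm, Ho, Wo, Cout, N, k, stride, pad, H, W, colsg); // (k*k*Cout) x (H*W*N)
  MT xmat;
  chan_first_t<MT>(xm, H, W, Ci, N, xmat);

  MT dW = colsg * xmat.t();                       // (k*k*Cout) x Ci
  NumericVector dWr(dW.n_elem);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWr.begin());
  dWr.attr("dim") = IntegerVector::create(k, k, Cout, Ci);

  NumericVector dbr(Cout);
  const double* dp = dout.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      const double* src = dp + ((arma::uword)n * Cout + c) * Ho * Wo;
      double s = 0;
      for (arma::uword p = 0; p < (arma::uword)Ho * Wo; ++p) s += src[p];
      dbr[c] += s;
    }

  NumericVector dxr;
  if (need_dx) {
    MT dxmat = wm.t() * colsg, dx;                // Ci x (H*W*N)
    chan_last_t<MT>(dxmat, H, W, Ci, N, dx);
    dxr = NumericVector(dx.n_elem);
    std::copy(dx.memptr(), dx.memptr() + dx.n_elem, dxr.begin());
    dxr.attr("dim") = IntegerVector::create(H, W, Ci, N);
  }
  return List::create(Rcpp::Named("dW") = dWr, Rcpp::Named("db") = dbr,
                      Rcpp::Named("dx") = dxr);
}

// conv forward that additionally hands back the im2col matrix as an
// external pointer, so the backward pass skips recomputing it
template <typename MT>
static List conv_fwd_cache_t(const NumericVector& x, const NumericVector& w,
                             const NumericVector& b, int stride, int pad) {
  typedef typename MT::elem_type T;
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) Rcpp::stop("channel mismatch in conv_fwd");
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);

  MT xm(x.size(), 1), wm((arma::uword)k * k * Cin, Cout);
  std::copy(x.begin(), x.end(), xm.memptr());
  std::copy(w.begin(), w.end(), wm.memptr());
  MT* cols = new MT();
  im2col_t<MT>(xm, H, W, C, N, k, stride, pad, Ho, Wo, *cols);
  MT om = wm.t() * (*cols);
  for (arma::uword c = 0; c < (arma::uword)Cout; ++c)
    om.row(c) += (T)b[c];
  MT out;
  chan_last_t<MT>(om, Ho, Wo, Cout, N, out);
  NumericVector res(out.n_elem);
  std::copy(out.memptr(), out.memptr() + out.n_elem, res.begin());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  Rcpp::XPtr<MT> px(cols, true);
  return List::create(Rcpp::Named("out") = res, Rcpp::Named("cols") = px,
                      Rcpp::Named("xdim") = xd);
}

template <typename MT>
static List conv_bwd_cache_t(SEXP colsp, const IntegerVector& xd,
                             const NumericVector& w,
                             const NumericVector& dout, int stride, int pad,
                             bool need_dx) {
  Rcpp::XPtr<MT> cols(colsp);
  IntegerVector wd = w.attr("dim"), dd = dout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = dd[0], Wo = dd[1];

  MT wm((arma::uword)k * k * C, Cout), dm(dout.size(), 1);
  std::copy(w.begin(), w.end(), wm.memptr());
  std::copy(dout.begin(), dout.end(), dm.memptr());
  MT dmat;
  chan_first_t<MT>(dm, Ho, Wo, Cout, N, dmat);

  MT dW = (*cols) * dmat.t();
  arma::Col<typename MT::elem_type> db = arma::sum(dmat, 1);

  NumericVector dWr(dW.n_elem);
  std::copy(dW.memptr(), dW.memptr() + dW.n_elem, dWr.begin());
  dWr.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector dbr(Cout);
  std::copy(db.memptr(), db.memptr() + Cout, dbr.begin());

  NumericVector dxr;
  if (need_dx) {
    MT dcols = wm * dmat, dx;
    col2im_t<MT>(dcols, H, W, C, N, k, stride, pad, Ho, Wo, dx);
    dxr = NumericVector(dx.n_elem);
    std::copy(dx.memptr(), dx.memptr() + dx.n_elem, dxr.begin());
    dxr.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  return List::create(Rcpp::Named("dW") = dWr, Rcpp::Named("db") = dbr,
                      Rcpp::Named("dx") = dxr);
}

// [[Rcpp::export]]
List conv_fwd_cache_cpp(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad, bool single) {
  return single ? conv_fwd_cache_t<arma::fmat>(x, w, b, stride, pad)
                : conv_fwd_cache_t<arma::mat>(x, w, b, stride, pad);
}

// [[Rcpp::export]]
List conv_bwd_cache_cpp(SEXP cols, IntegerVector xdim, NumericVector w,
                        NumericVector dout, int stride, int pad,
                        bool need_dx, bool single) {
  return single
    ? conv_bwd_cache_t<arma::fmat>(cols, xdim, w, dout, stride, pad, need_dx)
    : conv_bwd_cache_t<arma::mat>(cols, xdim, w, dout, stride, pad, need_dx);
}

// fused Adam leaf update: one pass, three output allocations
// [[Rcpp::export]]
List adam_leaf_cpp(NumericVector p, NumericVector g, NumericVector m,
                   NumericVector v, double c1, double c2, double lr,
                   double beta1, double beta2, double eps) {
  R_xlen_t n = p.size();
  NumericVector pn(n), mn(n), vn(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = beta1 * m[i] + (1 - beta1) * g[i];
    double vi = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    mn[i] = mi;
    vn[i] = vi;
    pn[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  pn.attr("dim") = p.attr("dim");
  return List::create(Rcpp::Named("p") = pn, Rcpp::Named("m") = mn,
                      Rcpp::Named("v") = vn);
}

// [[Rcpp::export]]
NumericVector lrelu_cpp(NumericVector x, double alpha) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? x[i] : alpha * x[i];
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector lrelu_bwd_cpp(NumericVector x, NumericVector dout,
                            double alpha) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? dout[i] : alpha * dout[i];
  out.attr("dim") = dout.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad, bool single) {
  return single ? conv_fwd_t<arma::fmat>(x, w, b, stride, pad)
                : conv_fwd_t<arma::mat>(x, w, b, stride, pad);
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                  int stride, int pad, bool need_dx, bool single) {
  return single ? conv_bwd_t<arma::fmat>(x, w, dout, stride, pad, need_dx)
                : conv_bwd_t<arma::mat>(x, w, dout, stride, pad, need_dx);
}

// [[Rcpp::export]]
NumericVector tconv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int opad, bool single) {
  return single ? tconv_fwd_t<arma::fmat>(x, w, b, stride, pad, opad)
                : tconv_fwd_t<arma::mat>(x, w, b, stride, pad, opad);
}

// [[Rcpp::export]]
List tconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                   int stride, int pad, bool need_dx, bool single) {
  return single ? tconv_bwd_t<arma::fmat>(x, w, dout, stride, pad, need_dx)
                : tconv_bwd_t<arma::mat>(x, w, dout, stride, pad, need_dx);
}
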