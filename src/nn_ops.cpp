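// Low-level numerical kernels for the denoising network and phantom renderer.
//
// Tensor layout: column-major R arrays of dim (H, W, C, N) — height fastest,
// then width, channel, batch. Convolution weights are (k*k*Cin) x Cout
// matrices whose rows are ordered kernel-row fastest, then kernel-col, then
// input channel. Convolutions build a full im2col matrix (columns in the
// same order as the weight rows) and run one GEMM; the GEMMs execute in
// single precision, which is the working precision of the network, while
// the R-facing arrays stay double. Elementwise ops (PReLU, Laplacian,
// composition) run in double.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::mat;
using arma::vec;

struct Dim4 { int H, W, C, N; };

static Dim4 dims4(const NumericVector& x) {
  if (Rf_isNull(x.attr("dim"))) stop("expected a 4-d array");
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return Dim4{d[0], d[1], d[2], d[3]};
}

// zero-pad each (H,W) slice by p on all sides, converting to float
static fvec pad4f(const double* x, Dim4 d, int p) {
  int Hp = d.H + 2 * p, Wp = d.W + 2 * p;
  fvec out((size_t)Hp * Wp * d.C * d.N, arma::fill::zeros);
  for (int n = 0; n < d.N; ++n)
    for (int c = 0; c < d.C; ++c)
      for (int w = 0; w < d.W; ++w) {
        const double* src = x + (size_t)d.H * (w + (size_t)d.W * (c + (size_t)d.C * n));
        float* dst = out.memptr() + p +
          (size_t)Hp * ((w + p) + (size_t)Wp * (c + (size_t)d.C * n));
        for (int h = 0; h < d.H; ++h) dst[h] = (float)src[h];
      }
  return out;
}

// crop the p-ring back off, converting to double (adjoint of pad4f)
static void unpad4f(const float* xp, Dim4 d, int p, double* out) {
  int Hp = d.H + 2 * p, Wp = d.W + 2 * p;
  for (int n = 0; n < d.N; ++n)
    for (int c = 0; c < d.C; ++c)
      for (int w = 0; w < d.W; ++w) {
        const float* src = xp + p +
          (size_t)Hp * ((w + p) + (size_t)Wp * (c + (size_t)d.C * n));
        double* dst = out + (size_t)d.H * (w + (size_t)d.W * (c + (size_t)d.C * n));
        for (int h = 0; h < d.H; ++h) dst[h] = (double)src[h];
      }
}

// gather strided window positions from the padded float buffer into column
// col0 + k*k*c of the im2col matrix (same ordering as the weight rows)
static void gather(const float* Xp, int Hp, int Wp, Dim4 d, int ki, int kj,
                   int s, int Ho, int Wo, fmat& M, int col0, int cstride) {
  size_t HoWo = (size_t)Ho * Wo;
  for (int c = 0; c < d.C; ++c) {
    float* dst0 = M.colptr(col0 + (size_t)cstride * c);
    for (int n = 0; n < d.N; ++n) {
      float* dst = dst0 + (size_t)n * HoWo;
      for (int ow = 0; ow < Wo; ++ow) {
        const float* src = Xp + ki +
          (size_t)Hp * ((kj + (size_t)s * ow) + (size_t)Wp * (c + (size_t)d.C * n));
        if (s == 1) memcpy(dst, src, Ho * sizeof(float));
        else for (int oh = 0; oh < Ho; ++oh) dst[oh] = src[(size_t)s * oh];
        dst += Ho;
      }
    }
  }
}

// adjoint of gather: add matrix columns back into strided padded positions
static void scatter_add(float* Xp, int Hp, int Wp, Dim4 d, int ki, int kj,
                        int s, int Ho, int Wo, const fmat& M, int col0,
                        int cstride) {
  size_t HoWo = (size_t)Ho * Wo;
  for (int c = 0; c < d.C; ++c) {
    const float* src0 = M.colptr(col0 + (size_t)cstride * c);
    for (int n = 0; n < d.N; ++n) {
      const float* src = src0 + (size_t)n * HoWo;
      for (int ow = 0; ow < Wo; ++ow) {
        float* dst = Xp + ki +
          (size_t)Hp * ((kj + (size_t)s * ow) + (size_t)Wp * (c + (size_t)d.C * n));
        if (s == 1) for (int oh = 0; oh < Ho; ++oh) dst[oh] += src[oh];
        else for (int oh = 0; oh < Ho; ++oh) dst[(size_t)s * oh] += src[oh];
        src += Ho;
      }
    }
  }
}

// (Ho,Wo,Cout,N) double array -> (N*Ho*Wo) x Cout float matrix, n-major rows
static fmat to_rows_f(const double* y, int Ho, int Wo, int Cout, int N) {
  size_t HoWo = (size_t)Ho * Wo;
  fmat M((size_t)N * HoWo, Cout);
  for (int co = 0; co < Cout; ++co) {
    float* dst = M.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* src = y + HoWo * (co + (size_t)Cout * n);
      for (size_t i = 0; i < HoWo; ++i) dst[(size_t)n * HoWo + i] = (float)src[i];
    }
  }
  return M;
}

static NumericVector from_rows_f(const fmat& M, int Ho, int Wo, int Cout, int N) {
  size_t HoWo = (size_t)Ho * Wo;
  NumericVector out((R_xlen_t)(HoWo * Cout * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* o = REAL(out);
  for (int co = 0; co < Cout; ++co) {
    const float* src = M.colptr(co);
    for (int n = 0; n < N; ++n) {
      double* dst = o + HoWo * (co + (size_t)Cout * n);
      for (size_t i = 0; i < HoWo; ++i) dst[i] = (double)src[(size_t)n * HoWo + i];
    }
  }
  return out;
}

// Reusable scratch pools: convolutions are called thousands of times with
// the same shapes during training, and repeated large malloc/munmap cycles
// (with their first-touch page faults) would dominate the runtime.
struct Pool {
  std::vector<float> v;
  float* get(size_t n) { if (v.size() < n) v.resize(n); return v.data(); }
};
static Pool P_pad, P_cols, P_rows, P_acc, P_vec;

// pad into pooled storage (zeroing only what is used)
static float* pad4f_pool(Pool& pool, const double* x, Dim4 d, int p) {
  int Hp = d.H + 2 * p, Wp = d.W + 2 * p;
  size_t n = (size_t)Hp * Wp * d.C * d.N;
  float* out = pool.get(n);
  if (p > 0) memset(out, 0, n * sizeof(float));
  for (int nn = 0; nn < d.N; ++nn)
    for (int c = 0; c < d.C; ++c)
      for (int w = 0; w < d.W; ++w) {
        const double* src = x + (size_t)d.H * (w + (size_t)d.W * (c + (size_t)d.C * nn));
        float* dst = out + p +
          (size_t)Hp * ((w + p) + (size_t)Wp * (c + (size_t)d.C * nn));
        for (int h = 0; h < d.H; ++h) dst[h] = (float)src[h];
      }
  return out;
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, const arma::mat& w, const arma::vec& b,
                          int k, int stride, int pad) {
  Dim4 d = dims4(x);
  int Cout = w.n_cols;
  if ((int)w.n_rows != k * k * d.C) stop("weight/input channel mismatch");
  int Ho = (d.H + 2 * pad - k) / stride + 1;
  int Wo = (d.W + 2 * pad - k) / stride + 1;
  int Hp = d.H + 2 * pad, Wp = d.W + 2 * pad;
  size_t nr = (size_t)d.N * Ho * Wo;
  size_t nc = (size_t)k * k * d.C;
  const float* xp = pad4f_pool(P_pad, REAL(x), d, pad);
  fmat cols(P_cols.get(nr * nc), nr, nc, false, true);
  // 1x1 unpadded convolutions reduce to a plain channel mix: the im2col
  // matrix is just the (pixels x channels) view built by the pad pass
  if (k == 1 && pad == 0 && stride == 1) {
    for (int c = 0; c < d.C; ++c) {
      float* dst = cols.colptr(c);
      for (int n = 0; n < d.N; ++n)
        memcpy(dst + (size_t)n * d.H * d.W,
               xp + (size_t)d.H * d.W * (c + (size_t)d.C * n),
               (size_t)d.H * d.W * sizeof(float));
    }
  } else {
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        gather(xp, Hp, Wp, d, ki, kj, stride, Ho, Wo, cols, ki + k * kj, k * k);
  }
  fmat wf = arma::conv_to<fmat>::from(w);
  fmat Y(P_rows.get(nr * Cout), nr, Cout, false, true);
  Y = cols * wf;
  Y.each_row() += arma::conv_to<fvec>::from(b).t();
  return from_rows_f(Y, Ho, Wo, Cout, d.N);
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, const arma::mat& w, NumericVector dy,
                 int k, int stride, int pad) {
  Dim4 d = dims4(x);
  Dim4 dd = dims4(dy);
  int Cout = dd.C;
  int Ho = dd.H, Wo = dd.W;
  int Hp = d.H + 2 * pad, Wp = d.W + 2 * pad;
  size_t nr = (size_t)d.N * Ho * Wo;
  size_t nc = (size_t)k * k * d.C;
  const float* xp = pad4f_pool(P_pad, REAL(x), d, pad);
  fmat cols(P_cols.get(nr * nc), nr, nc, false, true);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki)
      gather(xp, Hp, Wp, d, ki, kj, stride, Ho, Wo, cols, ki + k * kj, k * k);
  fmat dYm(P_rows.get(nr * Cout), nr, Cout, false, true);
  {
    const double* dyp = REAL(dy);
    size_t HoWo = (size_t)Ho * Wo;
    for (int co = 0; co < Cout; ++co) {
      float* dst = dYm.colptr(co);
      for (int n = 0; n < d.N; ++n) {
        const double* src = dyp + HoWo * (co + (size_t)Cout * n);
        for (size_t i = 0; i < HoWo; ++i) dst[(size_t)n * HoWo + i] = (float)src[i];
      }
    }
  }
  fmat wf = arma::conv_to<fmat>::from(w);
  fmat dWf = cols.t() * dYm;
  // data gradient: for each im2col column j = (ki,kj,c), the gradient
  // column is dYm * w[j,]^T (a cache-resident matvec: the k=Cout inner
  // dimension is far too small for a GEMM to run well), scattered straight
  // back into the padded accumulator
  size_t npad = (size_t)Hp * Wp * d.C * d.N;
  float* dXp = P_acc.get(npad);
  memset(dXp, 0, npad * sizeof(float));
  fvec colbuf(P_vec.get(nr), nr, false, true);
  fmat cb_m(colbuf.memptr(), nr, 1, false, true);
  for (int c = 0; c < d.C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int j = ki + k * kj + k * k * c;
        cb_m = dYm * wf.row(j).t();
        // channel c of the padded buffer, addressed via base-pointer offset
        for (int n = 0; n < d.N; ++n) {
          float* base = dXp + (size_t)Hp * Wp * (c + (size_t)d.C * n);
          const float* src = cb_m.colptr(0) + (size_t)n * Ho * Wo;
          for (int ow = 0; ow < Wo; ++ow) {
            float* dst = base + ki + (size_t)Hp * (kj + (size_t)stride * ow);
            if (stride == 1) for (int oh = 0; oh < Ho; ++oh) dst[oh] += src[oh];
            else for (int oh = 0; oh < Ho; ++oh) dst[(size_t)stride * oh] += src[oh];
            src += Ho;
          }
        }

      }
  vec db = arma::conv_to<vec>::from(arma::sum(dYm, 0).t());
  NumericVector dx((R_xlen_t)((size_t)d.H * d.W * d.C * d.N));
  dx.attr("dim") = IntegerVector::create(d.H, d.W, d.C, d.N);
  unpad4f(dXp, d, pad, REAL(dx));
  return List::create(_["dx"] = dx,
                      _["dw"] = arma::conv_to<mat>::from(dWf),
                      _["db"] = db);
}

// transposed convolution: y[s*h+ki-p, s*w+kj-p, co] += x[h,w,ci] * W[(ki,kj,ci),co]
// [[Rcpp::export]]
NumericVector nn_deconv_fwd(NumericVector x, const arma::mat& w, const arma::vec& b,
                            int k, int stride, int pad) {
  Dim4 d = dims4(x);
  int Cout = w.n_cols;
  if ((int)w.n_rows != k * k * d.C) stop("weight/input channel mismatch");
  int Oh = stride * (d.H - 1) + k - 2 * pad;
  int Ow = stride * (d.W - 1) + k - 2 * pad;
  int Hp = Oh + 2 * pad, Wp = Ow + 2 * pad;
  fmat Xm = to_rows_f(REAL(x), d.H, d.W, d.C, d.N);
  fmat wf = arma::conv_to<fmat>::from(w);
  // regroup the weight as Cin x (k*k*Cout) so the whole transposed
  // convolution is one GEMM; column ki + k*kj + k*k*co of the result is the
  // contribution of kernel offset (ki,kj) to output channel co
  fmat wre(d.C, (size_t)k * k * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (int c = 0; c < d.C; ++c)
          wre(c, ki + k * kj + (size_t)k * k * co) =
            wf(ki + k * kj + (size_t)k * k * c, co);
  fmat cols = Xm * wre;
  fvec Yp((size_t)Hp * Wp * Cout * d.N, arma::fill::zeros);
  Dim4 od{Oh, Ow, Cout, d.N};
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki)
      scatter_add(Yp.memptr(), Hp, Wp, od, ki, kj, stride, d.H, d.W, cols,
                  ki + k * kj, k * k);
  NumericVector y((R_xlen_t)((size_t)Oh * Ow * Cout * d.N));
  y.attr("dim") = IntegerVector::create(Oh, Ow, Cout, d.N);
  unpad4f(Yp.memptr(), od, pad, REAL(y));
  double* yp = REAL(y);
  size_t HW = (size_t)Oh * Ow;
  for (int n = 0; n < d.N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* p0 = yp + HW * (co + (size_t)Cout * n);
      for (size_t i = 0; i < HW; ++i) p0[i] += b[co];
    }
  return y;
}

// [[Rcpp::export]]
List nn_deconv_bwd(NumericVector x, const arma::mat& w, NumericVector dy,
                   int k, int stride, int pad) {
  Dim4 d = dims4(x);
  Dim4 od = dims4(dy);
  int Cout = od.C;
  int Hp = od.H + 2 * pad, Wp = od.W + 2 * pad;
  fvec dYp = pad4f(REAL(dy), od, pad);
  // im2col over the padded upstream gradient with the deconv's geometry
  // gives, per offset/channel column, exactly the strided positions the
  // forward scattered into
  fmat dCols((size_t)d.N * d.H * d.W, (size_t)k * k * Cout);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki)
      gather(dYp.memptr(), Hp, Wp, od, ki, kj, stride, d.H, d.W, dCols,
             ki + k * kj, k * k);
  fmat Xm = to_rows_f(REAL(x), d.H, d.W, d.C, d.N);
  // regrouped weight (Cin x (k*k*Cout)) as in the forward
  fmat wf = arma::conv_to<fmat>::from(w);
  fmat wre(d.C, (size_t)k * k * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (int c = 0; c < d.C; ++c)
          wre(c, ki + k * kj + (size_t)k * k * co) =
            wf(ki + k * kj + (size_t)k * k * c, co);
  fmat dXm = dCols * wre.t();
  fmat dWre = Xm.t() * dCols;   // Cin x (k*k*Cout)
  mat dW(w.n_rows, w.n_cols);
  for (int co = 0; co < Cout; ++co)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (int c = 0; c < d.C; ++c)
          dW(ki + k * kj + (size_t)k * k * c, co) =
            (double)dWre(c, ki + k * kj + (size_t)k * k * co);
  vec db(Cout, arma::fill::zeros);
  const double* dyp = REAL(dy);
  size_t HW = (size_t)od.H * od.W;
  for (int n = 0; n < od.N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* p0 = dyp + HW * (co + (size_t)Cout * n);
      for (size_t i = 0; i < HW; ++i) db[co] += p0[i];
    }
  return List::create(_["dx"] = from_rows_f(dXm, d.H, d.W, d.C, d.N),
                      _["dw"] = dW, _["db"] = db);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 4-neighbor Laplacian with replicate-padded borders, per (channel, batch)
// slice; double precision
// [[Rcpp::export]]
NumericVector nn_lap_fwd(NumericVector x) {
  Dim4 d = dims4(x);
  NumericVector y((R_xlen_t)((size_t)d.H * d.W * d.C * d.N));
  y.attr("dim") = IntegerVector::create(d.H, d.W, d.C, d.N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  size_t HW = (size_t)d.H * d.W;
  for (int s = 0; s < d.C * d.N; ++s) {
    const double* X = xp + HW * s;
    double* Y = yp + HW * s;
    for (int w = 0; w < d.W; ++w) {
      int wl = clampi(w - 1, 0, d.W - 1), wr = clampi(w + 1, 0, d.W - 1);
      for (int h = 0; h < d.H; ++h) {
        int hu = clampi(h - 1, 0, d.H - 1), hd = clampi(h + 1, 0, d.H - 1);
        Y[h + (size_t)d.H * w] =
          -4.0 * X[h + (size_t)d.H * w] +
          X[hu + (size_t)d.H * w] + X[hd + (size_t)d.H * w] +
          X[h + (size_t)d.H * wl] + X[h + (size_t)d.H * wr];
      }
    }
  }
  return y;
}

// exact adjoint of nn_lap_fwd (replicate padding folds border gradients back)
// [[Rcpp::export]]
NumericVector nn_lap_bwd(NumericVector dy) {
  Dim4 d = dims4(dy);
  NumericVector dx((R_xlen_t)((size_t)d.H * d.W * d.C * d.N));
  dx.attr("dim") = IntegerVector::create(d.H, d.W, d.C, d.N);
  const double* gp = REAL(dy);
  double* op = REAL(dx);
  size_t HW = (size_t)d.H * d.W;
  std::fill(op, op + HW * d.C * d.N, 0.0);
  const int dh[5] = {0, -1, 1, 0, 0};
  const int dw[5] = {0, 0, 0, -1, 1};
  const double wt[5] = {-4.0, 1.0, 1.0, 1.0, 1.0};
  for (int s = 0; s < d.C * d.N; ++s) {
    const double* G = gp + HW * s;
    double* O = op + HW * s;
    for (int w = 0; w < d.W; ++w)
      for (int h = 0; h < d.H; ++h) {
        double g = G[h + (size_t)d.H * w];
        for (int t = 0; t < 5; ++t) {
          int hh = clampi(h + dh[t], 0, d.H - 1);
          int ww = clampi(w + dw[t], 0, d.W - 1);
          O[hh + (size_t)d.H * ww] += wt[t] * g;
        }
      }
  }
  return dx;
}

// PReLU with a single learnable slope per layer
// [[Rcpp::export]]
NumericVector nn_prelu_fwd(NumericVector x, double a) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yp[i] = xp[i] >= 0 ? xp[i] : a * xp[i];
  return y;
}

// [[Rcpp::export]]
List nn_prelu_bwd(NumericVector z, double a, NumericVector dy) {
  NumericVector dx(z.size());
  dx.attr("dim") = z.attr("dim");
  const double* zp = REAL(z);
  const double* gp = REAL(dy);
  double* op = REAL(dx);
  double da = 0.0;
  R_xlen_t n = z.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (zp[i] >= 0) op[i] = gp[i];
    else { op[i] = a * gp[i]; da += gp[i] * zp[i]; }
  }
  return List::create(_["dx"] = dx, _["da"] = da);
}

// concatenate (H,W,Ci,N) arrays along the channel axis
// [[Rcpp::export]]
NumericVector nn_cat_channels(List xs) {
  int m = xs.size();
  std::vector<Dim4> ds(m);
  int Ctot = 0;
  for (int i = 0; i < m; ++i) {
    NumericVector xi = xs[i];
    ds[i] = dims4(xi);
    Ctot += ds[i].C;
  }
  Dim4 d0 = ds[0];
  NumericVector out((R_xlen_t)((size_t)d0.H * d0.W * Ctot * d0.N));
  out.attr("dim") = IntegerVector::create(d0.H, d0.W, Ctot, d0.N);
  double* op = REAL(out);
  size_t HW = (size_t)d0.H * d0.W;
  int coff = 0;
  for (int i = 0; i < m; ++i) {
    NumericVector xi = xs[i];
    const double* xp = REAL(xi);
    for (int n = 0; n < d0.N; ++n)
      memcpy(op + HW * (coff + (size_t)Ctot * n),
             xp + HW * (size_t)ds[i].C * n,
             HW * ds[i].C * sizeof(double));
    coff += ds[i].C;
  }
  return out;
}

// split along the channel axis into chunks of the given widths
// [[Rcpp::export]]
List nn_split_channels(NumericVector x, IntegerVector widths) {
  Dim4 d = dims4(x);
  const double* xp = REAL(x);
  size_t HW = (size_t)d.H * d.W;
  List out(widths.size());
  int coff = 0;
  for (int i = 0; i < widths.size(); ++i) {
    int C = widths[i];
    NumericVector yi((R_xlen_t)(HW * C * d.N));
    yi.attr("dim") = IntegerVector::create(d.H, d.W, C, d.N);
    double* yp = REAL(yi);
    for (int n = 0; n < d.N; ++n)
      memcpy(yp + HW * (size_t)C * n,
             xp + HW * (coff + (size_t)d.C * n),
             HW * C * sizeof(double));
    out[i] = yi;
    coff += C;
  }
  return out;
}

// elementwise a + b (dims of a), avoiding R-level copies in hot paths
// [[Rcpp::export]]
NumericVector nn_add(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  const double* ap = REAL(a);
  const double* bp = REAL(b);
  double* yp = REAL(y);
  R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = ap[i] + bp[i];
  return y;
}

// minimum Euclidean distance from each pixel to a polyline sample set,
// evaluated only within maxr of any sample (Inf elsewhere)
// [[Rcpp::export]]
NumericMatrix nn_min_dist(int H, int W, const arma::mat& pts, double maxr) {
  NumericMatrix D(H, W);
  std::fill(D.begin(), D.end(), R_PosInf);
  int r = (int)std::ceil(maxr);
  for (size_t i = 0; i < pts.n_rows; ++i) {
    double pr = pts(i, 0), pc = pts(i, 1);
    int h0 = clampi((int)std::floor(pr) - r, 0, H - 1);
    int h1 = clampi((int)std::ceil(pr) + r, 0, H - 1);
    int w0 = clampi((int)std::floor(pc) - r, 0, W - 1);
    int w1 = clampi((int)std::ceil(pc) + r, 0, W - 1);
    for (int w = w0; w <= w1; ++w)
      for (int h = h0; h <= h1; ++h) {
        double dr = h - pr, dc = w - pc;
        double dd = std::sqrt(dr * dr + dc * dc);
        if (dd < D(h, w)) D(h, w) = dd;
      }
  }
  return D;
}

// ---------------------------------------------------------------------------
// Ultra-dense block, fully in C++.
//
// A UDB is a dense block: layer l convolves (3x3, PReLU, `growth` output
// channels) the concatenation of the block input and all previous layer
// outputs; a 1x1 fusion conv maps the full concatenation back to the input
// width and the block output adds the input (local residual). Because each
// layer's im2col matrix is a prefix of the next one's, the columns are built
// incrementally and every feature is gathered exactly once; the backward
// pass reuses the cached columns of the immediately preceding forward (same
// scratch id), so it gathers nothing.
//
// Row layout of feature matrices: nr = N*H*W rows; column c of feature f
// holds n-major blocks of H*W pixels (h fastest, then w), matching
// to_rows_f.

struct UdbScratch {
  std::vector<float> cols;    // nr x 9*(C+L*g), incremental im2col
  std::vector<float> feats;   // nr x (C+L*g), raw feature rows (for fuse)
  std::vector<float> zs;      // nr x g per layer, pre-activations
  std::vector<float> pad;     // padded single-feature staging
  std::vector<float> acc;     // padded gradient accumulator
  std::vector<float> dz;      // nr x g staging
  std::vector<float> colbuf;  // nr, per-column data-gradient staging
  int H = 0, W = 0, C = 0, N = 0, L = 0, g = 0;
  size_t nr = 0;
};
static std::map<int, UdbScratch> g_udb;

static void grow(std::vector<float>& v, size_t n) {
  if (v.size() < n) { v.clear(); v.resize(n); }
}

// pad `nf` channels of a rows-layout float block with a 1-pixel zero ring
static void pad_rows_f(std::vector<float>& out, const float* rows, size_t nr,
                       int H, int W, int N, int nf) {
  int Hp = H + 2, Wp = W + 2;
  size_t need = (size_t)Hp * Wp * nf * N;
  grow(out, need);
  memset(out.data(), 0, need * sizeof(float));
  size_t HW = (size_t)H * W;
  for (int c = 0; c < nf; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < W; ++w) {
        const float* src = rows + (size_t)c * nr + (size_t)n * HW + (size_t)H * w;
        float* dst = out.data() + 1 +
          (size_t)Hp * ((w + 1) + (size_t)Wp * (c + (size_t)nf * n));
        memcpy(dst, src, H * sizeof(float));
      }
}

// gather the 9 shifted copies of `nf` padded channels into im2col columns
// starting at column base9 (layout: base9 + ki + 3*kj + 9*c)
static void gather_block(float* cols, size_t nr, const float* padbuf, int H,
                         int W, int N, int nf, size_t base9) {
  int Hp = H + 2, Wp = W + 2;
  size_t HW = (size_t)H * W;
  for (int c = 0; c < nf; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        float* dst0 = cols + nr * (base9 + ki + 3 * kj + 9 * (size_t)c);
        for (int n = 0; n < N; ++n) {
          float* dst = dst0 + (size_t)n * HW;
          for (int w = 0; w < W; ++w) {
            const float* src = padbuf + ki +
              (size_t)Hp * ((kj + w) + (size_t)Wp * (c + (size_t)nf * n));
            memcpy(dst, src, H * sizeof(float));
            dst += H;
          }
        }
      }
}

// weights come in as the R-side list: L layer convolutions (w: (9*Cin_l) x g,
// b: g, slope a) plus the fusion conv (w: (C+L*g) x C, b: C)
// [[Rcpp::export]]
NumericVector nn_udb_fwd(int id, NumericVector x, List layer_w, List layer_b,
                         NumericVector slopes, const arma::mat& fuse_w,
                         const arma::vec& fuse_b, int growth) {
  Dim4 d = dims4(x);
  int L = layer_w.size(), g = growth, C = d.C;
  int Ctot = C + L * g;
  size_t nr = (size_t)d.N * d.H * d.W;
  size_t HW = (size_t)d.H * d.W;
  UdbScratch& S = g_udb[id];
  S.H = d.H; S.W = d.W; S.C = C; S.N = d.N; S.L = L; S.g = g; S.nr = nr;
  grow(S.cols, nr * 9 * (size_t)Ctot);
  grow(S.feats, nr * (size_t)Ctot);
  grow(S.zs, nr * (size_t)g * L);
  // block input: convert to rows layout, pad, gather
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < d.N; ++n) {
      float* dst = S.feats.data() + (size_t)c * nr + (size_t)n * HW;
      const double* src = xp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) dst[i] = (float)src[i];
    }
  pad_rows_f(S.pad, S.feats.data(), nr, d.H, d.W, d.N, C);
  gather_block(S.cols.data(), nr, S.pad.data(), d.H, d.W, d.N, C, 0);
  // dense layers
  for (int l = 0; l < L; ++l) {
    int Cin = C + l * g;
    fmat wl = arma::conv_to<fmat>::from(as<arma::mat>(layer_w[l]));
    fvec bl = arma::conv_to<fvec>::from(as<arma::vec>(layer_b[l]));
    float a = (float)slopes[l];
    fmat colsv(S.cols.data(), nr, 9 * (size_t)Cin, false, true);
    fmat Z(S.zs.data() + (size_t)l * nr * g, nr, g, false, true);
    Z = colsv * wl;
    Z.each_row() += bl.t();
    // PReLU into the feats block for this layer
    float* hdst = S.feats.data() + (size_t)Cin * nr;
    const float* zsrc = Z.memptr();
    for (size_t i = 0; i < nr * (size_t)g; ++i)
      hdst[i] = zsrc[i] >= 0 ? zsrc[i] : a * zsrc[i];
    pad_rows_f(S.pad, hdst, nr, d.H, d.W, d.N, g);
    gather_block(S.cols.data(), nr, S.pad.data(), d.H, d.W, d.N, g,
                 9 * (size_t)Cin);
  }
  // fusion + residual
  fmat featsm(S.feats.data(), nr, Ctot, false, true);
  fmat fwf = arma::conv_to<fmat>::from(fuse_w);
  fvec fbf = arma::conv_to<fvec>::from(fuse_b);
  fmat F = featsm * fwf;
  F.each_row() += fbf.t();
  NumericVector out((R_xlen_t)(nr * C));
  out.attr("dim") = IntegerVector::create(d.H, d.W, C, d.N);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c) {
    const float* fc = F.colptr(c);
    for (int n = 0; n < d.N; ++n) {
      double* dst = op + HW * (c + (size_t)C * n);
      const double* src = xp + HW * (c + (size_t)C * n);
      const float* fs = fc + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) dst[i] = src[i] + (double)fs[i];
    }
  }
  return out;
}

// backward; must directly follow nn_udb_fwd with the same id and shapes
// [[Rcpp::export]]
List nn_udb_bwd(int id, List layer_w, NumericVector slopes,
                const arma::mat& fuse_w, NumericVector dout) {
  UdbScratch& S = g_udb[id];
  Dim4 d = dims4(dout);
  if (S.nr == 0 || d.H != S.H || d.W != S.W || d.C != S.C || d.N != S.N)
    stop("udb backward without a matching forward");
  int L = S.L, g = S.g, C = S.C, Ctot = C + L * g;
  int Hp = S.H + 2, Wp = S.W + 2;
  size_t nr = S.nr, HW = (size_t)S.H * S.W;
  // upstream gradient in rows layout
  fmat dYm(nr, C);
  const double* dp = REAL(dout);
  for (int c = 0; c < C; ++c) {
    float* dst = dYm.colptr(c);
    for (int n = 0; n < d.N; ++n) {
      const double* src = dp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) dst[(size_t)n * HW + i] = (float)src[i];
    }
  }
  fmat featsm(S.feats.data(), nr, Ctot, false, true);
  fmat fwf = arma::conv_to<fmat>::from(fuse_w);
  mat dWf = arma::conv_to<mat>::from(featsm.t() * dYm);
  vec dbf = arma::conv_to<vec>::from(arma::sum(dYm, 0).t());
  fmat dfeats = dYm * fwf.t();   // nr x Ctot
  // padded per-feature gradient accumulator, seeded with the fusion term
  size_t npad = (size_t)Hp * Wp * Ctot * d.N;
  grow(S.acc, npad);
  memset(S.acc.data(), 0, npad * sizeof(float));
  for (int c = 0; c < Ctot; ++c)
    for (int n = 0; n < d.N; ++n)
      for (int w = 0; w < S.W; ++w) {
        const float* src = dfeats.colptr(c) + (size_t)n * HW + (size_t)S.H * w;
        float* dst = S.acc.data() + 1 +
          (size_t)Hp * ((w + 1) + (size_t)Wp * (c + (size_t)Ctot * n));
        for (int h = 0; h < S.H; ++h) dst[h] += src[h];
      }
  List gw(L), gb(L);
  NumericVector ga(L);
  grow(S.dz, nr * (size_t)g);
  grow(S.colbuf, nr);
  for (int l = L - 1; l >= 0; --l) {
    int Cin = C + l * g;
    float a = (float)slopes[l];
    // total gradient of h_l: read back from the padded accumulator interior
    fmat dZ(S.dz.data(), nr, g, false, true);
    const float* zp = S.zs.data() + (size_t)l * nr * g;
    double da = 0.0;
    for (int c = 0; c < g; ++c) {
      float* dst = dZ.colptr(c);
      for (int n = 0; n < d.N; ++n)
        for (int w = 0; w < S.W; ++w) {
          const float* src = S.acc.data() + 1 +
            (size_t)Hp * ((w + 1) + (size_t)Wp * ((Cin + c) + (size_t)Ctot * n));
          memcpy(dst + (size_t)n * HW + (size_t)S.H * w, src,
                 S.H * sizeof(float));
        }
    }
    // PReLU backward (in place on dZ)
    {
      float* dzp = dZ.memptr();
      for (size_t i = 0; i < nr * (size_t)g; ++i)
        if (zp[i] < 0) { da += (double)dzp[i] * zp[i]; dzp[i] *= a; }
    }
    ga[l] = da;
    fmat wl = arma::conv_to<fmat>::from(as<arma::mat>(layer_w[l]));
    fmat colsv(S.cols.data(), nr, 9 * (size_t)Cin, false, true);
    gw[l] = arma::conv_to<mat>::from(colsv.t() * dZ);
    gb[l] = arma::conv_to<vec>::from(arma::sum(dZ, 0).t());
    // data gradient: per im2col column j = (ki,kj,c), a cache-resident
    // matvec scattered back into the padded accumulator
    fmat cb(S.colbuf.data(), nr, 1, false, true);
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < 3; ++kj)
        for (int ki = 0; ki < 3; ++ki) {
          int j = ki + 3 * kj + 9 * c;
          cb = dZ * wl.row(j).t();
          const float* src = cb.memptr();
          for (int n = 0; n < d.N; ++n) {
            float* base = S.acc.data() +
              (size_t)Hp * Wp * (c + (size_t)Ctot * n);
            const float* s = src + (size_t)n * HW;
            for (int w = 0; w < S.W; ++w) {
              float* dst = base + ki + (size_t)Hp * (kj + w);
              for (int h = 0; h < S.H; ++h) dst[h] += s[h];
              s += S.H;
            }
          }
        }
  }
  // block-input gradient: accumulator interior channels 0..C-1 + residual
  NumericVector dx((R_xlen_t)(nr * C));
  dx.attr("dim") = IntegerVector::create(S.H, S.W, C, d.N);
  double* op = REAL(dx);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < d.N; ++n)
      for (int w = 0; w < S.W; ++w) {
        const float* src = S.acc.data() + 1 +
          (size_t)Hp * ((w + 1) + (size_t)Wp * (c + (size_t)Ctot * n));
        const double* rg = dp + HW * (c + (size_t)C * n) + (size_t)S.H * w;
        double* dst = op + HW * (c + (size_t)C * n) + (size_t)S.H * w;
        for (int h = 0; h < S.H; ++h) dst[h] = (double)src[h] + rg[h];
      }
  return List::create(_["dx"] = dx, _["dw"] = gw, _["db"] = gb,
                      _["da"] = ga, _["fuse_dw"] = dWf, _["fuse_db"] = dbf);
}
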