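// Operational (Self-ONN) convolution and max-pooling kernels.
//
// Layout conventions (all column-major, matching the R arrays):
//   feature batch x : dim (C, H, W, N)
//   weights W       : dim (C_out, C_in, Q, kh, kw)
//   im2col rows     : r = dc + kw*(dr + kh*(q + Q*i))   [0-based]
//   im2col cols     : col = h + Hout*w
// The operational convolution is a standard cross-correlation applied to the
// power-stacked input (x - a)^q, q = 1..Q, so Q = 1 reduces exactly to a
// plain convolution layer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat weights_to_mat(const NumericVector &Warr, int Cout, int Cin,
                                int Q, int kh, int kw) {
  arma::mat Wm(Cout, Cin * Q * kh * kw);
  const double *w = Warr.begin();
  for (int k = 0; k < Cout; ++k)
    for (int i = 0; i < Cin; ++i)
      for (int q = 0; q < Q; ++q)
        for (int dr = 0; dr < kh; ++dr)
          for (int dc = 0; dc < kw; ++dc) {
            int row = dc + kw * (dr + kh * (q + Q * i));
            // R array index for (k,i,q,dr,dc)
            size_t idx = k + (size_t)Cout * (i + (size_t)Cin * (q + (size_t)Q * (dr + (size_t)kh * dc)));
            Wm(k, row) = w[idx];
          }
  return Wm;
}

static void mat_to_weights(const arma::mat &Wm, double *w, int Cout, int Cin,
                           int Q, int kh, int kw) {
  for (int k = 0; k < Cout; ++k)
    for (int i = 0; i < Cin; ++i)
      for (int q = 0; q < Q; ++q)
        for (int dr = 0; dr < kh; ++dr)
          for (int dc = 0; dc < kw; ++dc) {
            int row = dc + kw * (dr + kh * (q + Q * i));
            size_t idx = k + (size_t)Cout * (i + (size_t)Cin * (q + (size_t)Q * (dr + (size_t)kh * dc)));
            w[idx] = Wm(k, row);
          }
}

// power stack: P has C*Q channels, channel (i*Q+q) = (x_i - a)^(q+1)
static void power_stack(const double *x, double *P, int C, int H, int W,
                        int Q, double a) {
  size_t plane = (size_t)H * W;
  for (size_t hw = 0; hw < plane; ++hw)
    for (int i = 0; i < C; ++i) {
      double v = x[i + C * hw] - a;
      double p = 1.0;
      for (int q = 0; q < Q; ++q) {
        p *= v;
        P[(i * Q + q) + (size_t)C * Q * hw] = p;
      }
    }
}

// im2col over a (CC,H,W) image with zero padding (ph,pw), stride 1
static void im2col(const double *P, arma::mat &Xcol, int CC, int H, int W,
                   int kh, int kw, int ph, int pw) {
  int Hout = H, Wout = W; // same padding assumed: ph=(kh-1)/2 etc.
  Hout = H + 2 * ph - kh + 1;
  Wout = W + 2 * pw - kw + 1;
  for (int wo = 0; wo < Wout; ++wo)
    for (int ho = 0; ho < Hout; ++ho) {
      int col = ho + Hout * wo;
      for (int i = 0; i < CC; ++i)
        for (int dr = 0; dr < kh; ++dr)
          for (int dc = 0; dc < kw; ++dc) {
            int h = ho + dr - ph, w = wo + dc - pw;
            int row = dc + kw * (dr + kh * i);
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W)
              v = P[i + (size_t)CC * (h + (size_t)H * w)];
            Xcol(row, col) = v;
          }
    }
}

static void col2im_acc(const arma::mat &Xcol, double *P, int CC, int H, int W,
                       int kh, int kw, int ph, int pw) {
  int Hout = H + 2 * ph - kh + 1;
  int Wout = W + 2 * pw - kw + 1;
  for (int wo = 0; wo < Wout; ++wo)
    for (int ho = 0; ho < Hout; ++ho) {
      int col = ho + Hout * wo;
      for (int i = 0; i < CC; ++i)
        for (int dr = 0; dr < kh; ++dr)
          for (int dc = 0; dc < kw; ++dc) {
            int h = ho + dr - ph, w = wo + dc - pw;
            if (h >= 0 && h < H && w >= 0 && w < W)
              P[i + (size_t)CC * (h + (size_t)H * w)] +=
                  Xcol(dc + kw * (dr + kh * i), col);
          }
    }
}

// [[Rcpp::export]]
NumericVector cpp_opconv_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector Warr, NumericVector bias,
                                 int Q, double a, int ph, int pw) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Cout = bias.size();
  int wlen = Warr.size();
  int khkw = wlen / (Cout * C * Q);
  // weights dim (Cout, C, Q, kh, kw); kh, kw recovered from attribute-free call
  IntegerVector wd = Warr.attr("dim");
  int kh = wd[3], kw = wd[4];
  if (khkw != kh * kw) stop("weight dims inconsistent");
  int Hout = H + 2 * ph - kh + 1, Wout = W + 2 * pw - kw + 1;
  if (Hout < 1 || Wout < 1) stop("kernel larger than padded input");

  arma::mat Wm = weights_to_mat(Warr, Cout, C, Q, kh, kw);
  arma::colvec b(bias.begin(), Cout);

  NumericVector y((size_t)Cout * Hout * Wout * N);
  std::vector<double> P((size_t)C * Q * H * W);
  arma::mat Xcol(C * Q * kh * kw, (size_t)Hout * Wout);
  size_t xstride = (size_t)C * H * W, ystride = (size_t)Cout * Hout * Wout;
  for (int n = 0; n < N; ++n) {
    power_stack(x.begin() + n * xstride, P.data(), C, H, W, Q, a);
    im2col(P.data(), Xcol, C * Q, H, W, kh, kw, ph, pw);
    arma::mat Y = Wm * Xcol;
    Y.each_col() += b;
    std::copy(Y.begin(), Y.end(), y.begin() + n * ystride);
  }
  y.attr("dim") = IntegerVector::create(Cout, Hout, Wout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_opconv_backward(NumericVector x, IntegerVector xdim,
                         NumericVector Warr, NumericVector dy,
                         int Q, double a, int ph, int pw) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  IntegerVector wd = Warr.attr("dim");
  int Cout = wd[0], kh = wd[3], kw = wd[4];
  int Hout = H + 2 * ph - kh + 1, Wout = W + 2 * pw - kw + 1;

  arma::mat Wm = weights_to_mat(Warr, Cout, C, Q, kh, kw);
  arma::mat dWm(Cout, C * Q * kh * kw, arma::fill::zeros);
  arma::colvec db(Cout, arma::fill::zeros);
  NumericVector dx((size_t)C * H * W * N);

  std::vector<double> P((size_t)C * Q * H * W), dP((size_t)C * Q * H * W);
  arma::mat Xcol(C * Q * kh * kw, (size_t)Hout * Wout);
  size_t xstride = (size_t)C * H * W, ystride = (size_t)Cout * Hout * Wout;
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + n * xstride;
    power_stack(xn, P.data(), C, H, W, Q, a);
    im2col(P.data(), Xcol, C * Q, H, W, kh, kw, ph, pw);
    arma::mat dY(const_cast<double *>(dy.begin()) + n * ystride, Cout,
                 (size_t)Hout * Wout, false, true);
    dWm += dY * Xcol.t();
    db += arma::sum(dY, 1);
    arma::mat dXcol = Wm.t() * dY;
    std::fill(dP.begin(), dP.end(), 0.0);
    col2im_acc(dXcol, dP.data(), C * Q, H, W, kh, kw, ph, pw);
    // chain through the powers: d/dx (x-a)^(q+1) = (q+1)(x-a)^q
    double *dxn = dx.begin() + n * xstride;
    size_t plane = (size_t)H * W;
    for (size_t hw = 0; hw < plane; ++hw)
      for (int i = 0; i < C; ++i) {
        double v = xn[i + C * hw] - a, p = 1.0, g = 0.0;
        for (int q = 0; q < Q; ++q) {
          g += dP[(i * Q + q) + (size_t)C * Q * hw] * (q + 1) * p;
          p *= v;
        }
        dxn[i + C * hw] = g;
      }
  }

  NumericVector dW(Warr.size());
  mat_to_weights(dWm, dW.begin(), Cout, C, Q, kh, kw);
  dW.attr("dim") = wd;
  NumericVector dbv(db.begin(), db.end());
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["dW"] = dW, _["db"] = dbv, _["dx"] = dx);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim, int ph, int pw,
                         int sh, int sw) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Hout = (H - ph) / sh + 1, Wout = (W - pw) / sw + 1; // floor, no ceil mode
  if (Hout < 1 || Wout < 1) stop("pool window larger than input");
  NumericVector y((size_t)C * Hout * Wout * N);
  IntegerVector idx(y.size()); // flat 0-based index into the input batch
  size_t xstride = (size_t)C * H * W, ystride = (size_t)C * Hout * Wout;
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + n * xstride;
    for (int wo = 0; wo < Wout; ++wo)
      for (int ho = 0; ho < Hout; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL;
          size_t besti = 0;
          for (int dr = 0; dr < ph; ++dr)
            for (int dc = 0; dc < pw; ++dc) {
              int h = ho * sh + dr, w = wo * sw + dc;
              size_t ii = c + (size_t)C * (h + (size_t)H * w);
              if (xn[ii] > best) { best = xn[ii]; besti = ii; }
            }
          size_t oi = c + (size_t)C * (ho + (size_t)Hout * wo) + n * ystride;
          y[oi] = best;
          idx[oi] = (int)(besti + n * xstride);
        }
  }
  y.attr("dim") = IntegerVector::create(C, Hout, Wout, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t j = 0; j < dy.size(); ++j) dx[idx[j]] += dy[j];
  dx.attr("dim") = xdim;
  return dx;
}
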