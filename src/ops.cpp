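// Low-level numeric kernels for the network engine: same-padding
// convolutions (via im2col + BLAS gemm), 2x2 max pooling, stride-2
// transposed convolutions, separable Gaussian blur and linear resampling.
// Layouts follow R column-major arrays:
//   2D activations (H, W, C, N); 3D activations (H, W, D, C, N)
//   conv weights   (k, k, Cin, Cout) / (k, k, k, Cin, Cout)
//   upconv weights (2, 2, Cin, Cout) / (2, 2, 2, Cin, Cout)

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------- im2col --

static void im2col2d(const double* x, int H, int W, int C, int k,
                     arma::mat& cols) {
  const int pad = (k - 1) / 2;
  const long kkC = (long)k * k * C;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const long row = ki + (long)k * (kj + (long)k * c);
        double* out = cols.memptr() + row;
        for (int j = 0; j < W; ++j) {
          const int xj = j + kj - pad;
          const bool jin = (xj >= 0 && xj < W);
          for (int i = 0; i < H; ++i) {
            const int xi = i + ki - pad;
            double v = 0.0;
            if (jin && xi >= 0 && xi < H) v = xc[xi + (long)H * xj];
            out[kkC * (i + (long)H * j)] = v;
          }
        }
      }
    }
  }
}

static void col2im2d(const arma::mat& cols, int H, int W, int C, int k,
                     double* dx) {
  const int pad = (k - 1) / 2;
  const long kkC = (long)k * k * C;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (long)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const long row = ki + (long)k * (kj + (long)k * c);
        const double* in = cols.memptr() + row;
        for (int j = 0; j < W; ++j) {
          const int xj = j + kj - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int xi = i + ki - pad;
            if (xi < 0 || xi >= H) continue;
            xc[xi + (long)H * xj] += in[kkC * (i + (long)H * j)];
          }
        }
      }
    }
  }
}

static void im2col3d(const double* x, int H, int W, int D, int C, int k,
                     arma::mat& cols) {
  const int pad = (k - 1) / 2;
  const long kkkC = (long)k * k * k * C;
  const long HW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + HW * D * c;
    for (int kd = 0; kd < k; ++kd) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const long row = ki + (long)k * (kj + (long)k * (kd + (long)k * c));
          double* out = cols.memptr() + row;
          for (int d = 0; d < D; ++d) {
            const int xd = d + kd - pad;
            const bool din = (xd >= 0 && xd < D);
            for (int j = 0; j < W; ++j) {
              const int xj = j + kj - pad;
              const bool jin = din && (xj >= 0 && xj < W);
              for (int i = 0; i < H; ++i) {
                const int xi = i + ki - pad;
                double v = 0.0;
                if (jin && xi >= 0 && xi < H)
                  v = xc[xi + (long)H * xj + HW * xd];
                out[kkkC * (i + (long)H * j + HW * d)] = v;
              }
            }
          }
        }
      }
    }
  }
}

static void col2im3d(const arma::mat& cols, int H, int W, int D, int C, int k,
                     double* dx) {
  const int pad = (k - 1) / 2;
  const long kkkC = (long)k * k * k * C;
  const long HW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + HW * D * c;
    for (int kd = 0; kd < k; ++kd) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const long row = ki + (long)k * (kj + (long)k * (kd + (long)k * c));
          const double* in = cols.memptr() + row;
          for (int d = 0; d < D; ++d) {
            const int xd = d + kd - pad;
            if (xd < 0 || xd >= D) continue;
            for (int j = 0; j < W; ++j) {
              const int xj = j + kj - pad;
              if (xj < 0 || xj >= W) continue;
              for (int i = 0; i < H; ++i) {
                const int xi = i + ki - pad;
                if (xi < 0 || xi >= H) continue;
                xc[xi + (long)H * xj + HW * xd] +=
                  in[kkkC * (i + (long)H * j + HW * d)];
              }
            }
          }
        }
      }
    }
  }
}

// ----------------------------------------------------------- convolution --

// rank-agnostic driver: P = number of spatial positions per sample,
// K = k^rank * Cin rows of the unfolded input.
// [[Rcpp::export]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       IntegerVector spatial, int cin, int cout, int n,
                       int k) {
  const int rank = spatial.size();
  long P = 1;
  for (int a = 0; a < rank; ++a) P *= spatial[a];
  long K = cin;
  for (int a = 0; a < rank; ++a) K *= k;
  const long xs = P * cin, ys = P * cout;

  NumericVector y(ys * n);
  arma::mat W(w.begin(), K, cout, false);
  arma::rowvec bias(b.begin(), cout);

  arma::mat cols;
  if (k > 1) cols.set_size(K, P);
  for (int s = 0; s < n; ++s) {
    const double* xp = x.begin() + xs * s;
    arma::mat Y(y.begin() + ys * s, P, cout, false, true);
    if (k == 1) {
      arma::mat X(const_cast<double*>(xp), P, cin, false);
      Y = X * W;
    } else {
      if (rank == 2) im2col2d(xp, spatial[0], spatial[1], cin, k, cols);
      else im2col3d(xp, spatial[0], spatial[1], spatial[2], cin, k, cols);
      Y = cols.t() * W;
    }
    Y.each_row() += bias;
  }
  return y;
}

// [[Rcpp::export]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
              IntegerVector spatial, int cin, int cout, int n, int k) {
  const int rank = spatial.size();
  long P = 1;
  for (int a = 0; a < rank; ++a) P *= spatial[a];
  long K = cin;
  for (int a = 0; a < rank; ++a) K *= k;
  const long xs = P * cin, ys = P * cout;

  NumericVector dx(xs * n), dw(K * cout);
  NumericVector db(cout);
  arma::mat W(w.begin(), K, cout, false);
  arma::mat dW(dw.begin(), K, cout, false, true);
  arma::rowvec dB(db.begin(), cout, false, true);

  arma::mat cols;
  if (k > 1) cols.set_size(K, P);
  for (int s = 0; s < n; ++s) {
    const double* xp = x.begin() + xs * s;
    arma::mat dY(dy.begin() + ys * s, P, cout, false);
    dB += arma::sum(dY, 0);
    if (k == 1) {
      arma::mat X(const_cast<double*>(xp), P, cin, false);
      arma::mat dX(dx.begin() + xs * s, P, cin, false, true);
      dX = dY * W.t();
      dW += X.t() * dY;
    } else {
      if (rank == 2) im2col2d(xp, spatial[0], spatial[1], cin, k, cols);
      else im2col3d(xp, spatial[0], spatial[1], spatial[2], cin, k, cols);
      dW += cols * dY;
      arma::mat dcols = W * dY.t();  // K x P
      if (rank == 2)
        col2im2d(dcols, spatial[0], spatial[1], cin, k, dx.begin() + xs * s);
      else
        col2im3d(dcols, spatial[0], spatial[1], spatial[2], cin, k,
                 dx.begin() + xs * s);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------------------------ max pooling --

// 2x2 (2x2x2) window, stride 2; records winner offsets for the backward pass.
// [[Rcpp::export]]
List pool_fwd(NumericVector x, IntegerVector spatial, int c, int n) {
  const int rank = spatial.size();
  long P = 1, Q = 1;
  std::vector<int> outsp(rank);
  for (int a = 0; a < rank; ++a) {
    P *= spatial[a];
    outsp[a] = spatial[a] / 2;
    Q *= outsp[a];
  }
  const long planes = (long)c * n;
  NumericVector y(Q * planes);
  IntegerVector idx(Q * planes);
  const int H = spatial[0], W = spatial[1];
  const int D = (rank == 3) ? spatial[2] : 1;
  const int oH = outsp[0], oW = outsp[1];
  const int oD = (rank == 3) ? outsp[2] : 1;
  const long HW = (long)H * W;
  for (long pl = 0; pl < planes; ++pl) {
    const double* xp = x.begin() + P * pl;
    double* yp = y.begin() + Q * pl;
    int* ip = idx.begin() + Q * pl;
    for (int d = 0; d < oD; ++d) {
      for (int j = 0; j < oW; ++j) {
        for (int i = 0; i < oH; ++i) {
          double best = -1e308;
          long bidx = 0;
          const int dmax = (rank == 3) ? 2 : 1;
          for (int dd = 0; dd < dmax; ++dd)
            for (int jj = 0; jj < 2; ++jj)
              for (int ii = 0; ii < 2; ++ii) {
                long off = (2 * i + ii) + (long)H * (2 * j + jj) +
                           HW * (2 * d + dd);
                if (xp[off] > best) { best = xp[off]; bidx = off; }
              }
          long o = i + (long)oH * j + (long)oH * oW * d;
          yp[o] = best;
          ip[o] = (int)bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_bwd(NumericVector dy, IntegerVector idx,
                       IntegerVector spatial, int c, int n) {
  const int rank = spatial.size();
  long P = 1, Q = 1;
  for (int a = 0; a < rank; ++a) {
    P *= spatial[a];
    Q *= spatial[a] / 2;
  }
  const long planes = (long)c * n;
  NumericVector dx(P * planes);
  for (long pl = 0; pl < planes; ++pl) {
    const double* dyp = dy.begin() + Q * pl;
    const int* ip = idx.begin() + Q * pl;
    double* dxp = dx.begin() + P * pl;
    for (long q = 0; q < Q; ++q) dxp[ip[q]] += dyp[q];
  }
  return dx;
}

// -------------------------------------------------- transposed convolution --

// kernel 2 (2x2 / 2x2x2), stride 2: each input position paints a disjoint
// 2^rank output patch, so the op is a gemm followed by a scatter.
// [[Rcpp::export]]
NumericVector upconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                         IntegerVector spatial, int cin, int cout, int n) {
  const int rank = spatial.size();
  const int H = spatial[0], W = spatial[1];
  const int D = (rank == 3) ? spatial[2] : 1;
  const long P = (long)H * W * D;
  const int noff = 1 << rank;
  const long xs = P * cin, ys = P * noff * cout;
  NumericVector y(ys * n);

  const int oH = 2 * H, oW = 2 * W;
  const long oHW = (long)oH * oW;
  const long ostride = oHW * ((rank == 3) ? 2L * D : 1L);  // per channel
  for (int s = 0; s < n; ++s) {
    arma::mat X(x.begin() + xs * s, P, cin, false);
    double* yp = y.begin() + ys * s;
    for (int off = 0; off < noff; ++off) {
      const int a = off & 1, bb = (off >> 1) & 1, dd = (off >> 2) & 1;
      // gather W[a,bb,dd, , ] -> (cin x cout)
      arma::mat Wo(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wo(ci, co) = w[off + (long)noff * (ci + (long)cin * co)];
      arma::mat Yo = X * Wo;  // P x cout
      for (int co = 0; co < cout; ++co) {
        const double* src = Yo.colptr(co);
        double* dst = yp + ostride * co;
        double bias = b[co];
        for (int d = 0; d < D; ++d)
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              long o = (2 * i + a) + (long)oH * (2 * j + bb) +
                       oHW * (2 * d + dd);
              dst[o] = src[i + (long)H * j + (long)H * W * d] + bias;
            }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                IntegerVector spatial, int cin, int cout, int n) {
  const int rank = spatial.size();
  const int H = spatial[0], W = spatial[1];
  const int D = (rank == 3) ? spatial[2] : 1;
  const long P = (long)H * W * D;
  const int noff = 1 << rank;
  const long xs = P * cin, ys = P * noff * cout;

  NumericVector dx(xs * n), dw((long)noff * cin * cout), db(cout);
  const int oH = 2 * H, oW = 2 * W;
  const long oHW = (long)oH * oW;
  const long ostride = oHW * ((rank == 3) ? 2L * D : 1L);  // per channel
  arma::mat dYo(P, cout);
  for (int s = 0; s < n; ++s) {
    arma::mat X(x.begin() + xs * s, P, cin, false);
    arma::mat dX(dx.begin() + xs * s, P, cin, false, true);
    const double* dyp = dy.begin() + ys * s;
    for (int off = 0; off < noff; ++off) {
      const int a = off & 1, bb = (off >> 1) & 1, dd = (off >> 2) & 1;
      for (int co = 0; co < cout; ++co) {
        double* dst = dYo.colptr(co);
        const double* src = dyp + ostride * co;
        double acc = 0.0;
        for (int d = 0; d < D; ++d)
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              long o = (2 * i + a) + (long)oH * (2 * j + bb) +
                       oHW * (2 * d + dd);
              double v = src[o];
              dst[i + (long)H * j + (long)H * W * d] = v;
              acc += v;
            }
        db[co] += acc;
      }
      arma::mat Wo(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wo(ci, co) = w[off + (long)noff * (ci + (long)cin * co)];
      dX += dYo * Wo.t();
      arma::mat dWo = X.t() * dYo;  // cin x cout
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          dw[off + (long)noff * (ci + (long)cin * co)] += dWo(ci, co);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ------------------------------------------------- blur / linear resample --

// separable Gaussian blur over the first `rank` axes of an array whose dims
// are (spatial..., trailing); trailing axes (channels, batch) are untouched.
// Border handling: replicate.
static void blur_axis(std::vector<double>& buf, double* x,
                      const std::vector<long>& dims, int axis, int rank_all,
                      const std::vector<double>& kern) {
  const int r = (int)kern.size() / 2;
  long stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  const long n = dims[axis];
  long outer = 1;
  for (int a = axis + 1; a < rank_all; ++a) outer *= dims[a];
  long inner = stride;
  for (long o = 0; o < outer; ++o) {
    for (long in = 0; in < inner; ++in) {
      double* base = x + o * stride * n + in;
      for (long t = 0; t < n; ++t) buf[t] = base[t * stride];
      for (long t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int q = -r; q <= r; ++q) {
          long u = t + q;
          if (u < 0) u = 0;
          if (u >= n) u = n - 1;
          acc += kern[q + r] * buf[u];
        }
        base[t * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector gauss_blur(NumericVector x, IntegerVector dims, int rank,
                         double sigma) {
  NumericVector y = clone(x);
  if (sigma <= 0) return y;
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int q = -r; q <= r; ++q) {
    kern[q + r] = std::exp(-0.5 * q * q / (sigma * sigma));
    s += kern[q + r];
  }
  for (auto& v : kern) v /= s;
  std::vector<long> d(dims.size());
  long maxd = 0;
  for (int a = 0; a < dims.size(); ++a) {
    d[a] = dims[a];
    if (d[a] > maxd) maxd = d[a];
  }
  std::vector<double> buf(maxd);
  for (int a = 0; a < rank; ++a)
    blur_axis(buf, y.begin(), d, a, (int)d.size(), kern);
  return y;
}

// linear resampling of the first `rank` axes from dims to odims; trailing
// axes preserved. Applied one axis at a time.
// [[Rcpp::export]]
NumericVector resize_linear(NumericVector x, IntegerVector dims,
                            IntegerVector odims, int rank) {
  std::vector<long> cur(dims.size());
  for (int a = 0; a < dims.size(); ++a) cur[a] = dims[a];
  NumericVector src = x;
  for (int axis = 0; axis < rank; ++axis) {
    const long n = cur[axis], m = odims[axis];
    if (n == m) continue;
    long stride = 1;
    for (int a = 0; a < axis; ++a) stride *= cur[a];
    long outer = 1;
    for (size_t a = axis + 1; a < cur.size(); ++a) outer *= cur[a];
    long total_out = stride * m * outer;
    NumericVector dst(total_out);
    const double scale = (double)n / (double)m;
    for (long o = 0; o < outer; ++o) {
      const double* sbase = src.begin() + o * stride * n;
      double* dbase = dst.begin() + o * stride * m;
      for (long t = 0; t < m; ++t) {
        double pos = (t + 0.5) * scale - 0.5;
        long i0 = (long)std::floor(pos);
        double f = pos - i0;
        long i1 = i0 + 1;
        if (i0 < 0) i0 = 0;
        if (i1 > n - 1) i1 = n - 1;
        for (long in = 0; in < stride; ++in)
          dbase[t * stride + in] = (1.0 - f) * sbase[i0 * stride + in] +
                                   f * sbase[i1 * stride + in];
      }
    }
    src = dst;
    cur[axis] = m;
  }
  return src;
}

// ------------------------------------------------------ batch norm ----

// x layout (P, C, N) flattened; per-channel statistics over P and N.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, int P, int C, int n, NumericVector gamma,
            NumericVector beta, NumericVector runMean, NumericVector runVar,
            bool training, double momentum, double eps) {
  NumericVector y(x.size());
  NumericVector m(C), ivar(C);
  NumericVector newMean = clone(runMean), newVar = clone(runVar);
  const long PC = (long)P * C;
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < n; ++b) {
        const double* xp = x.begin() + (long)P * c + PC * b;
        for (int p = 0; p < P; ++p) { s += xp[p]; s2 += xp[p] * xp[p]; }
      }
      const double npc = (double)P * n;
      double mu = s / npc;
      double v = s2 / npc - mu * mu;
      if (v < 0) v = 0;
      m[c] = mu;
      ivar[c] = 1.0 / std::sqrt(v + eps);
      double vu = (npc > 1) ? v * npc / (npc - 1) : v;
      newMean[c] = (1 - momentum) * runMean[c] + momentum * mu;
      newVar[c] = (1 - momentum) * runVar[c] + momentum * vu;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      m[c] = runMean[c];
      ivar[c] = 1.0 / std::sqrt(runVar[c] + eps);
    }
  }
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] * ivar[c];
    const double bb = beta[c] - a * m[c];
    for (int b = 0; b < n; ++b) {
      const double* xp = x.begin() + (long)P * c + PC * b;
      double* yp = y.begin() + (long)P * c + PC * b;
      for (int p = 0; p < P; ++p) yp[p] = a * xp[p] + bb;
    }
  }
  return List::create(_["y"] = y, _["m"] = m, _["ivar"] = ivar,
                      _["runMean"] = newMean, _["runVar"] = newVar);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector dy, int P, int C, int n,
            NumericVector gamma, NumericVector m, NumericVector ivar) {
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const long PC = (long)P * C;
  const double npc = (double)P * n;
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int b = 0; b < n; ++b) {
      const double* xp = x.begin() + (long)P * c + PC * b;
      const double* dp = dy.begin() + (long)P * c + PC * b;
      for (int p = 0; p < P; ++p) {
        sg += dp[p] * (xp[p] - m[c]) * ivar[c];
        sb += dp[p];
      }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double a = gamma[c] * ivar[c];
    for (int b = 0; b < n; ++b) {
      const double* xp = x.begin() + (long)P * c + PC * b;
      const double* dp = dy.begin() + (long)P * c + PC * b;
      double* op = dx.begin() + (long)P * c + PC * b;
      for (int p = 0; p < P; ++p) {
        double xhat = (xp[p] - m[c]) * ivar[c];
        op[p] = a * (dp[p] - sb / npc - xhat * sg / npc);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ------------------------------------------------------------- relu ----

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (long i = 0; i < (long)x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector g, NumericVector x) {
  NumericVector dx(x.size());
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dp = dx.begin();
  for (long i = 0; i < (long)x.size(); ++i) dp[i] = xp[i] > 0 ? gp[i] : 0;
  return dx;
}
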