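// Low-level tensor primitives for the multi-output U-Net.
//
// Layout convention (R column-major): activations are 4-D arrays
// (H, W, C, N); conv kernels are (kh, kw, Cin, Cout); 2x2 transposed-conv
// kernels are (2, 2, Cin, Cout).  All convolutions are SAME-padded, stride 1;
// pooling and transposed convolution use stride 2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void check_dim4(const NumericVector& x, const char* what) {
  RObject d = x.attr("dim");
  if (d.isNULL() || as<IntegerVector>(d).size() != 4)
    stop("%s must be a 4-d array", what);
}

// im2col for one sample: P is (H*W) x (kh*kw*Ci), column index
// r = dy + kh*dx + kh*kw*ci matches the column-major flattening of the
// kernel array (kh, kw, Ci, Co).
static void im2col(const double* xs, int H, int W, int Ci, int kh, int kw,
                   arma::mat& P) {
  const int ph = kh / 2, pw = kw / 2;
  const size_t HW = (size_t)H * W;
  P.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = xs + (size_t)ci * HW;
    for (int dx = 0; dx < kw; ++dx) {
      for (int dy = 0; dy < kh; ++dy) {
        const int col = dy + kh * dx + kh * kw * ci;
        double* Pc = P.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pw;
          if (sj < 0 || sj >= W) continue;
          const double* xcol = xc + (size_t)sj * H;
          double* pcol = Pc + (size_t)j * H;
          const int i0 = std::max(0, ph - dy);
          const int i1 = std::min(H, H + ph - dy);
          for (int i = i0; i < i1; ++i) pcol[i] = xcol[i + dy - ph];
        }
      }
    }
  }
}

// col2im accumulate: inverse scatter of im2col.
static void col2im_add(const arma::mat& P, int H, int W, int Ci, int kh,
                       int kw, double* xs) {
  const int ph = kh / 2, pw = kw / 2;
  const size_t HW = (size_t)H * W;
  for (int ci = 0; ci < Ci; ++ci) {
    double* xc = xs + (size_t)ci * HW;
    for (int dx = 0; dx < kw; ++dx) {
      for (int dy = 0; dy < kh; ++dy) {
        const int col = dy + kh * dx + kh * kw * ci;
        const double* Pc = P.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dx - pw;
          if (sj < 0 || sj >= W) continue;
          double* xcol = xc + (size_t)sj * H;
          const double* pcol = Pc + (size_t)j * H;
          const int i0 = std::max(0, ph - dy);
          const int i1 = std::min(H, H + ph - dy);
          for (int i = i0; i < i1; ++i) xcol[i + dy - ph] += pcol[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  check_dim4(x, "x"); check_dim4(w, "w");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != Ci) stop("kernel input channels (%d) != activation channels (%d)", (int)wd[2], Ci);
  if (b.size() != Co) stop("bias length mismatch");
  const size_t HW = (size_t)H * W;
  const int K = kh * kw * Ci;
  arma::mat Wm(w.begin(), K, Co, false, true);
  arma::rowvec bv(b.begin(), Co);
  NumericVector out(HW * Co * N);
  out.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat P(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * Ci, H, W, Ci, kh, kw, P);
    arma::mat O(out.begin() + (size_t)n * HW * Co, HW, Co, false, true);
    O = P * Wm;
    O.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  check_dim4(x, "x"); check_dim4(w, "w"); check_dim4(gy, "gy");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const size_t HW = (size_t)H * W;
  const int K = kh * kw * Ci;
  arma::mat Wm(w.begin(), K, Co, false, true);
  NumericVector gx(HW * Ci * N);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  arma::mat Gw(gw.begin(), K, Co, false, true);
  arma::rowvec Gb(gb.begin(), Co, false, true);
  arma::mat P(HW, K), GP(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * Ci, H, W, Ci, kh, kw, P);
    arma::mat Gy(gy.begin() + (size_t)n * HW * Co, HW, Co, false, true);
    Gw += P.t() * Gy;
    Gb += arma::sum(Gy, 0);
    GP = Gy * Wm.t();
    col2im_add(GP, H, W, Ci, kh, kw, gx.begin() + (size_t)n * HW * Ci);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution: out(2i+dy, 2j+dx, co) =
// sum_ci x(i, j, ci) * w(dy, dx, ci, co) + b[co].  Output blocks do not
// overlap, so forward and backward are simple gather/scatter GEMMs.
// [[Rcpp::export]]
NumericVector convt2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  check_dim4(x, "x"); check_dim4(w, "w");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != Ci) stop("convt2 kernel must be (2,2,Ci,Co)");
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector out(HWo * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat O(HW, Co);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Ci, HW, Ci, false, true);
    double* os = out.begin() + (size_t)n * HWo * Co;
    for (int dx = 0; dx < 2; ++dx) {
      for (int dy = 0; dy < 2; ++dy) {
        arma::mat Wsub(Ci, Co);
        for (int co = 0; co < Co; ++co)
          for (int ci = 0; ci < Ci; ++ci)
            Wsub(ci, co) = w[dy + 2 * dx + 4 * ci + 4 * Ci * co];
        O = X * Wsub;
        for (int co = 0; co < Co; ++co) {
          const double* oc = O.colptr(co);
          double* dst = os + (size_t)co * HWo;
          const double bc = b[co];
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[(size_t)(2 * i + dy) + (size_t)Ho * (2 * j + dx)] =
                  oc[(size_t)i + (size_t)H * j] + bc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List convt2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  check_dim4(x, "x"); check_dim4(w, "w"); check_dim4(gy, "gy");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector gx(HW * Ci * N);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  arma::mat Gsub(HW, Co);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * HW * Ci, HW, Ci, false, true);
    arma::mat Gx(gx.begin() + (size_t)n * HW * Ci, HW, Ci, false, true);
    const double* gs = gy.begin() + (size_t)n * HWo * Co;
    for (int dx = 0; dx < 2; ++dx) {
      for (int dy = 0; dy < 2; ++dy) {
        for (int co = 0; co < Co; ++co) {
          double* gc = Gsub.colptr(co);
          const double* src = gs + (size_t)co * HWo;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              gc[(size_t)i + (size_t)H * j] =
                  src[(size_t)(2 * i + dy) + (size_t)Ho * (2 * j + dx)];
        }
        arma::mat Wsub(Ci, Co);
        for (int co = 0; co < Co; ++co)
          for (int ci = 0; ci < Ci; ++ci)
            Wsub(ci, co) = w[dy + 2 * dx + 4 * ci + 4 * Ci * co];
        Gx += Gsub * Wsub.t();
        arma::mat Gwsub = X.t() * Gsub;  // Ci x Co
        for (int co = 0; co < Co; ++co)
          for (int ci = 0; ci < Ci; ++ci)
            gw[dy + 2 * dx + 4 * ci + 4 * Ci * co] += Gwsub(ci, co);
        for (int co = 0; co < Co; ++co)
          gb[co] += arma::accu(Gsub.col(co));
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2.  idx records the winning linear index (1-based,
// into x) for the backward scatter; ties go to the first element scanned
// (top-left first), which fixes the subgradient deterministically.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  check_dim4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims, got %d x %d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  const size_t HWo = (size_t)Ho * Wo, HW = (size_t)H * W;
  NumericVector y(HWo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * HW;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -HUGE_VAL; size_t bi = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy) {
              const size_t li = base + (size_t)(2 * i + dy) + (size_t)H * (2 * j + dx);
              if (x[li] > best) { best = x[li]; bi = li; }
            }
          y[o] = best;
          idx[o] = (int)(bi + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < gy.size(); ++k) gx[idx[k] - 1] += gy[k];
  return gx;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            double eps) {
  check_dim4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector y(x.size()); y.attr("dim") = xd;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      for (size_t k = 0; k < HW; ++k) { s += xc[k]; s2 += xc[k] * xc[k]; }
    }
    const double mc = s / m;
    double vc = s2 / m - mc * mc;
    if (vc < 0) vc = 0;
    mu[c] = mc; var[c] = vc;
    const double inv = gamma[c] / std::sqrt(vc + eps), bc = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      double* yc = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t k = 0; k < HW; ++k) yc[k] = (xc[k] - mc) * inv + bc;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_eval(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector mu, NumericVector var, double eps) {
  check_dim4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  NumericVector y(x.size()); y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double inv = gamma[c] / std::sqrt(var[c] + eps);
    const double off = beta[c] - mu[c] * inv;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      double* yc = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t k = 0; k < HW; ++k) yc[k] = xc[k] * inv + off;
    }
  }
  return y;
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector gamma, NumericVector mu,
            NumericVector var, double eps, NumericVector gy) {
  check_dim4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  const double m = (double)HW * N;
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps), mc = mu[c];
    double sg = 0.0, sgx = 0.0;  // sum(gy), sum(gy * xhat)
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      const double* gc = gy.begin() + ((size_t)n * C + c) * HW;
      for (size_t k = 0; k < HW; ++k) {
        sg += gc[k];
        sgx += gc[k] * (xc[k] - mc) * istd;
      }
    }
    gbeta[c] = sg; ggamma[c] = sgx;
    const double a = gamma[c] * istd;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * HW;
      const double* gc = gy.begin() + ((size_t)n * C + c) * HW;
      double* oc = gx.begin() + ((size_t)n * C + c) * HW;
      for (size_t k = 0; k < HW; ++k) {
        const double xh = (xc[k] - mc) * istd;
        oc[k] = a * (gc[k] - sg / m - xh * sgx / m);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
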