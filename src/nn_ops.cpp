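// Numerical kernels for the quality-regression network.
//
// Activation tensors cross the R/C++ boundary as numeric 3-d arrays with
// dimensions (P, C, b): P = H*W spatial positions (column-major by height),
// C channels, b samples. Convolutions are stride-1, zero-padded to preserve
// H x W, and are evaluated as one im2col + GEMM per batch so the heavy
// lifting happens inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// column layout of the patch matrix: row index = di + k*(dj + k*c), matching
// the (Cout x k*k*Cin) weight matrix built on the R side. The patch matrix
// and the GEMM run in single precision: the kernels are 3x3 (short
// accumulations), activations are O(1), and the optimizer tolerates 1e-6
// relative noise, while SGEMM roughly doubles BLAS throughput.
static arma::fmat im2col(const arma::cube& x, const int H, const int W,
                         const int k) {
  const int P = H * W, C = x.n_cols, b = x.n_slices, pad = (k - 1) / 2;
  arma::fmat col(k * k * C, (arma::uword)P * b, arma::fill::zeros);
  for (int n = 0; n < b; ++n) {
    const arma::mat& xs = x.slice(n);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        float* dst = col.colptr((arma::uword)P * n + i + (arma::uword)H * j);
        for (int c = 0; c < C; ++c) {
          const double* src = xs.colptr(c);
          for (int dj = 0; dj < k; ++dj) {
            const int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            const double* srcj = src + (arma::uword)H * jj;
            for (int di = 0; di < k; ++di) {
              const int ii = i + di - pad;
              if (ii < 0 || ii >= H) continue;
              dst[di + k * (dj + k * c)] = (float)srcj[ii];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = "cpp_conv_fwd")]]
arma::cube cpp_conv_fwd(const arma::cube& x, const int H, const int W,
                        const arma::mat& wmat, const arma::vec& bias,
                        const int k) {
  const int P = H * W, b = x.n_slices, Cout = wmat.n_rows;
  arma::fmat col = im2col(x, H, W, k);
  arma::fmat fw = arma::conv_to<arma::fmat>::from(wmat);
  arma::fmat out = fw * col;  // Cout x (P*b)
  out.each_col() += arma::conv_to<arma::fvec>::from(bias);
  arma::cube y(P, Cout, b);
  for (int n = 0; n < b; ++n) {
    arma::fmat blk =
        out.cols((arma::uword)P * n, (arma::uword)P * n + P - 1).t();
    y.slice(n) = arma::conv_to<arma::mat>::from(blk);
  }
  return y;
}

// [[Rcpp::export(name = "cpp_conv_bwd")]]
List cpp_conv_bwd(const arma::cube& x, const int H, const int W,
                  const arma::mat& wmat, const int k, const arma::cube& dout) {
  const int P = H * W, C = x.n_cols, b = x.n_slices;
  const int Cout = wmat.n_rows, pad = (k - 1) / 2;
  arma::fmat dout_mat(Cout, (arma::uword)P * b);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < b; ++n) {
    dout_mat.cols((arma::uword)P * n, (arma::uword)P * n + P - 1) =
        arma::conv_to<arma::fmat>::from(dout.slice(n).t());
    db += arma::sum(dout.slice(n), 0).t();
  }
  arma::fmat col = im2col(x, H, W, k);
  arma::fmat fw = arma::conv_to<arma::fmat>::from(wmat);
  arma::mat dw = arma::conv_to<arma::mat>::from(dout_mat * col.t());
  arma::fmat dcol = fw.t() * dout_mat;  // (k*k*C) x (P*b)
  arma::cube dx(P, C, b, arma::fill::zeros);
  for (int n = 0; n < b; ++n) {
    arma::mat& dxs = dx.slice(n);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const float* src =
            dcol.colptr((arma::uword)P * n + i + (arma::uword)H * j);
        for (int c = 0; c < C; ++c) {
          double* dst = dxs.colptr(c);
          for (int dj = 0; dj < k; ++dj) {
            const int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            double* dstj = dst + (arma::uword)H * jj;
            for (int di = 0; di < k; ++di) {
              const int ii = i + di - pad;
              if (ii < 0 || ii >= H) continue;
              dstj[ii] += (double)src[di + k * (dj + k * c)];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Fused batchnorm + leaky rectifier. Training mode normalizes with the
// biased batch variance over the (P, b) axes of each channel and updates the
// running moments in place of the returned copies; eval mode uses the
// running moments. Cache for backward: mu, invsd.
// [[Rcpp::export(name = "cpp_bn_act_fwd")]]
List cpp_bn_act_fwd(const arma::cube& x, const arma::vec& gamma,
                    const arma::vec& beta, const arma::vec& rmean,
                    const arma::vec& rvar, const double eps,
                    const double momentum, const double slope,
                    const bool training) {
  const int P = x.n_rows, C = x.n_cols, b = x.n_slices;
  const double N = (double)P * b;
  arma::vec mu(C), var(C);
  if (training) {
    mu.zeros();
    var.zeros();
    for (int n = 0; n < b; ++n) {
      mu += arma::sum(x.slice(n), 0).t();
      var += arma::sum(arma::square(x.slice(n)), 0).t();
    }
    mu /= N;
    var = var / N - arma::square(mu);
    var.transform([](double v) { return v < 0 ? 0 : v; });
  } else {
    mu = rmean;
    var = rvar;
  }
  arma::vec invsd = 1.0 / arma::sqrt(var + eps);
  arma::cube y(P, C, b);
  for (int n = 0; n < b; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* src = x.slice(n).colptr(c);
      double* dst = y.slice(n).colptr(c);
      const double a = gamma(c) * invsd(c);
      const double d = beta(c) - a * mu(c);
      for (int p = 0; p < P; ++p) {
        const double z = a * src[p] + d;
        dst[p] = z >= 0 ? z : slope * z;
      }
    }
  }
  arma::vec new_rmean = rmean, new_rvar = rvar;
  if (training) {
    new_rmean = (1.0 - momentum) * rmean + momentum * mu;
    new_rvar = (1.0 - momentum) * rvar + momentum * var;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["invsd"] = invsd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export(name = "cpp_bn_act_bwd")]]
List cpp_bn_act_bwd(const arma::cube& x, const arma::vec& gamma,
                    const arma::vec& beta, const arma::vec& mu,
                    const arma::vec& invsd, const double slope,
                    const arma::cube& dout) {
  const int P = x.n_rows, C = x.n_cols, b = x.n_slices;
  const double N = (double)P * b;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  // first pass: per-channel sums of dz and dz*xhat (dz = leaky-masked dout)
  arma::mat sdz(C, 1, arma::fill::zeros), sdzx(C, 1, arma::fill::zeros);
  for (int n = 0; n < b; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.slice(n).colptr(c);
      const double* dp = dout.slice(n).colptr(c);
      const double a = gamma(c) * invsd(c), d = beta(c) - a * mu(c);
      double s1 = 0, s2 = 0;
      for (int p = 0; p < P; ++p) {
        const double xhat = (xp[p] - mu(c)) * invsd(c);
        const double z = a * xp[p] + d;
        const double dz = z >= 0 ? dp[p] : slope * dp[p];
        s1 += dz;
        s2 += dz * xhat;
      }
      sdz(c, 0) += s1;
      sdzx(c, 0) += s2;
    }
  }
  dbeta = sdz.col(0);
  dgamma = sdzx.col(0);
  arma::cube dx(P, C, b);
  for (int n = 0; n < b; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.slice(n).colptr(c);
      const double* dp = dout.slice(n).colptr(c);
      double* dst = dx.slice(n).colptr(c);
      const double a = gamma(c) * invsd(c), d = beta(c) - a * mu(c);
      const double m1 = sdz(c, 0) / N, m2 = sdzx(c, 0) / N;
      for (int p = 0; p < P; ++p) {
        const double xhat = (xp[p] - mu(c)) * invsd(c);
        const double z = a * xp[p] + d;
        const double dz = z >= 0 ? dp[p] : slope * dp[p];
        dst[p] = gamma(c) * invsd(c) * (dz - m1 - xhat * m2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// channel-wise rescaling by the SE excitation weights s (C x b)
// [[Rcpp::export(name = "cpp_scale_channels_fwd")]]
arma::cube cpp_scale_channels_fwd(const arma::cube& x, const arma::mat& s) {
  const int C = x.n_cols, b = x.n_slices;
  arma::cube y = x;
  for (int n = 0; n < b; ++n)
    for (int c = 0; c < C; ++c) y.slice(n).col(c) *= s(c, n);
  return y;
}

// [[Rcpp::export(name = "cpp_scale_channels_bwd")]]
List cpp_scale_channels_bwd(const arma::cube& x, const arma::mat& s,
                            const arma::cube& dout) {
  const int C = x.n_cols, b = x.n_slices;
  arma::cube dx(x.n_rows, C, b);
  arma::mat ds(C, b);
  for (int n = 0; n < b; ++n) {
    for (int c = 0; c < C; ++c) {
      dx.slice(n).col(c) = dout.slice(n).col(c) * s(c, n);
      ds(c, n) = arma::dot(dout.slice(n).col(c), x.slice(n).col(c));
    }
  }
  return List::create(_["dx"] = dx, _["ds"] = ds);
}

// 2x2 stride-2 max pooling, ceil mode. idx stores 0-based source pixels.
// [[Rcpp::export(name = "cpp_maxpool_fwd")]]
List cpp_maxpool_fwd(const arma::cube& x, const int H, const int W) {
  const int H2 = (H + 1) / 2, W2 = (W + 1) / 2, P2 = H2 * W2;
  const int C = x.n_cols, b = x.n_slices;
  arma::cube y(P2, C, b), idx(P2, C, b);
  for (int n = 0; n < b; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* src = x.slice(n).colptr(c);
      double* dst = y.slice(n).colptr(c);
      double* id = idx.slice(n).colptr(c);
      for (int j2 = 0; j2 < W2; ++j2) {
        for (int i2 = 0; i2 < H2; ++i2) {
          double best = -arma::datum::inf;
          int bi = -1;
          for (int dj = 0; dj < 2; ++dj) {
            const int j = 2 * j2 + dj;
            if (j >= W) continue;
            for (int di = 0; di < 2; ++di) {
              const int i = 2 * i2 + di;
              if (i >= H) continue;
              const double v = src[i + (arma::uword)H * j];
              if (v > best) {
                best = v;
                bi = i + H * j;
              }
            }
          }
          dst[i2 + (arma::uword)H2 * j2] = best;
          id[i2 + (arma::uword)H2 * j2] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool_bwd")]]
arma::cube cpp_maxpool_bwd(const arma::cube& idx, const int P,
                           const arma::cube& dout) {
  const int P2 = dout.n_rows, C = dout.n_cols, b = dout.n_slices;
  arma::cube dx(P, C, b, arma::fill::zeros);
  for (int n = 0; n < b; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dp = dout.slice(n).colptr(c);
      const double* id = idx.slice(n).colptr(c);
      double* dst = dx.slice(n).colptr(c);
      for (int p = 0; p < P2; ++p) dst[(int)id[p]] += dp[p];
    }
  }
  return dx;
}

// global max pool over all spatial positions of each channel
// [[Rcpp::export(name = "cpp_gmaxpool_fwd")]]
List cpp_gmaxpool_fwd(const arma::cube& x) {
  const int P = x.n_rows, C = x.n_cols, b = x.n_slices;
  arma::mat y(C, b), idx(C, b);
  for (int n = 0; n < b; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* src = x.slice(n).colptr(c);
      double best = src[0];
      int bi = 0;
      for (int p = 1; p < P; ++p)
        if (src[p] > best) {
          best = src[p];
          bi = p;
        }
      y(c, n) = best;
      idx(c, n) = bi;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_gmaxpool_bwd")]]
arma::cube cpp_gmaxpool_bwd(const arma::mat& idx, const int P,
                            const arma::mat& dout) {
  const int C = dout.n_rows, b = dout.n_cols;
  arma::cube dx(P, C, b, arma::fill::zeros);
  for (int n = 0; n < b; ++n)
    for (int c = 0; c < C; ++c) dx((int)idx(c, n), c, n) = dout(c, n);
  return dx;
}
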