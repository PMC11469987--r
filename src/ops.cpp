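// Low-level volume kernels: 3-D convolution (im2col + BLAS), stride-2
// transpose convolution, 2x2x2 max pooling, nearest-neighbor up-sampling,
// separable Gaussian blur, and ray-marched angle-averaged attenuation
// factors. Volumes are passed as flat numeric vectors in R array
// column-major order with dims (D, H, W[, C]) = (axial, coronal, sagittal).
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// persistent scratch buffers: repeated conv calls at the same feature-map
// sizes would otherwise pay large page-faulting allocations every call
static std::vector<double>& scratch(int which, std::size_t n) {
  static std::vector<double> bufs[2];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

// im2col for a 3x3x3 kernel with edge-replication padding.
// Column order: c * 27 + t, t = (dz+1) + 3*(dy+1) + 9*(dx+1).
static arma::mat im2col3(const double* x, int D, int H, int W, int Cin) {
  const std::size_t nv = (std::size_t)D * H * W;
  arma::mat P(scratch(0, nv * 27 * (std::size_t)Cin).data(),
              nv, 27 * (std::size_t)Cin, false, true);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + nv * c;
    int t = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz, ++t) {
          double* col = P.colptr((std::size_t)c * 27 + t);
          for (int k = 0; k < W; ++k) {
            const int kk = clampi(k + dx, 0, W - 1);
            for (int j = 0; j < H; ++j) {
              const int jj = clampi(j + dy, 0, H - 1);
              const double* src = xc + (std::size_t)D * (jj + (std::size_t)H * kk);
              double* dst = col + (std::size_t)D * (j + (std::size_t)H * k);
              // shifted copy with edge replication along the fast axis
              if (dz == 0) {
                std::memcpy(dst, src, D * sizeof(double));
              } else if (dz < 0) {
                dst[0] = src[0];
                std::memcpy(dst + 1, src, (D - 1) * sizeof(double));
              } else {
                std::memcpy(dst, src + 1, (D - 1) * sizeof(double));
                dst[D - 1] = src[D - 1];
              }
            }
          }
        }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fw(NumericVector x, NumericMatrix w, NumericVector b,
                           int D, int H, int W, int Cin, int Cout) {
  const std::size_t nv = (std::size_t)D * H * W;
  arma::mat P = im2col3(x.begin(), D, H, W, Cin);
  arma::mat Wm(w.begin(), 27 * (std::size_t)Cin, Cout, false);
  arma::mat Y = P * Wm;
  NumericVector out(nv * Cout);
  for (int c = 0; c < Cout; ++c) {
    double* oc = out.begin() + nv * c;
    const double* yc = Y.colptr(c);
    const double bc = b[c];
    for (std::size_t v = 0; v < nv; ++v) oc[v] = yc[v] + bc;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bw(NumericVector x, NumericMatrix w, NumericVector dy,
                  int D, int H, int W, int Cin, int Cout) {
  const std::size_t nv = (std::size_t)D * H * W;
  arma::mat P = im2col3(x.begin(), D, H, W, Cin);
  arma::mat Wm(w.begin(), 27 * (std::size_t)Cin, Cout, false);
  arma::mat dY(dy.begin(), nv, Cout, false);
  arma::mat dW = P.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dP(scratch(1, nv * 27 * (std::size_t)Cin).data(),
               nv, 27 * (std::size_t)Cin, false, true);
  dP = dY * Wm.t();
  NumericVector dx(nv * Cin);
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx.begin() + nv * c;
    int t = 0;
    for (int dxo = -1; dxo <= 1; ++dxo)
      for (int dyo = -1; dyo <= 1; ++dyo)
        for (int dzo = -1; dzo <= 1; ++dzo, ++t) {
          const double* col = dP.colptr((std::size_t)c * 27 + t);
          for (int k = 0; k < W; ++k) {
            const int kk = clampi(k + dxo, 0, W - 1);
            for (int j = 0; j < H; ++j) {
              const int jj = clampi(j + dyo, 0, H - 1);
              double* dst = xc + (std::size_t)D * (jj + (std::size_t)H * kk);
              const double* src = col + (std::size_t)D * (j + (std::size_t)H * k);
              if (dzo == 0) {
                for (int i = 0; i < D; ++i) dst[i] += src[i];
              } else if (dzo < 0) {
                dst[0] += src[0];
                for (int i = 1; i < D; ++i) dst[i - 1] += src[i];
              } else {
                for (int i = 0; i < D - 1; ++i) dst[i + 1] += src[i];
                dst[D - 1] += src[D - 1];
              }
            }
          }
        }
  }
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericVector(dW.begin(), dW.end()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transpose convolution, kernel 3, stride 2, exact spatial doubling.
// Output voxel o receives input i through kernel offset (dz,dy,dx) when
// o = 2 i + d along each axis (d in {-1,0,1}); out-of-range taps dropped.
// [[Rcpp::export]]
NumericVector cpp_convt3_fw(NumericVector x, NumericMatrix w, NumericVector b,
                            int D, int H, int W, int Cin, int Cout) {
  const std::size_t nvi = (std::size_t)D * H * W;
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  const std::size_t nvo = (std::size_t)D2 * H2 * W2;
  arma::mat X(x.begin(), nvi, Cin, false);
  NumericVector out(nvo * Cout);
  for (std::size_t v = 0; v < nvo * Cout; ++v) out[v] = b[v / nvo];
  int t = 0;
  for (int dxo = -1; dxo <= 1; ++dxo)
    for (int dyo = -1; dyo <= 1; ++dyo)
      for (int dzo = -1; dzo <= 1; ++dzo, ++t) {
        arma::mat Wt(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co) Wt(ci, co) = w((std::size_t)ci * 27 + t, co);
        arma::mat M = X * Wt;  // nvi x Cout
        for (int co = 0; co < Cout; ++co) {
          double* oc = out.begin() + nvo * co;
          const double* mc = M.colptr(co);
          for (int k = 0; k < W; ++k) {
            const int ko = 2 * k + dxo;
            if (ko < 0 || ko >= W2) continue;
            for (int j = 0; j < H; ++j) {
              const int jo = 2 * j + dyo;
              if (jo < 0 || jo >= H2) continue;
              double* dst = oc + (std::size_t)D2 * (jo + (std::size_t)H2 * ko);
              const double* src = mc + (std::size_t)D * (j + (std::size_t)H * k);
              for (int i = 0; i < D; ++i) {
                const int io = 2 * i + dzo;
                if (io >= 0 && io < D2) dst[io] += src[i];
              }
            }
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
List cpp_convt3_bw(NumericVector x, NumericMatrix w, NumericVector dy,
                   int D, int H, int W, int Cin, int Cout) {
  const std::size_t nvi = (std::size_t)D * H * W;
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  const std::size_t nvo = (std::size_t)D2 * H2 * W2;
  arma::mat X(x.begin(), nvi, Cin, false);
  arma::mat dX(nvi, Cin, arma::fill::zeros);
  NumericMatrix dW(27 * Cin, Cout);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* dc = dy.begin() + nvo * co;
    double s = 0;
    for (std::size_t v = 0; v < nvo; ++v) s += dc[v];
    db[co] = s;
  }
  int t = 0;
  for (int dxo = -1; dxo <= 1; ++dxo)
    for (int dyo = -1; dyo <= 1; ++dyo)
      for (int dzo = -1; dzo <= 1; ++dzo, ++t) {
        // gather G (nvi x Cout): dY at output position 2 i + d (0 if clipped)
        arma::mat G(nvi, Cout, arma::fill::zeros);
        for (int co = 0; co < Cout; ++co) {
          const double* dc = dy.begin() + nvo * co;
          double* gc = G.colptr(co);
          for (int k = 0; k < W; ++k) {
            const int ko = 2 * k + dxo;
            if (ko < 0 || ko >= W2) continue;
            for (int j = 0; j < H; ++j) {
              const int jo = 2 * j + dyo;
              if (jo < 0 || jo >= H2) continue;
              const double* src = dc + (std::size_t)D2 * (jo + (std::size_t)H2 * ko);
              double* dst = gc + (std::size_t)D * (j + (std::size_t)H * k);
              for (int i = 0; i < D; ++i) {
                const int io = 2 * i + dzo;
                if (io >= 0 && io < D2) dst[i] = src[io];
              }
            }
          }
        }
        arma::mat Wt(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co) Wt(ci, co) = w((std::size_t)ci * 27 + t, co);
        dX += G * Wt.t();
        arma::mat dWt = X.t() * G;  // Cin x Cout
        for (int ci = 0; ci < Cin; ++ci)
          for (int co = 0; co < Cout; ++co) dW((std::size_t)ci * 27 + t, co) += dWt(ci, co);
      }
  return List::create(_["dx"] = NumericVector(dX.begin(), dX.end()),
                      _["dw"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int D, int H, int W, int C) {
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const std::size_t nvo = (std::size_t)Do * Ho * Wo;
  const std::size_t nvi = (std::size_t)D * H * W;
  NumericVector y(nvo * C);
  IntegerVector idx(nvo * C);  // 0-based linear index into x
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + nvi * c;
    for (int k = 0; k < Wo; ++k)
      for (int j = 0; j < Ho; ++j)
        for (int i = 0; i < Do; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bidx = 0;
          for (int a = 0; a < 2; ++a)
            for (int bq = 0; bq < 2; ++bq)
              for (int cq = 0; cq < 2; ++cq) {
                const std::size_t li = (std::size_t)(2 * i + cq) +
                  (std::size_t)D * ((2 * j + bq) + (std::size_t)H * (2 * k + a));
                if (xc[li] > best) { best = xc[li]; bidx = li; }
              }
          const std::size_t lo = (std::size_t)i + (std::size_t)Do * (j + (std::size_t)Ho * k);
          y[nvo * c + lo] = best;
          idx[nvo * c + lo] = (int)(nvi * c + bidx);
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector dy, R_xlen_t n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t v = 0; v < dy.size(); ++v) dx[idx[v]] += dy[v];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upnn_fw(NumericVector x, int D, int H, int W, int C) {
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  const std::size_t nvi = (std::size_t)D * H * W, nvo = (std::size_t)D2 * H2 * W2;
  NumericVector y(nvo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + nvi * c;
    double* yc = y.begin() + nvo * c;
    for (int k = 0; k < W2; ++k)
      for (int j = 0; j < H2; ++j) {
        const double* src = xc + (std::size_t)D * ((j / 2) + (std::size_t)H * (k / 2));
        double* dst = yc + (std::size_t)D2 * (j + (std::size_t)H2 * k);
        for (int i = 0; i < D2; ++i) dst[i] = src[i / 2];
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upnn_bw(NumericVector dy, int D, int H, int W, int C) {
  // D,H,W are the *input* (coarse) dims
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  const std::size_t nvi = (std::size_t)D * H * W, nvo = (std::size_t)D2 * H2 * W2;
  NumericVector dx(nvi * C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dy.begin() + nvo * c;
    double* xc = dx.begin() + nvi * c;
    for (int k = 0; k < W2; ++k)
      for (int j = 0; j < H2; ++j) {
        double* dst = xc + (std::size_t)D * ((j / 2) + (std::size_t)H * (k / 2));
        const double* src = dc + (std::size_t)D2 * (j + (std::size_t)H2 * k);
        for (int i = 0; i < D2; ++i) dst[i / 2] += src[i];
      }
  }
  return dx;
}

// Separable Gaussian blur, zero padding, kernel truncated at 3 sigma.
static void blur_axis(std::vector<double>& v, int D, int H, int W,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int m = -r; m <= r; ++m) { ker[m + r] = std::exp(-0.5 * m * m / (sigma * sigma)); s += ker[m + r]; }
  for (double& kv : ker) kv /= s;
  std::vector<double> out(v.size(), 0.0);
  const int n = axis == 0 ? D : (axis == 1 ? H : W);
  const std::size_t stride = axis == 0 ? 1 : (axis == 1 ? (std::size_t)D : (std::size_t)D * H);
  for (int k = 0; k < W; ++k)
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < D; ++i) {
        const int pos = axis == 0 ? i : (axis == 1 ? j : k);
        const std::size_t base = (std::size_t)i + (std::size_t)D * (j + (std::size_t)H * k);
        double acc = 0;
        for (int m = -r; m <= r; ++m) {
          const int p = pos + m;
          if (p < 0 || p >= n) continue;
          acc += ker[m + r] * v[base + (std::size_t)(p - pos) * stride];
        }
        out[base] = acc;
      }
  v.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector x, int D, int H, int W,
                             double sd_d, double sd_h, double sd_w) {
  std::vector<double> v(x.begin(), x.end());
  blur_axis(v, D, H, W, 0, sd_d);
  blur_axis(v, D, H, W, 1, sd_h);
  blur_axis(v, D, H, W, 2, sd_w);
  return NumericVector(v.begin(), v.end());
}

// Angle-averaged attenuation factor. Rays travel in the transverse (H, W)
// plane within a fixed axial slice; angle 0 points along +H (second dim),
// 90 degrees along +W. Midpoint rule with half-voxel steps and
// nearest-voxel sampling, from the voxel center to the grid boundary.
// [[Rcpp::export]]
NumericVector cpp_atten_factor(NumericVector mu, int D, int H, int W,
                               double voxel_cm, NumericVector angles_deg) {
  const std::size_t nv = (std::size_t)D * H * W;
  NumericVector out(nv);
  const int na = angles_deg.size();
  std::vector<double> dyv(na), dxv(na);
  for (int a = 0; a < na; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    dyv[a] = std::cos(th);
    dxv[a] = std::sin(th);
  }
  // Axis-aligned angles admit the exact line integral of the voxelized
  // field (half the source voxel plus every voxel beyond it): computed via
  // running sums, one pass per angle. Oblique angles fall back to ray
  // marching.
  std::vector<bool> axis_fast(na, false);
  bool all_fast = true;
  for (int a = 0; a < na; ++a) {
    axis_fast[a] = std::abs(dyv[a]) < 1e-12 || std::abs(dxv[a]) < 1e-12;
    if (!axis_fast[a]) all_fast = false;
  }
  std::vector<double> acc(nv, 0.0);
  for (int a = 0; a < na; ++a) {
    if (!axis_fast[a]) continue;
    const bool along_y = std::abs(dxv[a]) < 1e-12;
    const int dir = along_y ? (dyv[a] > 0 ? 1 : -1) : (dxv[a] > 0 ? 1 : -1);
    const int n_line = along_y ? H : W;
    for (int o = 0; o < (along_y ? W : H); ++o)
      for (int i = 0; i < D; ++i) {
        double run = 0;
        for (int s = n_line - 1; s >= 0; --s) {
          const int pos = dir > 0 ? s : n_line - 1 - s;
          const int j = along_y ? pos : o;
          const int k = along_y ? o : pos;
          const std::size_t vi = (std::size_t)i + (std::size_t)D * (j + (std::size_t)H * k);
          const double m = mu[vi];
          acc[vi] += std::exp(-(run + 0.5 * m) * voxel_cm);
          run += m;
        }
      }
  }
  for (int k = 0; k < W; ++k)
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < D; ++i) {
        const std::size_t vi = (std::size_t)i + (std::size_t)D * (j + (std::size_t)H * k);
        double fsum = acc[vi];
        if (all_fast) { out[vi] = fsum / na; continue; }
        for (int a = 0; a < na; ++a) {
          if (axis_fast[a]) continue;
          const double dy = dyv[a], dx = dxv[a];
          double tmax = std::numeric_limits<double>::infinity();
          if (dy > 1e-12) tmax = std::min(tmax, ((H - 0.5) - j) / dy);
          else if (dy < -1e-12) tmax = std::min(tmax, (j + 0.5) / (-dy));
          if (dx > 1e-12) tmax = std::min(tmax, ((W - 0.5) - k) / dx);
          else if (dx < -1e-12) tmax = std::min(tmax, (k + 0.5) / (-dx));
          double integ = 0;
          if (tmax > 0 && std::isfinite(tmax)) {
            const int ns = (int)std::ceil(tmax / 0.5);
            const double h = tmax / ns;
            double s = 0;
            for (int m = 0; m < ns; ++m) {
              const double t = (m + 0.5) * h;
              const int jj = clampi((int)std::lround(j + t * dy), 0, H - 1);
              const int kk = clampi((int)std::lround(k + t * dx), 0, W - 1);
              s += mu[(std::size_t)i + (std::size_t)D * (jj + (std::size_t)H * kk)];
            }
            integ = s * h * voxel_cm;
          }
          fsum += std::exp(-integ);
        }
        out[vi] = fsum / na;
      }
  return out;
}
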