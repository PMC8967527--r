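// Numerical kernels for the segmentation networks and mask geometry.
// Feature maps are arma::cube (H x W x C); convolution weights are
// (k*k*Cin) x Cout matrices with column order (ki, kj, c) fastest-first,
// matching the im2col layout below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out_dim(int n, int k, int dil, int stride, int pad) {
  int eff = (k - 1) * dil + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// Patch matrix: rows index output pixels (oh + ow*outH), columns index
// (ki, kj, c) with ki fastest.
static arma::mat im2col(const arma::cube& x, int k, int dil, int stride,
                        int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outH = conv_out_dim(H, k, dil, stride, pad);
  const int outW = conv_out_dim(W, k, dil, stride, pad);
  arma::mat M(outH * outW, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        for (int ow = 0; ow < outW; ++ow) {
          const int iw = ow * stride - pad + kj * dil;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < outH; ++oh) {
            const int ih = oh * stride - pad + ki * dil;
            if (ih < 0 || ih >= H) continue;
            M(oh + ow * outH, col) = xc(ih, iw);
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter-add patch matrix back onto an H x W x C grid.
static arma::cube col2im(const arma::mat& M, int H, int W, int C, int k,
                         int dil, int stride, int pad) {
  const int outH = conv_out_dim(H, k, dil, stride, pad);
  const int outW = conv_out_dim(W, k, dil, stride, pad);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        for (int ow = 0; ow < outW; ++ow) {
          const int iw = ow * stride - pad + kj * dil;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < outH; ++oh) {
            const int ih = oh * stride - pad + ki * dil;
            if (ih < 0 || ih >= H) continue;
            xc(ih, iw) += M(oh + ow * outH, col);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".nf_conv_fwd")]]
arma::cube nf_conv_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, int k, int dil, int stride,
                       int pad) {
  const int outH = conv_out_dim(x.n_rows, k, dil, stride, pad);
  const int outW = conv_out_dim(x.n_cols, k, dil, stride, pad);
  arma::mat ym = im2col(x, k, dil, stride, pad) * w;
  ym.each_row() += b.t();
  arma::cube y(outH, outW, w.n_cols);
  std::memcpy(y.memptr(), ym.memptr(), sizeof(double) * ym.n_elem);
  return y;
}

// [[Rcpp::export(name = ".nf_conv_bwd")]]
List nf_conv_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                 int k, int dil, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat gym(const_cast<double*>(gy.memptr()), gy.n_rows * gy.n_cols,
                gy.n_slices, false, true);
  arma::mat M = im2col(x, k, dil, stride, pad);
  arma::mat gw = M.t() * gym;
  arma::vec gb = arma::sum(gym, 0).t();
  arma::cube gx = col2im(gym * w.t(), H, W, C, k, dil, stride, pad);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed (fractionally strided) convolution, defined as the adjoint of a
// stride-`stride` convolution mapping (outH,outW,Cout) -> (H,W,Cin) with
// weights w of shape (k*k*Cout) x Cin.
// [[Rcpp::export(name = ".nf_tconv_fwd")]]
arma::cube nf_tconv_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, int k, int stride, int pad,
                        int outH, int outW) {
  const int Cout = w.n_rows / (k * k);
  arma::mat xm(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols,
               x.n_slices, false, true);
  arma::cube y = col2im(xm * w.t(), outH, outW, Cout, k, 1, stride, pad);
  for (int c = 0; c < Cout; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export(name = ".nf_tconv_bwd")]]
List nf_tconv_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                  int k, int stride, int pad) {
  arma::mat xm(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols,
               x.n_slices, false, true);
  arma::mat Mg = im2col(gy, k, 1, stride, pad);
  arma::mat gxm = Mg * w;
  arma::mat gw = Mg.t() * xm;
  arma::vec gb(gy.n_slices);
  for (arma::uword c = 0; c < gy.n_slices; ++c) gb(c) = arma::accu(gy.slice(c));
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices);
  std::memcpy(gx.memptr(), gxm.memptr(), sizeof(double) * gxm.n_elem);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".nf_maxpool2_fwd")]]
List nf_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = H / 2, ow = W / 2;
  arma::cube y(oh, ow, C);
  arma::ucube idx(oh, ow, C);  // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = ii + (arma::uword)jj * H; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nf_maxpool2_bwd")]]
arma::cube nf_maxpool2_bwd(const arma::cube& gy, const arma::ucube& idx, int H,
                           int W) {
  arma::cube gx(H, W, gy.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < gy.n_slices; ++c) {
    for (arma::uword j = 0; j < gy.n_cols; ++j) {
      for (arma::uword i = 0; i < gy.n_rows; ++i) {
        gx.slice(c)(idx(i, j, c)) += gy(i, j, c);
      }
    }
  }
  return gx;
}

// Bilinear resize with the half-pixel (pixel-centre) convention; exact
// identity when the size is unchanged.
// [[Rcpp::export(name = ".nf_resize_bilinear")]]
arma::mat nf_resize_bilinear(const arma::mat& x, int outH, int outW) {
  const int H = x.n_rows, W = x.n_cols;
  if (outH == H && outW == W) return x;
  arma::mat y(outH, outW);
  const double sh = (double)H / outH, sw = (double)W / outW;
  for (int j = 0; j < outW; ++j) {
    double fw = (j + 0.5) * sw - 0.5;
    fw = std::min(std::max(fw, 0.0), (double)(W - 1));
    const int j0 = (int)std::floor(fw), j1 = std::min(j0 + 1, W - 1);
    const double wj = fw - j0;
    for (int i = 0; i < outH; ++i) {
      double fh = (i + 0.5) * sh - 0.5;
      fh = std::min(std::max(fh, 0.0), (double)(H - 1));
      const int i0 = (int)std::floor(fh), i1 = std::min(i0 + 1, H - 1);
      const double wi = fh - i0;
      y(i, j) = (1 - wi) * ((1 - wj) * x(i0, j0) + wj * x(i0, j1)) +
                wi * ((1 - wj) * x(i1, j0) + wj * x(i1, j1));
    }
  }
  return y;
}

// Trilinear / nearest-neighbour volume resampling (half-pixel convention).
// vol is a (z,y,x) cube; out dims given explicitly.
// [[Rcpp::export(name = ".nf_resample3d")]]
arma::cube nf_resample3d(const arma::cube& vol, int oz, int oy, int ox,
                         bool nearest) {
  const int Z = vol.n_rows, Y = vol.n_cols, X = vol.n_slices;
  arma::cube out(oz, oy, ox);
  const double sz = (double)Z / oz, sy = (double)Y / oy, sx = (double)X / ox;
  for (int k = 0; k < ox; ++k) {
    double fx = std::min(std::max((k + 0.5) * sx - 0.5, 0.0), (double)(X - 1));
    for (int j = 0; j < oy; ++j) {
      double fy =
          std::min(std::max((j + 0.5) * sy - 0.5, 0.0), (double)(Y - 1));
      for (int i = 0; i < oz; ++i) {
        double fz =
            std::min(std::max((i + 0.5) * sz - 0.5, 0.0), (double)(Z - 1));
        if (nearest) {
          out(i, j, k) = vol((int)std::lround(fz), (int)std::lround(fy),
                             (int)std::lround(fx));
        } else {
          const int z0 = (int)std::floor(fz), z1 = std::min(z0 + 1, Z - 1);
          const int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, Y - 1);
          const int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, X - 1);
          const double wz = fz - z0, wy = fy - y0, wx = fx - x0;
          double v = 0.0;
          v += (1 - wz) * (1 - wy) * (1 - wx) * vol(z0, y0, x0);
          v += (1 - wz) * (1 - wy) * wx * vol(z0, y0, x1);
          v += (1 - wz) * wy * (1 - wx) * vol(z0, y1, x0);
          v += (1 - wz) * wy * wx * vol(z0, y1, x1);
          v += wz * (1 - wy) * (1 - wx) * vol(z1, y0, x0);
          v += wz * (1 - wy) * wx * vol(z1, y0, x1);
          v += wz * wy * (1 - wx) * vol(z1, y1, x0);
          v += wz * wy * wx * vol(z1, y1, x1);
          out(i, j, k) = v;
        }
      }
    }
  }
  return out;
}

// 26-connected component labelling of a 3D logical array (z,y,x).
// [[Rcpp::export(name = ".nf_label3d")]]
IntegerVector nf_label3d(const LogicalVector& mask, int Z, int Y, int X) {
  IntegerVector lab(mask.size(), 0);
  auto at = [&](int z, int y, int x) { return z + Z * (y + Y * x); };
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < X; ++x) {
    for (int y = 0; y < Y; ++y) {
      for (int z = 0; z < Z; ++z) {
        const int p = at(z, y, x);
        if (!mask[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        stack.push_back(p);
        while (!stack.empty()) {
          const int q = stack.back();
          stack.pop_back();
          const int qz = q % Z, qy = (q / Z) % Y, qx = q / (Z * Y);
          for (int dx = -1; dx <= 1; ++dx) {
            const int nx = qx + dx;
            if (nx < 0 || nx >= X) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              const int ny = qy + dy;
              if (ny < 0 || ny >= Y) continue;
              for (int dz = -1; dz <= 1; ++dz) {
                const int nz = qz + dz;
                if (nz < 0 || nz >= Z) continue;
                const int r = at(nz, ny, nx);
                if (mask[r] && !lab[r]) {
                  lab[r] = next;
                  stack.push_back(r);
                }
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing of a connected 2D region; returns the
// polygonal arc length of the outer contour (unit steps 1, diagonal sqrt(2)).
// [[Rcpp::export(name = ".nf_trace_perimeter")]]
double nf_trace_perimeter(const LogicalMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  auto fg = [&](int i, int j) {
    return i >= 0 && i < H && j >= 0 && j < W && m(i, j);
  };
  // first foreground pixel in column-major scan
  int si = -1, sj = -1;
  for (int j = 0; j < W && si < 0; ++j)
    for (int i = 0; i < H; ++i)
      if (m(i, j)) { si = i; sj = j; break; }
  if (si < 0) return NA_REAL;
  // Moore neighbourhood, clockwise starting from W
  const int di[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double len[8] = {1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2};
  int ci = si, cj = sj;
  int back = 0;  // direction of the pixel we came from; start pretends W
  double per = 0.0;
  int firstMove = -1;
  const long maxSteps = 4L * (long)H * W + 8;
  for (long step = 0; step < maxSteps; ++step) {
    int found = -1;
    for (int t = 0; t < 8; ++t) {
      const int d = (back + 1 + t) % 8;  // clockwise scan from the backtrack
      if (fg(ci + di[d], cj + dj[d])) { found = d; break; }
    }
    if (found < 0) {
      // isolated pixel: perimeter of the equal-area disc
      return 2.0 * std::sqrt(M_PI);
    }
    // Jacob's criterion: back at the start about to repeat the first move
    if (ci == si && cj == sj && firstMove >= 0 && found == firstMove) break;
    if (firstMove < 0) firstMove = found;
    per += len[found];
    ci += di[found];
    cj += dj[found];
    back = (found + 4) % 8;
  }
  return per;
}
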