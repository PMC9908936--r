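// Volumetric network primitives (3x3x3 'same' convolution via im2col + GEMM,
// 2x max pooling, nearest-neighbour upsampling) and 3D connected-component
// labeling. Arrays follow the package convention dim = (z, y, x[, channel]),
// column-major as R stores them, so z is the fastest axis.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3^3 neighbourhood with zero padding 1, transposed layout.
// x: (D,H,W,Cin). Result: N x (27*Cin) with N = D*H*W; row n corresponds to
// voxel n in column-major (z fastest) order; column index is
// dz + 3*dy + 9*dx + 27*cin with dz,dy,dx in {0,1,2} (offset - 1), matching
// the column-major layout of a weight array dim (3,3,3,Cin,Cout). Each
// (offset, channel) pair fills one contiguous matrix column.
static arma::mat im2col3(const double* x, int D, int H, int W, int Cin) {
  const int N = D * H * W;
  arma::mat col(N, 27 * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * N;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dz = -1; dz <= 1; ++dz) {
          const int r = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1) + 27 * ci;
          double* cp = col.colptr(r);
          for (int ix = 0; ix < W; ++ix) {
            const int sx = ix + dx;
            if (sx < 0 || sx >= W) continue;
            for (int iy = 0; iy < H; ++iy) {
              const int sy = iy + dy;
              if (sy < 0 || sy >= H) continue;
              const int zlo = std::max(0, -dz);
              const int zhi = std::min(D, D - dz);
              const size_t ncol0 = (size_t)(ix * H + iy) * D;
              const size_t nsrc0 = (size_t)(sx * H + sy) * D + dz;
              std::memcpy(cp + ncol0 + zlo, xc + nsrc0 + zlo,
                          (size_t)(zhi - zlo) * sizeof(double));
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector conv3_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int D = dx[0], H = dx[1], W = dx[2], Cin = dx[3];
  const int Cout = dw[4];
  const int N = D * H * W;
  arma::mat col = im2col3(x.begin(), D, H, W, Cin);
  arma::mat Wm(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat Y = col * Wm;  // N x Cout, column-major => (D,H,W,Cout)
  for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return out;
}

// col2im scatter-add, inverse of im2col3 (transposed layout: gcol is
// N x 27*Cin, so each (offset, channel) column is read contiguously).
static void col2im3(const arma::mat& gcol, double* gx, int D, int H, int W,
                    int Cin) {
  const int N = D * H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gc = gx + (size_t)ci * N;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dz = -1; dz <= 1; ++dz) {
          const int r = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1) + 27 * ci;
          const double* cp = gcol.colptr(r);
          for (int ix = 0; ix < W; ++ix) {
            const int sx = ix + dx;
            if (sx < 0 || sx >= W) continue;
            for (int iy = 0; iy < H; ++iy) {
              const int sy = iy + dy;
              if (sy < 0 || sy >= H) continue;
              const int zlo = std::max(0, -dz);
              const int zhi = std::min(D, D - dz);
              const size_t ncol0 = (size_t)(ix * H + iy) * D;
              const size_t ndst0 = (size_t)(sx * H + sy) * D + dz;
              for (int iz = zlo; iz < zhi; ++iz) {
                gc[ndst0 + iz] += cp[ncol0 + iz];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv3_bw(NumericVector x, NumericVector w, NumericVector gout) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int D = dx[0], H = dx[1], W = dx[2], Cin = dx[3];
  const int Cout = dw[4];
  const int N = D * H * W;
  arma::mat col = im2col3(x.begin(), D, H, W, Cin);
  arma::mat G(gout.begin(), N, Cout, false, true);
  arma::mat Wm(w.begin(), 27 * Cin, Cout, false, true);

  arma::mat gW = col.t() * G;          // (27*Cin) x Cout
  arma::rowvec gb = arma::sum(G, 0);   // 1 x Cout
  arma::mat gcol = G * Wm.t();         // N x (27*Cin)

  NumericVector gx(x.size());
  gx.attr("dim") = dx;
  col2im3(gcol, gx.begin(), D, H, W, Cin);

  NumericVector gw(gW.begin(), gW.end());
  gw.attr("dim") = dw;
  NumericVector gbv(gb.begin(), gb.end());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbv);
}

// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int D = dx[0], H = dx[1], W = dx[2], C = dx[3];
  const int D2 = D / 2, H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)D2 * H2 * W2 * C);
  IntegerVector idx((size_t)D2 * H2 * W2 * C);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    const size_t cb = (size_t)c * D * H * W;
    for (int ix = 0; ix < W2; ++ix) {
      for (int iy = 0; iy < H2; ++iy) {
        for (int iz = 0; iz < D2; ++iz, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int ox = 0; ox < 2; ++ox)
            for (int oy = 0; oy < 2; ++oy)
              for (int oz = 0; oz < 2; ++oz) {
                const size_t li = cb +
                  (size_t)(2 * ix + ox) * H * D + (size_t)(2 * iy + oy) * D +
                  (2 * iz + oz);
                if (xp[li] > best) { best = xp[li]; bidx = li; }
              }
          y[o] = best;
          idx[o] = (int)bidx;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(D2, H2, W2, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector gy, IntegerVector idx,
                          IntegerVector dim_in) {
  NumericVector gx((size_t)dim_in[0] * dim_in[1] * dim_in[2] * dim_in[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = dim_in;
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fw(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int D = dx[0], H = dx[1], W = dx[2], C = dx[3];
  const int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)D2 * H2 * W2 * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const size_t cb = (size_t)c * D * H * W;
    const size_t cb2 = (size_t)c * D2 * H2 * W2;
    for (int ix = 0; ix < W2; ++ix)
      for (int iy = 0; iy < H2; ++iy)
        for (int iz = 0; iz < D2; ++iz) {
          y[cb2 + (size_t)ix * H2 * D2 + (size_t)iy * D2 + iz] =
            xp[cb + (size_t)(ix / 2) * H * D + (size_t)(iy / 2) * D + iz / 2];
        }
  }
  y.attr("dim") = IntegerVector::create(D2, H2, W2, C);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw(NumericVector gy) {
  IntegerVector dy = gy.attr("dim");
  const int D2 = dy[0], H2 = dy[1], W2 = dy[2], C = dy[3];
  const int D = D2 / 2, H = H2 / 2, W = W2 / 2;
  NumericVector gx((size_t)D * H * W * C);
  for (int c = 0; c < C; ++c) {
    const size_t cb = (size_t)c * D * H * W;
    const size_t cb2 = (size_t)c * D2 * H2 * W2;
    for (int ix = 0; ix < W2; ++ix)
      for (int iy = 0; iy < H2; ++iy)
        for (int iz = 0; iz < D2; ++iz) {
          gx[cb + (size_t)(ix / 2) * H * D + (size_t)(iy / 2) * D + iz / 2] +=
            gy[cb2 + (size_t)ix * H2 * D2 + (size_t)iy * D2 + iz];
        }
  }
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  return gx;
}

// 3D connected components on a binary volume (0/1), dim (D,H,W).
// connectivity 6, 18 or 26. Components are numbered 1,2,... in the scan
// order (column-major, z fastest) of their minimum-index voxel.
// [[Rcpp::export]]
IntegerVector cc_label3d(IntegerVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  const int D = dm[0], H = dm[1], W = dm[2];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  IntegerVector lab(N);
  lab.attr("dim") = dm;

  std::vector<int> offs;  // packed neighbour offsets dz,dy,dx
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        offs.push_back(dz); offs.push_back(dy); offs.push_back(dx);
      }

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t n = 0; n < N; ++n) {
    if (mask[n] == 0 || lab[n] != 0) continue;
    ++next;
    lab[n] = next;
    stack.clear();
    stack.push_back(n);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = (int)(cur % D);
      const int y = (int)((cur / D) % H);
      const int x = (int)(cur / ((R_xlen_t)D * H));
      for (size_t k = 0; k < offs.size(); k += 3) {
        const int nz = z + offs[k], ny = y + offs[k + 1], nx = x + offs[k + 2];
        if (nz < 0 || nz >= D || ny < 0 || ny >= H || nx < 0 || nx >= W)
          continue;
        const R_xlen_t ni = (R_xlen_t)nx * H * D + (R_xlen_t)ny * D + nz;
        if (mask[ni] != 0 && lab[ni] == 0) {
          lab[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  return lab;
}
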