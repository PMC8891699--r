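// Low-level numerical kernels for the segmentation network and image ops.
// Tensors are column-major R arrays laid out (X, Y, Z, C); convolution
// kernels are (kx, ky, kz, Cin, Cout).  Convolutions are "same"-padded with
// zeros and evaluated per z-slab through an im2col buffer and a single
// GEMM per slab, in single precision (the R interface stays double).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fvec as_fvec(const NumericVector& v) {
  arma::fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float) v[i];
  return out;
}

// Gather one z-slab of the im2col matrix.  col is (X*Y) x K with
// K = kx*ky*kz*Cin and column index r = dx + kx*(dy + ky*(dz + kz*ci)),
// so every (r, iy) pair is a contiguous run along ix in both source and
// destination.
static void im2col_slab_ld(const arma::fvec& x, int X, int Y, int Z, int Cin,
                           int kx, int ky, int kz, int iz, float* colmem,
                           size_t ld, size_t rowOff) {
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dz = 0; dz < kz; ++dz) {
      const int zz = iz + dz - pz;
      const bool zok = zz >= 0 && zz < Z;
      const size_t zbase = zok ? (size_t) X * Y * (zz + (size_t) Z * ci) : 0;
      for (int dy = 0; dy < ky; ++dy) {
        for (int dx = 0; dx < kx; ++dx) {
          const int r = dx + kx * (dy + ky * (dz + kz * ci));
          float* dst = colmem + ld * (size_t) r + rowOff;
          const int xs = dx - px;
          const int lo = std::max(0, -xs), hi = std::min(X, X - xs);
          for (int iy = 0; iy < Y; ++iy) {
            float* drow = dst + (size_t) X * iy;
            const int yy = iy + dy - py;
            if (!zok || yy < 0 || yy >= Y) {
              std::fill(drow, drow + X, 0.0f);
              continue;
            }
            const float* src = x.memptr() + zbase + (size_t) X * yy + xs;
            for (int ix = 0; ix < lo; ++ix) drow[ix] = 0.0f;
            for (int ix = lo; ix < hi; ++ix) drow[ix] = src[ix];
            for (int ix = hi; ix < X; ++ix) drow[ix] = 0.0f;
          }
        }
      }
    }
  }
}

static void im2col_slab(const arma::fvec& x, int X, int Y, int Z, int Cin,
                        int kx, int ky, int kz, int iz, arma::fmat& col) {
  im2col_slab_ld(x, X, Y, Z, Cin, kx, ky, kz, iz, col.memptr(),
                 col.n_rows, 0);
}

// Scatter-add the im2col gradient slab back into gx.
static void col2im_slab(const arma::fmat& gcol, int X, int Y, int Z, int Cin,
                        int kx, int ky, int kz, int iz, arma::fvec& gx) {
  const int px = kx / 2, py = ky / 2, pz = kz / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dz = 0; dz < kz; ++dz) {
      const int zz = iz + dz - pz;
      if (zz < 0 || zz >= Z) continue;
      const size_t zbase = (size_t) X * Y * (zz + (size_t) Z * ci);
      for (int dy = 0; dy < ky; ++dy) {
        for (int dx = 0; dx < kx; ++dx) {
          const int r = dx + kx * (dy + ky * (dz + kz * ci));
          const float* srcc = gcol.colptr(r);
          const int xs = dx - px;
          const int lo = std::max(0, -xs), hi = std::min(X, X - xs);
          for (int iy = 0; iy < Y; ++iy) {
            const int yy = iy + dy - py;
            if (yy < 0 || yy >= Y) continue;
            float* dst = gx.memptr() + zbase + (size_t) X * yy + xs;
            const float* src = srcc + (size_t) X * iy;
            for (int ix = lo; ix < hi; ++ix) dst[ix] += src[ix];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3_fwd(NumericVector x, IntegerVector xdim,
                        NumericVector w, IntegerVector wdim,
                        NumericVector bias) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], Cout = wdim[4];
  if (wdim[3] != Cin) stop("conv3_fwd: channel mismatch");
  const int K = kx * ky * kz * Cin;
  arma::fvec xf = as_fvec(x);
  arma::fmat W(K, Cout);
  for (int i = 0; i < K * Cout; ++i) W[i] = (float) w[i];
  NumericVector y((R_xlen_t) X * Y * Z * Cout);
  double* yp = REAL(y);
  arma::fmat col((size_t) X * Y, K);
  arma::fmat out;
  for (int iz = 0; iz < Z; ++iz) {
    im2col_slab(xf, X, Y, Z, Cin, kx, ky, kz, iz, col);
    out = col * W;                       // (XY x Cout)
    for (int co = 0; co < Cout; ++co) {
      const size_t base = (size_t) X * Y * (iz + (size_t) Z * co);
      const float* oc = out.colptr(co);
      const double b = bias[co];
      for (size_t p = 0; p < (size_t) X * Y; ++p) yp[base + p] = oc[p] + b;
    }
  }
  y.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return y;
}

// Forward pass that additionally returns the im2col buffer of the whole
// volume (all slabs stacked) as an external pointer, so the backward pass
// can skip re-gathering.  Only used when the buffer stays small.
// [[Rcpp::export]]
List conv3_fwd_cache(NumericVector x, IntegerVector xdim,
                     NumericVector w, IntegerVector wdim,
                     NumericVector bias, double maxCacheMB) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], Cout = wdim[4];
  if (wdim[3] != Cin) stop("conv3_fwd_cache: channel mismatch");
  const int K = kx * ky * kz * Cin;
  const double mb = (double) X * Y * Z * K * 4.0 / 1048576.0;
  if (mb > maxCacheMB) {
    NumericVector y = conv3_fwd(x, xdim, w, wdim, bias);
    return List::create(_["y"] = y, _["col"] = R_NilValue);
  }
  arma::fvec xf = as_fvec(x);
  arma::fmat W(K, Cout);
  for (int i = 0; i < K * Cout; ++i) W[i] = (float) w[i];
  NumericVector y((R_xlen_t) X * Y * Z * Cout);
  double* yp = REAL(y);
  Rcpp::XPtr<arma::fmat> colAll(new arma::fmat((size_t) X * Y * Z, K), true);
  arma::fmat out;
  for (int iz = 0; iz < Z; ++iz) {
    im2col_slab_ld(xf, X, Y, Z, Cin, kx, ky, kz, iz, colAll->memptr(),
                   colAll->n_rows, (size_t) X * Y * iz);
    out = colAll->rows((size_t) X * Y * iz, (size_t) X * Y * (iz + 1) - 1) * W;
    for (int co = 0; co < Cout; ++co) {
      const size_t base = (size_t) X * Y * (iz + (size_t) Z * co);
      const float* oc = out.colptr(co);
      const double b = bias[co];
      for (size_t p = 0; p < (size_t) X * Y; ++p) yp[base + p] = oc[p] + b;
    }
  }
  y.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return List::create(_["y"] = y, _["col"] = colAll);
}

// [[Rcpp::export]]
List conv3_bwd(NumericVector x, IntegerVector xdim,
               NumericVector w, IntegerVector wdim,
               NumericVector gy, SEXP colCache = R_NilValue) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], Cout = wdim[4];
  const int K = kx * ky * kz * Cin;
  const bool haveCache = colCache != R_NilValue;
  arma::fmat* colAll = haveCache ? Rcpp::XPtr<arma::fmat>(colCache).get()
                                 : (arma::fmat*) 0;
  arma::fvec xf;
  if (!haveCache) xf = as_fvec(x);
  const double* gyp = REAL(gy);
  arma::fmat W(K, Cout);
  for (int i = 0; i < K * Cout; ++i) W[i] = (float) w[i];
  arma::fvec gx((size_t) X * Y * Z * Cin, arma::fill::zeros);
  arma::fmat gW(K, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::fmat col;
  if (!haveCache) col.set_size((size_t) X * Y, K);
  arma::fmat gys((size_t) X * Y, Cout);
  arma::fmat gcol;
  for (int iz = 0; iz < Z; ++iz) {
    for (int co = 0; co < Cout; ++co) {
      const size_t base = (size_t) X * Y * (iz + (size_t) Z * co);
      float* gc = gys.colptr(co);
      double s = 0.0;
      for (size_t p = 0; p < (size_t) X * Y; ++p) {
        const double g = gyp[base + p];
        gc[p] = (float) g;
        s += g;
      }
      gb[co] += s;
    }
    if (haveCache) {
      const arma::fmat slab = colAll->rows((size_t) X * Y * iz,
                                           (size_t) X * Y * (iz + 1) - 1);
      gW += slab.t() * gys;
    } else {
      im2col_slab(xf, X, Y, Z, Cin, kx, ky, kz, iz, col);
      gW += col.t() * gys;
    }
    gcol = gys * W.t();                  // (XY x K)
    col2im_slab(gcol, X, Y, Z, Cin, kx, ky, kz, iz, gx);
  }
  NumericVector gxr(gx.n_elem), gwr((R_xlen_t) K * Cout), gbr(Cout);
  for (size_t i = 0; i < gx.n_elem; ++i) gxr[i] = gx[i];
  for (int i = 0; i < K * Cout; ++i) gwr[i] = gW[i];
  for (int i = 0; i < Cout; ++i) gbr[i] = gb[i];
  gxr.attr("dim") = xdim;
  gwr.attr("dim") = wdim;
  return List::create(_["gx"] = gxr, _["gw"] = gwr, _["gb"] = gbr);
}

// [[Rcpp::export]]
List maxpool3_fwd(NumericVector x, IntegerVector xdim, IntegerVector pool) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int px = pool[0], py = pool[1], pz = pool[2];
  if (X % px || Y % py || Z % pz) stop("maxpool3_fwd: dims not divisible by pool");
  const int Xo = X / px, Yo = Y / py, Zo = Z / pz;
  NumericVector y((R_xlen_t) Xo * Yo * Zo * C);
  IntegerVector idx(y.size());
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < Zo; ++oz)
      for (int oy = 0; oy < Yo; ++oy)
        for (int ox = 0; ox < Xo; ++ox) {
          double best = R_NegInf; size_t bi = 0;
          for (int dz = 0; dz < pz; ++dz)
            for (int dy = 0; dy < py; ++dy)
              for (int dx = 0; dx < px; ++dx) {
                const size_t i = (size_t)(ox * px + dx) + (size_t) X * ((oy * py + dy)
                                 + (size_t) Y * ((oz * pz + dz) + (size_t) Z * c));
                if (x[i] > best) { best = x[i]; bi = i; }
              }
          const size_t o = (size_t) ox + (size_t) Xo * (oy + (size_t) Yo * (oz + (size_t) Zo * c));
          y[o] = best; idx[o] = (int) bi;
        }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3_bwd(NumericVector gy, IntegerVector idx, R_xlen_t xlen,
                           IntegerVector xdim) {
  NumericVector gx(xlen);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector maxunpool3(NumericVector y, IntegerVector idx, R_xlen_t xlen,
                         IntegerVector xdim) {
  NumericVector up(xlen);   // zeros except at pooled maxima
  for (R_xlen_t i = 0; i < y.size(); ++i) up[idx[i]] = y[i];
  up.attr("dim") = xdim;
  return up;
}

// [[Rcpp::export]]
NumericVector maxunpool3_bwd(NumericVector gup, IntegerVector idx,
                             IntegerVector ydim) {
  R_xlen_t n = 1;
  for (int k = 0; k < ydim.size(); ++k) n *= ydim[k];
  NumericVector gy(n);
  for (R_xlen_t i = 0; i < n; ++i) gy[i] = gup[idx[i]];
  gy.attr("dim") = ydim;
  return gy;
}

// Batch normalization over all voxels per channel (batch of one volume).
// [[Rcpp::export]]
List bn_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
            NumericVector beta, double eps) {
  const size_t N = (size_t) xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector y(x.size()), xhat(x.size()), mean(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const size_t base = N * c;
    double m = 0;
    for (size_t i = 0; i < N; ++i) m += x[base + i];
    m /= (double) N;
    double v = 0;
    for (size_t i = 0; i < N; ++i) { const double d = x[base + i] - m; v += d * d; }
    v /= (double) N;
    const double is = 1.0 / std::sqrt(v + eps);
    mean[c] = m; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (size_t i = 0; i < N; ++i) {
      const double xh = (x[base + i] - m) * is;
      xhat[base + i] = xh;
      y[base + i] = g * xh + b;
    }
  }
  y.attr("dim") = xdim; xhat.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector gy, NumericVector xhat, NumericVector invstd,
            NumericVector gamma, IntegerVector xdim) {
  const size_t N = (size_t) xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector gx(gy.size()), ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const size_t base = N * c;
    double sg = 0, sgx = 0;
    for (size_t i = 0; i < N; ++i) {
      sg += gy[base + i];
      sgx += gy[base + i] * xhat[base + i];
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double g = gamma[c], is = invstd[c];
    const double a = sg / (double) N, b = sgx / (double) N;
    for (size_t i = 0; i < N; ++i)
      gx[base + i] = g * is * (gy[base + i] - a - xhat[base + i] * b);
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector leaky_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : slope * x[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector leaky_bwd(NumericVector gy, NumericVector x, double slope) {
  NumericVector gx(gy.size());
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[i] = x[i] > 0 ? gy[i] : slope * gy[i];
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

// Isotropic rescaling about the volume centre; linear interpolation for
// images, nearest neighbour for label maps; zero fill outside the source.
// [[Rcpp::export]]
NumericVector rescale3(NumericVector x, IntegerVector xdim, double alpha,
                       bool nearest) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const double cx = (X - 1) / 2.0, cy = (Y - 1) / 2.0, cz = (Z - 1) / 2.0;
  NumericVector y(x.size());
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= X || j >= Y || k >= Z) return 0.0;
    return x[(size_t) i + (size_t) X * (j + (size_t) Y * k)];
  };
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const double sx = cx + (i - cx) / alpha;
        const double sy = cy + (j - cy) / alpha;
        const double sz = cz + (k - cz) / alpha;
        double val;
        if (nearest) {
          val = at((int) std::lround(sx), (int) std::lround(sy),
                   (int) std::lround(sz));
        } else {
          const int x0 = (int) std::floor(sx), y0 = (int) std::floor(sy),
                    z0 = (int) std::floor(sz);
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          val = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy)
                                 * (dz ? fz : 1 - fz);
                if (wgt > 0) val += wgt * at(x0 + dx, y0 + dy, z0 + dz);
              }
        }
        y[(size_t) i + (size_t) X * (j + (size_t) Y * k)] = val;
      }
  y.attr("dim") = IntegerVector::create(X, Y, Z);
  return y;
}

// Connected-component labelling (6 or 26 connectivity), labels in scan order.
// [[Rcpp::export]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const R_xlen_t n = (R_xlen_t) X * Y * Z;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int ci = cur % X, cj = (cur / X) % Y, ck = cur / ((R_xlen_t) X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            const int i = ci + dx, j = cj + dy, k = ck + dz;
            if (i < 0 || j < 0 || k < 0 || i >= X || j >= Y || k >= Z) continue;
            const R_xlen_t q = (R_xlen_t) i + (R_xlen_t) X * (j + (R_xlen_t) Y * k);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Fill cavities: background voxels not 6-connected to the array border.
// [[Rcpp::export]]
LogicalVector fill_holes(LogicalVector mask, IntegerVector dim) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const R_xlen_t n = (R_xlen_t) X * Y * Z;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  auto push = [&](int i, int j, int k) {
    const R_xlen_t q = (R_xlen_t) i + (R_xlen_t) X * (j + (R_xlen_t) Y * k);
    if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
  };
  for (int j = 0; j < Y; ++j)
    for (int k = 0; k < Z; ++k) { push(0, j, k); push(X - 1, j, k); }
  for (int i = 0; i < X; ++i)
    for (int k = 0; k < Z; ++k) { push(i, 0, k); push(i, Y - 1, k); }
  for (int i = 0; i < X; ++i)
    for (int j = 0; j < Y; ++j) { push(i, j, 0); push(i, j, Z - 1); }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    const R_xlen_t cur = stack.back(); stack.pop_back();
    const int ci = cur % X, cj = (cur / X) % Y, ck = cur / ((R_xlen_t) X * Y);
    for (int t = 0; t < 6; ++t) {
      const int i = ci + off[t][0], j = cj + off[t][1], k = ck + off[t][2];
      if (i < 0 || j < 0 || k < 0 || i >= X || j >= Y || k >= Z) continue;
      push(i, j, k);
    }
  }
  LogicalVector out(n);
  for (R_xlen_t q = 0; q < n; ++q) out[q] = mask[q] || !outside[q];
  out.attr("dim") = dim;
  return out;
}

static LogicalVector morph3(LogicalVector mask, IntegerVector dim,
                            IntegerMatrix off, bool dilate) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  const R_xlen_t n = (R_xlen_t) X * Y * Z;
  LogicalVector out(n);
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        bool acc = !dilate;
        for (int t = 0; t < off.nrow(); ++t) {
          const int ii = i + off(t, 0), jj = j + off(t, 1), kk = k + off(t, 2);
          bool v = false;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < X && jj < Y && kk < Z)
            v = mask[(R_xlen_t) ii + (R_xlen_t) X * (jj + (R_xlen_t) Y * kk)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[(R_xlen_t) i + (R_xlen_t) X * (j + (R_xlen_t) Y * k)] = acc;
      }
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
LogicalVector dilate3(LogicalVector mask, IntegerVector dim, IntegerMatrix off) {
  return morph3(mask, dim, off, true);
}

// [[Rcpp::export]]
LogicalVector erode3(LogicalVector mask, IntegerVector dim, IntegerMatrix off) {
  return morph3(mask, dim, off, false);
}

// Millimetre coordinates of surface voxels (any 6-neighbour background or
// array border counts as exposure).
static arma::mat surface_coords(const LogicalVector& m, const IntegerVector& dim,
                                const NumericVector& sp) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  std::vector<double> pts;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const R_xlen_t q = (R_xlen_t) i + (R_xlen_t) X * (j + (R_xlen_t) Y * k);
        if (!m[q]) continue;
        bool surf = false;
        const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int t = 0; t < 6 && !surf; ++t) {
          const int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= X || jj >= Y || kk >= Z) surf = true;
          else if (!m[(R_xlen_t) ii + (R_xlen_t) X * (jj + (R_xlen_t) Y * kk)]) surf = true;
        }
        if (surf) { pts.push_back(i * sp[0]); pts.push_back(j * sp[1]); pts.push_back(k * sp[2]); }
      }
  arma::mat out(3, pts.size() / 3);
  for (size_t c = 0; c < out.n_cols; ++c)
    for (int r = 0; r < 3; ++r) out(r, c) = pts[3 * c + r];
  return out;
}

// Directed surface distances (mm) from every surface voxel of `a` to the
// nearest surface voxel of `b`.
// [[Rcpp::export]]
NumericVector surface_dists(LogicalVector a, LogicalVector b,
                            IntegerVector dim, NumericVector spacing) {
  arma::mat A = surface_coords(a, dim, spacing);
  arma::mat B = surface_coords(b, dim, spacing);
  if (A.n_cols == 0 || B.n_cols == 0) stop("surface_dists: empty mask");
  NumericVector d(A.n_cols);
  for (size_t i = 0; i < A.n_cols; ++i) {
    double best = R_PosInf;
    const double ax = A(0, i), ay = A(1, i), az = A(2, i);
    for (size_t j = 0; j < B.n_cols; ++j) {
      const double dx = ax - B(0, j), dy = ay - B(1, j), dz = az - B(2, j);
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    d[i] = std::sqrt(best);
  }
  return d;
}

// Fused LeakyReLU -> BatchNorm forward: a = leaky(x), then per-channel
// normalisation of a by the statistics of the current batch (one training
// sample, or one whole volume at inference).  Returns y (conv input),
// xhat and invstd for the backward pass.  Numerically identical to
// leaky_fwd followed by bn_fwd.
// [[Rcpp::export]]
List lbn_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
             NumericVector beta, double slope, double eps) {
  const size_t N = (size_t) xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector y(x.size()), xhat(x.size()), mean(C), invstd(C);
  const double* xp = REAL(x);
  double* yp = REAL(y); double* hp = REAL(xhat);
  for (int c = 0; c < C; ++c) {
    const size_t base = N * c;
    double s = 0, ss = 0;
    for (size_t i = 0; i < N; ++i) {
      const double xi = xp[base + i];
      const double a = xi > 0 ? xi : slope * xi;
      hp[base + i] = a;          // temporarily holds the activation
      s += a; ss += a * a;
    }
    const double m = s / (double) N;
    const double v = std::max(ss / (double) N - m * m, 0.0);
    const double is = 1.0 / std::sqrt(v + eps);
    mean[c] = m; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (size_t i = 0; i < N; ++i) {
      const double xh = (hp[base + i] - m) * is;
      hp[base + i] = xh;
      yp[base + i] = g * xh + b;
    }
  }
  y.attr("dim") = xdim; xhat.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["invstd"] = invstd);
}

// Fused backward of LeakyReLU -> BatchNorm.
// [[Rcpp::export]]
List lbn_bwd(NumericVector gy, NumericVector xhat, NumericVector invstd,
             NumericVector gamma, NumericVector x, double slope,
             IntegerVector xdim) {
  const size_t N = (size_t) xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector gx(gy.size()), ggamma(C), gbeta(C);
  const double* gp = REAL(gy); const double* hp = REAL(xhat);
  const double* xp = REAL(x); double* op = REAL(gx);
  for (int c = 0; c < C; ++c) {
    const size_t base = N * c;
    double sg = 0, sgx = 0;
    for (size_t i = 0; i < N; ++i) {
      sg += gp[base + i];
      sgx += gp[base + i] * hp[base + i];
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double g = gamma[c], is = invstd[c];
    const double a = sg / (double) N, b = sgx / (double) N;
    for (size_t i = 0; i < N; ++i) {
      const double ga = g * is * (gp[base + i] - a - hp[base + i] * b);
      op[base + i] = xp[base + i] > 0 ? ga : slope * ga;
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// One rectified-Adam leaf update in a single pass (used by radamStep).
// [[Rcpp::export]]
List radam_leaf(NumericVector p, NumericVector g, NumericVector m,
                NumericVector v, double lr, double b1, double b2,
                double eps, double wd, int t, bool rect, double r) {
  const R_xlen_t n = p.size();
  NumericVector pn(n), mn(n), vn(n);
  const double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    if (wd > 0) gi += wd * p[i];
    const double mi = b1 * m[i] + (1 - b1) * gi;
    const double vi = b2 * v[i] + (1 - b2) * gi * gi;
    const double mh = mi / c1;
    double pi;
    if (rect) pi = p[i] - lr * r * mh / (std::sqrt(vi / c2) + eps);
    else      pi = p[i] - lr * mh;
    pn[i] = pi; mn[i] = mi; vn[i] = vi;
  }
  pn.attr("dim") = p.attr("dim");
  return List::create(_["p"] = pn, _["m"] = mn, _["v"] = vn);
}
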