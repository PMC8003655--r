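// 3D convolution kernels for the block-named encoder-decoder network.
//
// Layout convention: an R array of dim (X, Y, Z, C) is column-major, so it
// can be viewed without copying as an (X*Y*Z) x C matrix with voxels running
// fastest along x.  All gemm-sized work runs in single precision through the
// BLAS behind Armadillo; parameters and activations cross the R boundary as
// doubles.  Single precision is deterministic run-to-run on one thread, which
// the freeze bit-identity contract relies on.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

// Copy an (nx,ny,nz,c) volume into an (nx+2,ny+2,nz+2,c) zero-halo buffer.
static void pad_in(const double* x, int nx, int ny, int nz, int cin,
                   arma::fmat& P) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  P.zeros();
  for (int c = 0; c < cin; ++c) {
    float* pc = P.colptr(c);
    const double* xc = x + (size_t)nx * ny * nz * c;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        float* prow = pc + ((size_t)(k + 1) * py + (j + 1)) * px + 1;
        const double* xrow = xc + ((size_t)k * ny + j) * nx;
        for (int i = 0; i < nx; ++i) prow[i] = (float)xrow[i];
      }
  }
}

// Extract the interior of a padded buffer into a double R array.
static NumericVector unpad_out(const arma::fmat& P, int nx, int ny, int nz,
                               int cout) {
  const int px = nx + 2, py = ny + 2;
  NumericVector out((R_xlen_t)nx * ny * nz * cout);
  double* o = out.begin();
  for (int c = 0; c < cout; ++c) {
    const float* pc = P.colptr(c);
    double* oc = o + (size_t)nx * ny * nz * c;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const float* prow = pc + ((size_t)(k + 1) * py + (j + 1)) * px + 1;
        double* orow = oc + ((size_t)k * ny + j) * nx;
        for (int i = 0; i < nx; ++i) orow[i] = (double)prow[i];
      }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// Zero every halo voxel of a padded buffer (rows outside the interior).
static void zero_halo(arma::fmat& P, int nx, int ny, int nz) {
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  for (arma::uword c = 0; c < P.n_cols; ++c) {
    float* pc = P.colptr(c);
    for (int k = 0; k < pz; ++k)
      for (int j = 0; j < py; ++j) {
        float* row = pc + ((size_t)k * py + j) * px;
        if (k == 0 || k == pz - 1 || j == 0 || j == py - 1) {
          std::fill(row, row + px, 0.0f);
        } else {
          row[0] = 0.0f;
          row[px - 1] = 0.0f;
        }
      }
  }
}

static arma::fmat as_fmat(const NumericVector& v, int nrow, int ncol) {
  arma::fmat out(nrow, ncol);
  const double* p = v.begin();
  float* q = out.memptr();
  const R_xlen_t n = (R_xlen_t)nrow * ncol;
  for (R_xlen_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return out;
}

static NumericVector to_numeric(const arma::fmat& m, IntegerVector dim) {
  NumericVector out(m.n_elem);
  const float* p = m.memptr();
  double* q = out.begin();
  for (arma::uword i = 0; i < m.n_elem; ++i) q[i] = (double)p[i];
  out.attr("dim") = dim;
  return out;
}

static IntegerVector get_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return d;
}

// im2col for a 3x3x3 kernel with zero padding 1.  Column order matches the
// column-major layout of a (3,3,3,Cin,Cout) weight array: dx fastest, then
// dy, dz, cin.
static void im2col3(const arma::fmat& X, int nx, int ny, int nz, int cin,
                    int stride, int ox, int oy, int oz, arma::fmat& cols) {
  for (int c = 0; c < cin; ++c) {
    const float* xc = X.colptr(c);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int col = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1) + 27 * c;
          float* cp = cols.colptr(col);
          for (int k = 0; k < oz; ++k) {
            const int sz = k * stride + dz;
            const bool zok = (sz >= 0 && sz < nz);
            for (int j = 0; j < oy; ++j) {
              const int sy = j * stride + dy;
              float* crow = cp + ((size_t)k * oy + j) * ox;
              if (!zok || sy < 0 || sy >= ny) {
                std::fill(crow, crow + ox, 0.0f);
                continue;
              }
              const float* xrow = xc + ((size_t)sz * ny + sy) * nx;
              if (stride == 1) {
                int i0 = std::max(0, -dx), i1 = std::min(ox, nx - dx);
                for (int i = 0; i < i0; ++i) crow[i] = 0.0f;
                for (int i = i0; i < i1; ++i) crow[i] = xrow[i + dx];
                for (int i = i1; i < ox; ++i) crow[i] = 0.0f;
              } else {
                for (int i = 0; i < ox; ++i) {
                  const int sx = i * stride + dx;
                  crow[i] = (sx >= 0 && sx < nx) ? xrow[sx] : 0.0f;
                }
              }
            }
          }
        }
  }
}

// scatter-add transpose of im2col3
static void col2im3(const arma::fmat& cols, int nx, int ny, int nz, int cin,
                    int stride, int ox, int oy, int oz, arma::fmat& X) {
  X.zeros();
  for (int c = 0; c < cin; ++c) {
    float* xc = X.colptr(c);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int col = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1) + 27 * c;
          const float* cp = cols.colptr(col);
          for (int k = 0; k < oz; ++k) {
            const int sz = k * stride + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int j = 0; j < oy; ++j) {
              const int sy = j * stride + dy;
              if (sy < 0 || sy >= ny) continue;
              const float* crow = cp + ((size_t)k * oy + j) * ox;
              float* xrow = xc + ((size_t)sz * ny + sy) * nx;
              for (int i = 0; i < ox; ++i) {
                const int sx = i * stride + dx;
                if (sx >= 0 && sx < nx) xrow[sx] += crow[i];
              }
            }
          }
        }
  }
}

// Forward 3x3x3 convolution, padding 1, optional fused ReLU.
// x: (X,Y,Z,Cin); w: (3,3,3,Cin,Cout); b: length Cout.
// Stride 1 runs as 27 row-shifted sgemms on a zero-halo padded layout (the
// halo makes the shifted reads exact, no im2col materialization); stride 2
// falls back to im2col.
// [[Rcpp::export(name = ".conv3_fw")]]
NumericVector conv3_fw(NumericVector x, NumericVector w, NumericVector b,
                       int stride, bool relu) {
  IntegerVector dx = get_dim(x), dw = get_dim(w);
  const int nx = dx[0], ny = dx[1], nz = dx[2], cin = dx[3];
  const int cout = dw[4];

  if (stride == 1) {
    const int px = nx + 2, py = ny + 2, pz = nz + 2;
    const int npad = px * py * pz;
    arma::fmat Xp(npad, cin), Yp(npad, cout, arma::fill::zeros);
    pad_in(x.begin(), nx, ny, nz, cin, Xp);
    arma::fmat W = as_fmat(w, 27 * cin, cout);
    arma::fmat Woff(cin, cout);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dxo = -1; dxo <= 1; ++dxo) {
          const int off = (dxo + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          for (int ci = 0; ci < cin; ++ci)
            Woff.row(ci) = W.row(off + 27 * ci);
          const int s = dxo + px * dy + px * py * dz;
          const int r0 = std::max(0, -s);
          const int m = npad - std::max(0, s) - r0;
          sgemm('N', 'N', m, cout, cin, 1.0f, Xp.memptr() + r0 + s, npad,
                Woff.memptr(), cin, 1.0f, Yp.memptr() + r0, npad);
        }
    for (int c = 0; c < cout; ++c) Yp.col(c) += (float)b[c];
    if (relu) Yp.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    zero_halo(Yp, nx, ny, nz);
    return unpad_out(Yp, nx, ny, nz, cout);
  }

  const int ox = (nx + 2 - 3) / stride + 1;
  const int oy = (ny + 2 - 3) / stride + 1;
  const int oz = (nz + 2 - 3) / stride + 1;
  const int nvox = nx * ny * nz, ovox = ox * oy * oz;
  arma::fmat X = as_fmat(x, nvox, cin);
  arma::fmat W = as_fmat(w, 27 * cin, cout);
  arma::fmat cols(ovox, 27 * cin);
  im2col3(X, nx, ny, nz, cin, stride, ox, oy, oz, cols);
  arma::fmat Y = cols * W;
  for (int c = 0; c < cout; ++c) Y.col(c) += (float)b[c];
  if (relu) Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  return to_numeric(Y, IntegerVector::create(ox, oy, oz, cout));
}

// Backward pass for conv3_fw.  y is the forward output (post-ReLU when relu
// is true); want_dw = FALSE skips the weight-gradient gemm for frozen layers.
// [[Rcpp::export(name = ".conv3_bw")]]
List conv3_bw(NumericVector x, NumericVector w, NumericVector dy,
              NumericVector y, int stride, bool relu, bool want_dw,
              bool want_dx) {
  IntegerVector dxd = get_dim(x), dwd = get_dim(w), dyd = get_dim(dy);
  const int nx = dxd[0], ny = dxd[1], nz = dxd[2], cin = dxd[3];
  const int cout = dwd[4];
  const int ox = dyd[0], oy = dyd[1], oz = dyd[2];
  const int nvox = nx * ny * nz, ovox = ox * oy * oz;

  if (stride == 1) {
    const int px = nx + 2, py = ny + 2, pz = nz + 2;
    const int npad = px * py * pz;
    arma::fmat Xp(npad, cin), dYp(npad, cout);
    pad_in(x.begin(), nx, ny, nz, cin, Xp);
    pad_in(dy.begin(), nx, ny, nz, cout, dYp);
    if (relu) {
      // mask by the (interior) forward output; halo already zero
      const double* yp = y.begin();
      for (int c = 0; c < cout; ++c) {
        float* g = dYp.colptr(c);
        const double* yc = yp + (size_t)nvox * c;
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j) {
            float* grow = g + ((size_t)(k + 1) * py + (j + 1)) * px + 1;
            const double* yrow = yc + ((size_t)k * ny + j) * nx;
            for (int i = 0; i < nx; ++i)
              if (yrow[i] <= 0.0) grow[i] = 0.0f;
          }
      }
    }
    arma::fmat W = as_fmat(w, 27 * cin, cout);
    arma::fmat Woff(cin, cout), dWoff(cin, cout);
    arma::fmat dXp(npad, cin, arma::fill::zeros);
    NumericVector dwv, dbv(cout);
    arma::fmat dWall(27 * cin, cout, arma::fill::zeros);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dyo = -1; dyo <= 1; ++dyo)
        for (int dxo = -1; dxo <= 1; ++dxo) {
          const int off = (dxo + 1) + 3 * (dyo + 1) + 9 * (dz + 1);
          for (int ci = 0; ci < cin; ++ci)
            Woff.row(ci) = W.row(off + 27 * ci);
          const int s = dxo + px * dyo + px * py * dz;
          const int r0 = std::max(0, -s);
          const int m = npad - std::max(0, s) - r0;
          // dX[r + s] += dY[r] * Woff^T
          if (want_dx)
            sgemm('N', 'T', m, cin, cout, 1.0f, dYp.memptr() + r0, npad,
                  Woff.memptr(), cin, 1.0f, dXp.memptr() + r0 + s, npad);
          if (want_dw) {
            // dWoff = X[r + s]^T * dY[r]
            sgemm('T', 'N', cin, cout, m, 1.0f, Xp.memptr() + r0 + s, npad,
                  dYp.memptr() + r0, npad, 0.0f, dWoff.memptr(), cin);
            for (int ci = 0; ci < cin; ++ci)
              dWall.row(off + 27 * ci) = dWoff.row(ci);
          }
        }
    if (want_dw) {
      dwv = to_numeric(dWall, IntegerVector::create(3, 3, 3, cin, cout));
      for (int c = 0; c < cout; ++c) dbv[c] = arma::accu(dYp.col(c));
    }
    NumericVector dxv;
    if (want_dx) {
      zero_halo(dXp, nx, ny, nz);
      dxv = unpad_out(dXp, nx, ny, nz, cin);
    }
    return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
  }

  arma::fmat dY = as_fmat(dy, ovox, cout);
  if (relu) {
    const double* yp = y.begin();
    float* g = dY.memptr();
    const R_xlen_t n = (R_xlen_t)ovox * cout;
    for (R_xlen_t i = 0; i < n; ++i)
      if (yp[i] <= 0.0) g[i] = 0.0f;
  }

  arma::fmat X = as_fmat(x, nvox, cin);
  arma::fmat W = as_fmat(w, 27 * cin, cout);

  NumericVector dwv, dbv(cout);
  if (want_dw) {
    arma::fmat cols(ovox, 27 * cin);
    im2col3(X, nx, ny, nz, cin, stride, ox, oy, oz, cols);
    arma::fmat dW = cols.t() * dY;
    dwv = to_numeric(dW, IntegerVector::create(3, 3, 3, cin, cout));
    for (int c = 0; c < cout; ++c) dbv[c] = arma::accu(dY.col(c));
  }

  NumericVector dxv;
  if (want_dx) {
    arma::fmat dcols = dY * W.t();
    arma::fmat dX(nvox, cin);
    col2im3(dcols, nx, ny, nz, cin, stride, ox, oy, oz, dX);
    dxv = to_numeric(dX, IntegerVector::create(nx, ny, nz, cin));
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Transposed convolution, kernel 2, stride 2 (resolution doubling).
// Each output voxel receives exactly one kernel tap, so the op decomposes
// into 8 offset-wise gemms.  w: (2,2,2,Cin,Cout).
// [[Rcpp::export(name = ".convt2_fw")]]
NumericVector convt2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = get_dim(x), dw = get_dim(w);
  const int nx = dx[0], ny = dx[1], nz = dx[2], cin = dx[3];
  const int cout = dw[4];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const int nvox = nx * ny * nz;

  arma::fmat X = as_fmat(x, nvox, cin);
  arma::fmat Wall = as_fmat(w, 8 * cin, cout);  // tap index fastest
  arma::fmat Y((size_t)ox * oy * oz, cout);

  for (int off = 0; off < 8; ++off) {
    const int tx = off & 1, ty = (off >> 1) & 1, tz = (off >> 2) & 1;
    arma::fmat Woff(cin, cout);
    for (int ci = 0; ci < cin; ++ci)
      Woff.row(ci) = Wall.row(off + 8 * ci);
    arma::fmat Yoff = X * Woff;  // nvox x cout
    for (int c = 0; c < cout; ++c) {
      const float* src = Yoff.colptr(c);
      float* dst = Y.colptr(c);
      const float bias = (float)b[c];
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          const float* s = src + ((size_t)k * ny + j) * nx;
          float* d = dst + ((size_t)(2 * k + tz) * oy + (2 * j + ty)) * ox + tx;
          for (int i = 0; i < nx; ++i) d[2 * i] = s[i] + bias;
        }
    }
  }
  return to_numeric(Y, IntegerVector::create(ox, oy, oz, cout));
}

// [[Rcpp::export(name = ".convt2_bw")]]
List convt2_bw(NumericVector x, NumericVector w, NumericVector dy,
               bool want_dw) {
  IntegerVector dxd = get_dim(x), dwd = get_dim(w), dyd = get_dim(dy);
  const int nx = dxd[0], ny = dxd[1], nz = dxd[2], cin = dxd[3];
  const int cout = dwd[4];
  const int ox = dyd[0], oy = dyd[1];
  const int nvox = nx * ny * nz;
  const int ovox = ox * oy * dyd[2];

  arma::fmat X = as_fmat(x, nvox, cin);
  arma::fmat Wall = as_fmat(w, 8 * cin, cout);
  arma::fmat dYfull = as_fmat(dy, ovox, cout);
  arma::fmat dX(nvox, cin, arma::fill::zeros);
  arma::fmat dWall(8 * cin, cout, arma::fill::zeros);

  for (int off = 0; off < 8; ++off) {
    const int tx = off & 1, ty = (off >> 1) & 1, tz = (off >> 2) & 1;
    arma::fmat dYoff(nvox, cout);
    for (int c = 0; c < cout; ++c) {
      float* d = dYoff.colptr(c);
      const float* src = dYfull.colptr(c);
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          float* drow = d + ((size_t)k * ny + j) * nx;
          const float* s =
              src + ((size_t)(2 * k + tz) * oy + (2 * j + ty)) * ox + tx;
          for (int i = 0; i < nx; ++i) drow[i] = s[2 * i];
        }
    }
    arma::fmat Woff(cin, cout);
    for (int ci = 0; ci < cin; ++ci) Woff.row(ci) = Wall.row(off + 8 * ci);
    dX += dYoff * Woff.t();
    if (want_dw) {
      arma::fmat dWoff = X.t() * dYoff;  // cin x cout
      for (int ci = 0; ci < cin; ++ci)
        dWall.row(off + 8 * ci) += dWoff.row(ci);
    }
  }

  NumericVector dwv, dbv(cout);
  if (want_dw) {
    dwv = to_numeric(dWall, IntegerVector::create(2, 2, 2, cin, cout));
    for (int c = 0; c < cout; ++c) dbv[c] = arma::accu(dYfull.col(c));
  }
  NumericVector dxv = to_numeric(dX, IntegerVector::create(nx, ny, nz, cin));
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Pointwise (1x1x1) convolution head with optional fused sigmoid.
// w: (Cin, Cout).
// [[Rcpp::export(name = ".conv1_fw")]]
NumericVector conv1_fw(NumericVector x, NumericVector w, NumericVector b,
                       bool sigmoid) {
  IntegerVector dx = get_dim(x), dw = get_dim(w);
  const int nvox = dx[0] * dx[1] * dx[2];
  const int cin = dx[3], cout = dw[1];
  arma::fmat X = as_fmat(x, nvox, cin);
  arma::fmat W = as_fmat(w, cin, cout);
  arma::fmat Y = X * W;
  for (int c = 0; c < cout; ++c) Y.col(c) += (float)b[c];
  if (sigmoid) Y.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  return to_numeric(Y, IntegerVector::create(dx[0], dx[1], dx[2], cout));
}

// [[Rcpp::export(name = ".conv1_bw")]]
List conv1_bw(NumericVector x, NumericVector w, NumericVector dy,
              NumericVector y, bool sigmoid, bool want_dw) {
  IntegerVector dxd = get_dim(x), dwd = get_dim(w);
  const int nvox = dxd[0] * dxd[1] * dxd[2];
  const int cin = dxd[3], cout = dwd[1];
  arma::fmat dY = as_fmat(dy, nvox, cout);
  if (sigmoid) {
    const double* yp = y.begin();
    float* g = dY.memptr();
    const R_xlen_t n = (R_xlen_t)nvox * cout;
    for (R_xlen_t i = 0; i < n; ++i) {
      const float s = (float)yp[i];
      g[i] *= s * (1.0f - s);
    }
  }
  arma::fmat X = as_fmat(x, nvox, cin);
  arma::fmat W = as_fmat(w, cin, cout);
  NumericVector dwv, dbv(cout);
  if (want_dw) {
    arma::fmat dW = X.t() * dY;
    dwv = to_numeric(dW, IntegerVector::create(cin, cout));
    for (int c = 0; c < cout; ++c) dbv[c] = arma::accu(dY.col(c));
  }
  arma::fmat dX = dY * W.t();
  NumericVector dxv =
      to_numeric(dX, IntegerVector::create(dxd[0], dxd[1], dxd[2], cin));
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}
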