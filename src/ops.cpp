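// Low-level raster and convolution kernels.
//
// Layout conventions (must match R/nn-autograd.R):
//  - feature maps are arma::cube (H rows, W cols, C slices); batches are
//    handled in R by looping over samples.
//  - im2col output: (k*k*C) x (Ho*Wo); row index = ky + k*kx + k*k*c,
//    column index = oy + Ho*ox (column-major over the output map, so an
//    (Ho*Wo x Cout) matrix can be reshaped directly to an (Ho,Wo,Cout) array
//    on the R side).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// im2colT: (Ho*Wo) x (k*k*C); row index = oy + Ho*ox (column-major over
// the output map), column index r = ky + k*kx + k*k*c. This layout keeps
// both the gather loops and the GEMMs contiguous.
static arma::mat im2colT(const arma::cube& x, int k, int stride, int pad,
                         int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  arma::mat cols(Ho * Wo, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int r = ky + k * kx + k * k * c;
        double* colr = cols.colptr(r);
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + kx * dil;
          if (ix < 0 || ix >= W) continue;
          const double* src = x.slice_colptr(c, ix);
          double* dst = colr + Ho * ox;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride - pad + ky * dil;
            if (iy < 0 || iy >= H) continue;
            dst[oy] = src[iy];
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2colT: scatter-add (Ho*Wo) x (k*k*C) back into H x W x C
static void col2imT_into(const arma::mat& cols, arma::cube& x, int k,
                         int stride, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int r = ky + k * kx + k * k * c;
        const double* colr = cols.colptr(r);
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride - pad + kx * dil;
          if (ix < 0 || ix >= W) continue;
          double* dst = x.slice_colptr(c, ix);
          const double* src = colr + Ho * ox;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride - pad + ky * dil;
            if (iy < 0 || iy >= H) continue;
            dst[iy] += src[oy];
          }
        }
      }
    }
  }
}

static arma::cube cube_view(const Rcpp::NumericVector& x, int H, int W, int C,
                            int n) {
  // zero-copy view of sample n of an (H,W,C,N) array
  return arma::cube(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                    H, W, C, false, true);
}

static arma::mat mat_view(const Rcpp::NumericVector& x, int HW, int C, int n) {
  // zero-copy (H*W) x C matrix view of sample n of an (H,W,C,N) array
  return arma::mat(const_cast<double*>(x.begin()) + (size_t)n * HW * C,
                   HW, C, false, true);
}

// Batched convolution forward: x (H,W,C,N), w (Cout x k*k*C), b length Cout.
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(const NumericVector& x, const arma::mat& w,
                           const arma::vec& b, int k, int stride, int pad,
                           int dil) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int Cout = w.n_rows;
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat wt = w.t();
  for (int n = 0; n < N; ++n) {
    arma::cube xn = cube_view(x, H, W, C, n);
    arma::mat cols = im2colT(xn, k, stride, pad, dil);
    arma::mat on(out.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                 false, true);
    on = cols * wt;
    on.each_row() += b.t();
  }
  return out;
}

// Batched convolution backward; recomputes im2colT internally.
// [[Rcpp::export]]
List cpp_conv_bwd(const NumericVector& x, const arma::mat& w,
                  const NumericVector& gout, int k, int stride, int pad,
                  int dil) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = out_size(H, k, stride, pad, dil);
  const int Wo = out_size(W, k, stride, pad, dil);
  const int Cout = w.n_rows;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dw(Cout, w.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::cube xn = cube_view(x, H, W, C, n);
    arma::mat cols = im2colT(xn, k, stride, pad, dil);
    arma::mat gm = mat_view(gout, Ho * Wo, Cout, n);
    dw += gm.t() * cols;
    db += arma::sum(gm, 0).t();
    arma::mat gcols = gm * w;                     // HoWo x kkC
    arma::cube dxn(dx.begin() + (size_t)n * H * W * C, H, W, C, false, true);
    col2imT_into(gcols, dxn, k, stride, pad, dil);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Batched transposed convolution forward: x (H,W,Cin,N),
// w (Cin x k*k*Cout); output ((H-1)s+k-2p, ., Cout, N).
// [[Rcpp::export]]
NumericVector cpp_convt_fwd(const NumericVector& x, const arma::mat& w,
                            const arma::vec& b, int k, int stride, int pad,
                            int cout) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Ho = (H - 1) * stride + k - 2 * pad;
  const int Wo = (W - 1) * stride + k - 2 * pad;
  NumericVector out((R_xlen_t)Ho * Wo * cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xm = mat_view(x, H * W, Cin, n);
    arma::mat cols = xm * w;                      // HW x kkCout
    arma::cube on(out.begin() + (size_t)n * Ho * Wo * cout, Ho, Wo, cout,
                  false, true);
    on.zeros();
    col2imT_into(cols, on, k, stride, pad, 1);
    arma::mat onm(out.begin() + (size_t)n * Ho * Wo * cout, Ho * Wo, cout,
                  false, true);
    onm.each_row() += b.t();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convt_bwd(const NumericVector& x, const arma::mat& w,
                   const NumericVector& gout, int k, int stride, int pad,
                   int cout) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Ho = (H - 1) * stride + k - 2 * pad;
  const int Wo = (W - 1) * stride + k - 2 * pad;
  NumericVector dx((R_xlen_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dw(Cin, w.n_cols, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  const arma::mat wt = w.t();
  for (int n = 0; n < N; ++n) {
    arma::cube gn = cube_view(gout, Ho, Wo, cout, n);
    arma::mat gcols = im2colT(gn, k, stride, pad, 1);   // HW x kkCout
    arma::mat dxm(dx.begin() + (size_t)n * H * W * Cin, H * W, Cin, false,
                  true);
    dxm = gcols * wt;
    arma::mat xm = mat_view(x, H * W, Cin, n);
    dw += xm.t() * gcols;
    arma::mat gm = mat_view(gout, Ho * Wo, cout, n);
    db += arma::sum(gm, 0).t();
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Valid-mode 2D cross-correlation of a matrix with a small kernel (SSIM
// windows and similar separable filters).
// [[Rcpp::export]]
arma::mat cpp_conv2_valid(const arma::mat& x, const arma::mat& kern) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = kern.n_rows, kw = kern.n_cols;
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than image");
  arma::mat out(Ho, Wo, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      out(i, j) = arma::accu(x.submat(i, j, i + kh - 1, j + kw - 1) % kern);
  return out;
}

// Connected-component labelling of a binary matrix (conn = 4 or 8).
// Returns integer labels 1..n, 0 for background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int conn) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qy(H * W), qx(H * W);
  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[] = {-1, 1, 0, 0};
  const int dx4[] = {0, 0, -1, 1};
  const int nn = (conn == 8) ? 8 : 4;
  const int* dy = (conn == 8) ? dy8 : dy4;
  const int* dx = (conn == 8) ? dx8 : dx4;
  int next = 0;
  for (int x0 = 0; x0 < W; ++x0) {
    for (int y0 = 0; y0 < H; ++y0) {
      if (mask(y0, x0) == 0 || lab(y0, x0) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qy[tail] = y0; qx[tail] = x0; ++tail;
      lab(y0, x0) = next;
      while (head < tail) {
        const int cy = qy[head], cx = qx[head]; ++head;
        for (int d = 0; d < nn; ++d) {
          const int ny = cy + dy[d], nx = cx + dx[d];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            qy[tail] = ny; qx[tail] = nx; ++tail;
          }
        }
      }
    }
  }
  return lab;
}

static double pt_seg_dist(double px, double py, double x1, double y1,
                          double x2, double y2) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double len2 = dx * dx + dy * dy;
  double t = len2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / len2 : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  const double qx = x1 + t * dx, qy = y1 + t * dy;
  return std::sqrt((px - qx) * (px - qx) + (py - qy) * (py - qy));
}

// Even-odd scanline fill at pixel centres, with on-boundary pixels included.
// Vertices are 0-based pixel-centred (x, y); pixels are matrix cells
// (row = y, col = x).
// [[Rcpp::export]]
IntegerMatrix cpp_fill_polygon(int H, int W, const NumericVector& xs,
                               const NumericVector& ys) {
  const int n = xs.size();
  IntegerMatrix out(H, W);
  if (n < 3) return out;
  // interior: crossing-number test at each pixel centre
  double ymin = *std::min_element(ys.begin(), ys.end());
  double ymax = *std::max_element(ys.begin(), ys.end());
  double xmin = *std::min_element(xs.begin(), xs.end());
  double xmax = *std::max_element(xs.begin(), xs.end());
  const int y0 = std::max(0, (int)std::floor(ymin));
  const int y1 = std::min(H - 1, (int)std::ceil(ymax));
  const int x0 = std::max(0, (int)std::floor(xmin));
  const int x1 = std::min(W - 1, (int)std::ceil(xmax));
  for (int py = y0; py <= y1; ++py) {
    for (int px = x0; px <= x1; ++px) {
      bool inside = false;
      for (int i = 0, j = n - 1; i < n; j = i++) {
        const double xi = xs[i], yi = ys[i], xj = xs[j], yj = ys[j];
        if ((yi > py) != (yj > py)) {
          const double xint = xi + (py - yi) * (xj - xi) / (yj - yi);
          if (px < xint) inside = !inside;
        }
      }
      if (inside) out(py, px) = 1;
    }
  }
  // boundary pixels: centre within eps of any edge
  const double eps = 1e-9;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    const double exmin = std::min(xs[i], xs[j]) - 1, exmax = std::max(xs[i], xs[j]) + 1;
    const double eymin = std::min(ys[i], ys[j]) - 1, eymax = std::max(ys[i], ys[j]) + 1;
    const int by0 = std::max(0, (int)std::floor(eymin));
    const int by1 = std::min(H - 1, (int)std::ceil(eymax));
    const int bx0 = std::max(0, (int)std::floor(exmin));
    const int bx1 = std::min(W - 1, (int)std::ceil(exmax));
    for (int py = by0; py <= by1; ++py)
      for (int px = bx0; px <= bx1; ++px)
        if (pt_seg_dist(px, py, xs[i], ys[i], xs[j], ys[j]) < eps)
          out(py, px) = 1;
  }
  return out;
}

// Bilinear resize of an H x W x C cube (align_corners = FALSE convention).
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(Ho, Wo, C);
  const double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int c = 0; c < C; ++c) {
    for (int ox = 0; ox < Wo; ++ox) {
      double fx = (ox + 0.5) * sx - 0.5;
      if (fx < 0) fx = 0;
      if (fx > W - 1) fx = W - 1;
      const int ix = (int)fx;
      const int ix1 = std::min(ix + 1, W - 1);
      const double wx = fx - ix;
      for (int oy = 0; oy < Ho; ++oy) {
        double fy = (oy + 0.5) * sy - 0.5;
        if (fy < 0) fy = 0;
        if (fy > H - 1) fy = H - 1;
        const int iy = (int)fy;
        const int iy1 = std::min(iy + 1, H - 1);
        const double wy = fy - iy;
        out(oy, ox, c) =
          (1 - wy) * ((1 - wx) * x(iy, ix, c) + wx * x(iy, ix1, c)) +
          wy * ((1 - wx) * x(iy1, ix, c) + wx * x(iy1, ix1, c));
      }
    }
  }
  return out;
}

// Nearest-neighbour resize of a matrix (binary masks).
// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(const NumericMatrix& x, int Ho, int Wo) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(Ho, Wo);
  const double sy = (double)H / Ho, sx = (double)W / Wo;
  for (int ox = 0; ox < Wo; ++ox) {
    int ix = (int)((ox + 0.5) * sx);
    if (ix > W - 1) ix = W - 1;
    for (int oy = 0; oy < Ho; ++oy) {
      int iy = (int)((oy + 0.5) * sy);
      if (iy > H - 1) iy = H - 1;
      out(oy, ox) = x(iy, ix);
    }
  }
  return out;
}
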