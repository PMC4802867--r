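// Low-level image kernels: FFT-based complex convolution for the Gabor
// bank, elliptical-neighborhood median filtering, and connected-component
// labeling.  All boundary handling is symmetric reflection (edge pixel
// included), applied by the R callers before these routines run where
// padding is needed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// smallest integer >= n whose prime factors are all in {2, 3, 5};
// keeps arma::fft2 off slow prime-length transforms
static int good_fft_size(int n) {
  for (;; n++) {
    int m = n;
    while (m % 2 == 0) m /= 2;
    while (m % 3 == 0) m /= 3;
    while (m % 5 == 0) m /= 5;
    if (m == 1) return n;
  }
}

// Linear convolution of a pre-padded real image with a list of complex
// w x w kernels.  `padded` carries (w-1)/2 reflected pixels on every
// side of the original M x N image, so cropping the full convolution at
// offset w-1 returns the same-size response aligned with the original.
// [[Rcpp::export]]
arma::cube gabor_convolve_cpp(const arma::mat& padded, const List& kernels,
                              int M, int N, int w, bool magnitude) {
  const int Mp = padded.n_rows, Np = padded.n_cols;
  if (Mp < w || Np < w) stop("padded image smaller than kernel");
  const int L1 = good_fft_size(Mp + w - 1);
  const int L2 = good_fft_size(Np + w - 1);

  arma::cx_mat A(L1, L2, arma::fill::zeros);
  A.submat(0, 0, Mp - 1, Np - 1) =
      arma::cx_mat(padded, arma::mat(Mp, Np, arma::fill::zeros));
  const arma::cx_mat FA = arma::fft2(A);

  const int nk = kernels.size();
  arma::cube out(M, N, nk);
  arma::cx_mat B(L1, L2);
  for (int k = 0; k < nk; k++) {
    arma::cx_mat ker = as<arma::cx_mat>(kernels[k]);
    if ((int)ker.n_rows != w || (int)ker.n_cols != w)
      stop("kernel %d is not %d x %d", k + 1, w, w);
    B.zeros();
    B.submat(0, 0, w - 1, w - 1) = ker;
    arma::cx_mat conv = arma::ifft2(FA % arma::fft2(B));
    arma::cx_mat same = conv.submat(w - 1, w - 1, w + M - 2, w + N - 2);
    if (magnitude) out.slice(k) = arma::abs(same);
    else           out.slice(k) = arma::real(same);
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// Median filter over an axis-aligned elliptical neighborhood with
// semi-axes long_axis/2 (columns) and minor_axis/2 (rows).  Even-sized
// neighborhoods take the mean of the two middle order statistics, the
// same convention as stats::median().
// [[Rcpp::export]]
arma::mat median_filter_ellipse_cpp(const arma::mat& img,
                                    int long_axis, int minor_axis) {
  const int M = img.n_rows, N = img.n_cols;
  const double a = long_axis / 2.0;   // column (horizontal) semi-axis
  const double b = minor_axis / 2.0;  // row (vertical) semi-axis
  const int ra = (int)std::floor(a), rb = (int)std::floor(b);
  if (ra >= N || rb >= M)
    stop("median template larger than the image");

  std::vector<int> dr, dc;
  for (int i = -rb; i <= rb; i++)
    for (int j = -ra; j <= ra; j++)
      if ((j / a) * (j / a) + (i / b) * (i / b) <= 1.0) {
        dr.push_back(i);
        dc.push_back(j);
      }
  const int n = (int)dr.size();
  std::vector<double> buf(n);

  arma::mat out(M, N);
  for (int c = 0; c < N; c++) {
    for (int r = 0; r < M; r++) {
      for (int t = 0; t < n; t++)
        buf[t] = img(reflect_idx(r + dr[t], M), reflect_idx(c + dc[t], N));
      const int h = n / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double med = buf[h];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + h);
        med = (med + lo) / 2.0;
      }
      out(r, c) = med;
    }
  }
  return out;
}

// Label connected components of a binary mask (0 = background); returns
// integer labels 1..k in first-encounter (column-major) order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int M = mask.nrow(), N = mask.ncol();
  IntegerMatrix lab(M, N);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < N; c++) {
    for (int r = 0; r < M; r++) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      next++;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * M);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % M, pc = p / M;
        for (int k = 0; k < nn; k++) {
          const int qr = pr + dr8[k], qc = pc + dc8[k];
          if (qr < 0 || qr >= M || qc < 0 || qc >= N) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * M);
          }
        }
      }
    }
  }
  return lab;
}
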