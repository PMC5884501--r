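#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// FFT of A zero-padded to P x P (A placed at the top-left corner).
static arma::cx_mat pad_fft(const arma::cx_mat& A, int P) {
  arma::cx_mat B(P, P, arma::fill::zeros);
  B.submat(0, 0, A.n_rows - 1, A.n_cols - 1) = A;
  return arma::fft2(B);
}

// Bresenham rasterization of line segments onto an n x n canvas.
// Each traversal adds `increment` to every pixel on the discrete line
// (endpoints included); intensities are clipped at 1.
// Coordinates are 0-based canvas columns (x) and rows (y).
// [[Rcpp::export]]
NumericMatrix render_accumulate_cpp(IntegerVector x0, IntegerVector y0,
                                    IntegerVector x1, IntegerVector y1,
                                    int n, double increment) {
  NumericMatrix img(n, n);
  int nseg = x0.size();
  for (int s = 0; s < nseg; ++s) {
    int xa = x0[s], ya = y0[s], xb = x1[s], yb = y1[s];
    int dx = std::abs(xb - xa), sx = xa < xb ? 1 : -1;
    int dy = -std::abs(yb - ya), sy = ya < yb ? 1 : -1;
    int err = dx + dy;
    int x = xa, y = ya;
    while (true) {
      if (x >= 0 && x < n && y >= 0 && y < n) {
        double v = img(y, x) + increment;
        img(y, x) = v > 1.0 ? 1.0 : v;
      }
      if (x == xb && y == yb) break;
      int e2 = 2 * err;
      if (e2 >= dy) { err += dy; x += sx; }
      if (e2 <= dx) { err += dx; y += sy; }
    }
  }
  return img;
}

// Magnitude of the linear convolution of a square image with one complex
// kernel, cropped to the image size ("same" placement). `hw` is the kernel
// half-width (kernel is (2*hw+1) square); `pad` the FFT size, chosen in R
// so that pad >= N + 2*hw (full linear convolution, no wrap-around).
// [[Rcpp::export]]
arma::mat gabor_response_cpp(const arma::mat& img, const arma::cx_mat& kernel,
                             int hw, int pad) {
  int N = img.n_rows;
  arma::cx_mat imgc(img, arma::mat(img.n_rows, img.n_cols, arma::fill::zeros));
  arma::cx_mat resp = arma::ifft2(pad_fft(imgc, pad) % pad_fft(kernel, pad));
  return arma::abs(resp.submat(hw, hw, hw + N - 1, hw + N - 1));
}

// Batch texture-feature extraction: for each image, convolve with every
// kernel and return (mean, population sd) of each magnitude response.
// Kernel FFTs are computed once; image FFTs once per distinct pad size.
// Output: n_images x (2 * n_kernels), (mean, sd) adjacent per kernel.
// [[Rcpp::export]]
arma::mat gabor_features_cpp(List images, List kernels,
                             IntegerVector hw, IntegerVector pad) {
  int n_img = images.size();
  int K = kernels.size();
  std::vector<arma::cx_mat> kF(K);
  for (int k = 0; k < K; ++k) {
    arma::cx_mat ker = as<arma::cx_mat>(kernels[k]);
    kF[k] = pad_fft(ker, pad[k]);
  }
  arma::mat out(n_img, 2 * K);
  for (int i = 0; i < n_img; ++i) {
    checkUserInterrupt();
    arma::mat img = as<arma::mat>(images[i]);
    int N = img.n_rows;
    arma::cx_mat imgc(img, arma::mat(N, N, arma::fill::zeros));
    std::map<int, arma::cx_mat> imgF;
    for (int k = 0; k < K; ++k) {
      int P = pad[k];
      std::map<int, arma::cx_mat>::iterator it = imgF.find(P);
      if (it == imgF.end())
        it = imgF.insert(std::make_pair(P, pad_fft(imgc, P))).first;
      arma::cx_mat resp = arma::ifft2(it->second % kF[k]);
      int h = hw[k];
      arma::vec mag = arma::vectorise(
        arma::abs(resp.submat(h, h, h + N - 1, h + N - 1)));
      double m = arma::mean(mag);
      out(i, 2 * k) = m;
      out(i, 2 * k + 1) = std::sqrt(arma::mean(arma::square(mag - m)));
    }
  }
  return out;
}
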