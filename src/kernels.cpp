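#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout conventions shared by all kernels:
//  * image tensors are arma::cube (rows H, cols W, slices = channels);
//  * im2col rows index output pixels column-major (r + Ho*c);
//  * im2col cols index kernel taps di + kh*dj + kh*kw*channel;
//  * conv weights are (kh*kw*Cin) x Cout matrices, one bias per output channel.

static arma::mat im2col(const arma::cube& x, int kh, int kw) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = H - kh + 1, Wo = W - kw + 1;
  arma::mat out(static_cast<arma::uword>(Ho) * Wo,
                static_cast<arma::uword>(kh) * kw * C);
  for (int ch = 0; ch < C; ++ch)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        arma::uword colidx = di + kh * dj + kh * kw * ch;
        out.col(colidx) = arma::vectorise(
          x.slice(ch).submat(di, dj, di + Ho - 1, dj + Wo - 1));
      }
  return out;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int kh, int kw) {
  int Ho = H - kh + 1, Wo = W - kw + 1;
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        arma::uword colidx = di + kh * dj + kh * kw * ch;
        arma::mat patch(const_cast<double*>(cols.colptr(colidx)), Ho, Wo,
                        false, true);
        x.slice(ch).submat(di, dj, di + Ho - 1, dj + Wo - 1) += patch;
      }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& bias, int kh, int kw) {
  int Ho = x.n_rows - kh + 1, Wo = x.n_cols - kw + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than convolution kernel");
  if (w.n_rows != static_cast<arma::uword>(kh) * kw * x.n_slices)
    stop("weight matrix does not match kernel/channel geometry");
  arma::mat y = im2col(x, kh, kw) * w;
  y.each_row() += bias.t();
  arma::cube out(Ho, Wo, w.n_cols);
  for (arma::uword c = 0; c < w.n_cols; ++c)
    out.slice(c) = arma::reshape(y.col(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List conv2d_backward(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gout, int kh, int kw) {
  int Ho = gout.n_rows, Wo = gout.n_cols, Co = gout.n_slices;
  arma::mat g(static_cast<arma::uword>(Ho) * Wo, Co);
  for (int c = 0; c < Co; ++c) g.col(c) = arma::vectorise(gout.slice(c));
  arma::mat cols = im2col(x, kh, kw);
  arma::mat gw = cols.t() * g;
  arma::vec gb = arma::sum(g, 0).t();
  arma::cube gx = col2im(g * w.t(), x.n_rows, x.n_cols, x.n_slices, kh, kw);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled cube and the within-cube linear
// index of each argmax so backward is a pure scatter.
// [[Rcpp::export]]
List maxpool2_forward(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("max pooling requires even spatial dimensions");
  int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            arma::uword lin = (2 * i + di) +
              static_cast<arma::uword>(H) * (2 * j + dj) +
              static_cast<arma::uword>(H) * W * c;
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = lin; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::cube& gout, const arma::ucube& idx,
                             int H, int W, int C) {
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < gout.n_slices; ++c)
    for (arma::uword j = 0; j < gout.n_cols; ++j)
      for (arma::uword i = 0; i < gout.n_rows; ++i)
        gx(idx(i, j, c)) += gout(i, j, c);
  return gx;
}

// Transposed 2x2 stride-2 convolution ("up-convolution"). Weight matrix is
// Cin x (4*Cout); offset block o = di + 2*dj occupies columns
// o*Cout .. (o+1)*Cout-1 and feeds output pixel (2i+di, 2j+dj).
// [[Rcpp::export]]
arma::cube upconv2_forward(const arma::cube& x, const arma::mat& w,
                           const arma::vec& bias) {
  int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  int Cout = w.n_cols / 4;
  if (w.n_rows != static_cast<arma::uword>(Cin))
    stop("up-convolution weight rows must equal input channels");
  arma::mat xm(static_cast<arma::uword>(H) * W, Cin);
  for (int c = 0; c < Cin; ++c) xm.col(c) = arma::vectorise(x.slice(c));
  arma::cube out(2 * H, 2 * W, Cout);
  for (int c = 0; c < Cout; ++c) out.slice(c).fill(bias(c));
  for (int o = 0; o < 4; ++o) {
    int di = o % 2, dj = o / 2;
    arma::mat yo = xm * w.cols(o * Cout, (o + 1) * Cout - 1);
    for (int c = 0; c < Cout; ++c) {
      arma::mat block = arma::reshape(yo.col(c), H, W);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          out(2 * i + di, 2 * j + dj, c) += block(i, j);
    }
  }
  return out;
}

// [[Rcpp::export]]
List upconv2_backward(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gout) {
  int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  int Cout = gout.n_slices;
  arma::mat xm(static_cast<arma::uword>(H) * W, Cin);
  for (int c = 0; c < Cin; ++c) xm.col(c) = arma::vectorise(x.slice(c));
  arma::mat gw(Cin, 4 * Cout, arma::fill::zeros);
  arma::mat gxm(static_cast<arma::uword>(H) * W, Cin, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int c = 0; c < Cout; ++c) gb(c) = arma::accu(gout.slice(c));
  for (int o = 0; o < 4; ++o) {
    int di = o % 2, dj = o / 2;
    arma::mat go(static_cast<arma::uword>(H) * W, Cout);
    for (int c = 0; c < Cout; ++c) {
      arma::mat block(H, W);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          block(i, j) = gout(2 * i + di, 2 * j + dj, c);
      go.col(c) = arma::vectorise(block);
    }
    gw.cols(o * Cout, (o + 1) * Cout - 1) = xm.t() * go;
    gxm += go * w.cols(o * Cout, (o + 1) * Cout - 1).t();
  }
  arma::cube gx(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    gx.slice(c) = arma::reshape(gxm.col(c), H, W);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
arma::cube relu_cube(arma::cube x) {
  x.transform([](double v) { return v > 0 ? v : 0.0; });
  return x;
}

// Connected components of a 3D binary volume under 26- (default) or
// 6-connectivity. Labels are contiguous from 1 in discovery (scan) order.
// [[Rcpp::export]]
IntegerVector label_components_26(const LogicalVector& mask,
                                  const IntegerVector& dims, int conn) {
  int H = dims[0], W = dims[1], D = dims[2];
  IntegerVector labels(mask.size(), 0);
  std::vector<long> stack;
  int next = 0;
  for (long start = 0; start < (long)mask.size(); ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next;
    labels[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i = v % H, j = (v / H) % W, k = v / ((long)H * W);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            if (conn == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
              continue;
            int ni = i + di, nj = j + dj, nk = k + dk;
            if (ni < 0 || nj < 0 || nk < 0 || ni >= H || nj >= W || nk >= D)
              continue;
            long nv = ni + (long)H * nj + (long)H * W * nk;
            if (mask[nv] && !labels[nv]) {
              labels[nv] = next;
              stack.push_back(nv);
            }
          }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Per-slice binary median filter with a win x win window (win odd).
// Border pixels use edge replication; the median of 0/1 values is the
// majority vote over the window.
// [[Rcpp::export]]
IntegerVector binary_median_slices(const IntegerVector& mask,
                                   const IntegerVector& dims, int win) {
  int H = dims[0], W = dims[1], D = dims[2];
  int r = win / 2, half = (win * win) / 2;
  IntegerVector out(mask.size());
  for (int k = 0; k < D; ++k)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int count = 0;
        for (int dj = -r; dj <= r; ++dj)
          for (int di = -r; di <= r; ++di) {
            int ni = std::min(std::max(i + di, 0), H - 1);
            int nj = std::min(std::max(j + dj, 0), W - 1);
            count += mask[ni + (long)H * nj + (long)H * W * k];
          }
        out[i + (long)H * j + (long)H * W * k] = count > half ? 1 : 0;
      }
  out.attr("dim") = dims;
  return out;
}
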