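// Hot paths of the neural-network engine: 3x3 same-padding convolution and
// 2x2/stride-2 max pooling, forward and backward. Tensors arrive as
// (N*H*W) x C matrices (sample-major, row-major pixels, channels in
// columns); kernels as Cin x Cout x 9 cubes, offset slices ordered
// (dr, dc) in {-1,0,1}^2 row-major. Arithmetic runs in single precision:
// convolution stacks are robust to it, and it doubles GEMM throughput on
// one CPU core.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::fvec;

// copy the (dr, dc)-shifted view of X into G (zero outside the image)
static void gatherOffset(const fmat& X, fmat& G,
                         int N, int H, int W, int dr, int dc) {
    const int P = H * W;
    G.zeros();
    const int clo = std::max(0, -dc), chi = std::min(W, W - dc);
    if (chi <= clo) return;
    for (int n = 0; n < N; ++n) {
        for (int r = 0; r < H; ++r) {
            const int rr = r + dr;
            if (rr < 0 || rr >= H) continue;
            const int dst = n * P + r * W + clo;
            const int src = n * P + rr * W + clo + dc;
            G.rows(dst, dst + (chi - clo) - 1) =
                X.rows(src, src + (chi - clo) - 1);
        }
    }
}

// accumulate rows of T (laid out at output positions) back onto the
// (dr, dc)-shifted source positions of dX
static void scatterOffset(fmat& dX, const fmat& T,
                          int N, int H, int W, int dr, int dc) {
    const int P = H * W;
    const int clo = std::max(0, -dc), chi = std::min(W, W - dc);
    if (chi <= clo) return;
    for (int n = 0; n < N; ++n) {
        for (int r = 0; r < H; ++r) {
            const int rr = r + dr;
            if (rr < 0 || rr >= H) continue;
            const int dst = n * P + r * W + clo;
            const int src = n * P + rr * W + clo + dc;
            dX.rows(src, src + (chi - clo) - 1) +=
                T.rows(dst, dst + (chi - clo) - 1);
        }
    }
}

// [[Rcpp::export]]
arma::mat nn_conv_fwd_cpp(const arma::mat& X, const arma::cube& W,
                          const arma::vec& b, int N, int H, int Wd,
                          bool relu) {
    const fmat Xf = arma::conv_to<fmat>::from(X);
    const fcube Wf = arma::conv_to<fcube>::from(W);
    fmat Y(Xf.n_rows, Wf.n_cols);
    Y.each_row() = arma::conv_to<fvec>::from(b).t();
    fmat G(Xf.n_rows, Xf.n_cols);
    int o = 0;
    for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
            gatherOffset(Xf, G, N, H, Wd, dr, dc);
            Y += G * Wf.slice(o);
            ++o;
        }
    if (relu) Y.clamp(0.0f, arma::fdatum::inf);
    return arma::conv_to<arma::mat>::from(Y);
}

// [[Rcpp::export]]
List nn_conv_bwd_cpp(const arma::mat& X, const arma::mat& Ypost,
                     const arma::cube& W, const arma::mat& dY,
                     int N, int H, int Wd) {
    const fmat Xf = arma::conv_to<fmat>::from(X);
    const fcube Wf = arma::conv_to<fcube>::from(W);
    fmat dYf = arma::conv_to<fmat>::from(dY);
    dYf %= arma::conv_to<fmat>::from(Ypost > 0);   // ReLU mask
    fcube dW(Wf.n_rows, Wf.n_cols, 9);
    fvec db = arma::sum(dYf, 0).t();
    fmat dX(Xf.n_rows, Xf.n_cols, arma::fill::zeros);
    fmat G(Xf.n_rows, Xf.n_cols);
    int o = 0;
    for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
            gatherOffset(Xf, G, N, H, Wd, dr, dc);
            dW.slice(o) = G.t() * dYf;
            scatterOffset(dX, dYf * Wf.slice(o).t(), N, H, Wd, dr, dc);
            ++o;
        }
    return List::create(_["dX"] = arma::conv_to<arma::mat>::from(dX),
                        _["dW"] = arma::conv_to<arma::cube>::from(dW),
                        _["db"] = arma::conv_to<arma::vec>::from(db));
}

// [[Rcpp::export]]
List nn_pool_fwd_cpp(const arma::mat& X, int N, int H, int W) {
    const int H2 = H / 2, W2 = W / 2, C = X.n_cols;
    const int P = H * W, P2 = H2 * W2;
    arma::mat Y(N * P2, C);
    arma::imat arg(N * P2, C);
    for (int n = 0; n < N; ++n)
        for (int r2 = 0; r2 < H2; ++r2)
            for (int c2 = 0; c2 < W2; ++c2) {
                const int outr = n * P2 + r2 * W2 + c2;
                const int base = n * P + 2 * r2 * W + 2 * c2;
                const int idx[4] = {base, base + 1, base + W, base + W + 1};
                for (int ch = 0; ch < C; ++ch) {
                    double best = X(idx[0], ch);
                    int a = 0;
                    for (int k = 1; k < 4; ++k) {
                        const double v = X(idx[k], ch);
                        if (v > best) { best = v; a = k; }
                    }
                    Y(outr, ch) = best;
                    arg(outr, ch) = a;
                }
            }
    return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::mat nn_pool_bwd_cpp(const arma::mat& dY, const arma::imat& arg,
                          int N, int H, int W) {
    const int H2 = H / 2, W2 = W / 2, C = dY.n_cols;
    const int P = H * W, P2 = H2 * W2;
    arma::mat dX(N * P, C, arma::fill::zeros);
    for (int n = 0; n < N; ++n)
        for (int r2 = 0; r2 < H2; ++r2)
            for (int c2 = 0; c2 < W2; ++c2) {
                const int outr = n * P2 + r2 * W2 + c2;
                const int base = n * P + 2 * r2 * W + 2 * c2;
                const int idx[4] = {base, base + 1, base + W, base + W + 1};
                for (int ch = 0; ch < C; ++ch)
                    dX(idx[arg(outr, ch)], ch) += dY(outr, ch);
            }
    return dX;
}
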