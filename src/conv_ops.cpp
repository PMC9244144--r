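// Minimal conv/pool kernels for the RISE networks.
// Layout follows R column-major arrays: feature maps are [H, W, C, N],
// conv weights [k, k, Cin, Cout].  Convolutions are stride-1 with
// "same" zero padding (k odd); pooling supports arbitrary size/stride/pad.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather the k x k x C neighbourhood of every output pixel into a
// (H*W) x (k*k*C) matrix.  Column order di + k*dj + k*k*c matches the
// column-major flattening of the [k, k, Cin, Cout] weight array, so the
// convolution is a single matrix product.
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& M) {
    const int pad = k / 2;
    for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int dj = 0; dj < k; ++dj) {
            for (int di = 0; di < k; ++di) {
                double* Mcol = M.colptr(di + k * dj + k * k * c);
                for (int j = 0; j < W; ++j) {
                    const int sj = j + dj - pad;
                    if (sj < 0 || sj >= W) {
                        for (int i = 0; i < H; ++i) Mcol[i + H * j] = 0.0;
                        continue;
                    }
                    const double* xcol = xc + (size_t)H * sj;
                    for (int i = 0; i < H; ++i) {
                        const int si = i + di - pad;
                        Mcol[i + H * j] = (si < 0 || si >= H) ? 0.0 : xcol[si];
                    }
                }
            }
        }
    }
}

// Scatter-add: exact adjoint of im2col.
static void col2im_add(const arma::mat& M, int H, int W, int C, int k, double* dx) {
    const int pad = k / 2;
    for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int dj = 0; dj < k; ++dj) {
            for (int di = 0; di < k; ++di) {
                const double* Mcol = M.colptr(di + k * dj + k * k * c);
                for (int j = 0; j < W; ++j) {
                    const int sj = j + dj - pad;
                    if (sj < 0 || sj >= W) continue;
                    double* xcol = xc + (size_t)H * sj;
                    for (int i = 0; i < H; ++i) {
                        const int si = i + di - pad;
                        if (si >= 0 && si < H) xcol[si] += Mcol[i + H * j];
                    }
                }
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
    IntegerVector xd = x.attr("dim");
    IntegerVector wd = w.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int k = wd[0], Cout = wd[3];
    if (wd[1] != k) stop("conv kernel must be square");
    if (wd[2] != C) stop("conv weight input channels do not match input");
    NumericVector out((R_xlen_t)H * W * Cout * N);
    out.attr("dim") = IntegerVector::create(H, W, Cout, N);
    arma::mat Wm(w.begin(), k * k * C, Cout, false, true);
    arma::mat M(H * W, k * k * C);
    for (int n = 0; n < N; ++n) {
        im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, M);
        arma::mat O(out.begin() + (size_t)H * W * Cout * n, H * W, Cout, false, true);
        O = M * Wm;
        for (int co = 0; co < Cout; ++co) O.col(co) += b[co];
    }
    return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gout) {
    IntegerVector xd = x.attr("dim");
    IntegerVector wd = w.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int k = wd[0], Cout = wd[3];
    NumericVector dx((R_xlen_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    NumericVector dw((R_xlen_t)k * k * C * Cout);
    dw.attr("dim") = IntegerVector::create(k, k, C, Cout);
    NumericVector db(Cout);
    arma::mat Wm(w.begin(), k * k * C, Cout, false, true);
    arma::mat dWm(dw.begin(), k * k * C, Cout, false, true);
    arma::vec dbv(db.begin(), Cout, false, true);
    arma::mat M(H * W, k * k * C);
    arma::mat dM(H * W, k * k * C);
    for (int n = 0; n < N; ++n) {
        im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, M);
        arma::mat G(gout.begin() + (size_t)H * W * Cout * n, H * W, Cout, false, true);
        dWm += M.t() * G;
        dbv += arma::sum(G, 0).t();
        dM = G * Wm.t();
        col2im_add(dM, H, W, C, k, dx.begin() + (size_t)H * W * C * n);
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int size, int stride, int pad) {
    IntegerVector xd = x.attr("dim");
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int Ho = (H + 2 * pad - size) / stride + 1;
    const int Wo = (W + 2 * pad - size) / stride + 1;
    NumericVector out((R_xlen_t)Ho * Wo * C * N);
    out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
    IntegerVector idx(out.size());  // 0-based linear index into x of each max
    double* op = out.begin();
    int* ip = idx.begin();
    const double* xp = x.begin();
    size_t m = 0;
    for (int n = 0; n < N; ++n) {
        for (int c = 0; c < C; ++c) {
            const size_t base = (size_t)H * W * ((size_t)C * n + c);
            for (int jo = 0; jo < Wo; ++jo) {
                for (int io = 0; io < Ho; ++io) {
                    double best = -HUGE_VAL;
                    size_t besti = base;  // fallback; windows always hit >=1 pixel here
                    for (int dj = 0; dj < size; ++dj) {
                        const int sj = jo * stride + dj - pad;
                        if (sj < 0 || sj >= W) continue;
                        for (int di = 0; di < size; ++di) {
                            const int si = io * stride + di - pad;
                            if (si < 0 || si >= H) continue;
                            const double v = xp[base + si + (size_t)H * sj];
                            if (v > best) { best = v; besti = base + si + (size_t)H * sj; }
                        }
                    }
                    // column-major order of out matches loop nesting (io fastest)
                    const size_t o = (size_t)io + (size_t)Ho * jo +
                        (size_t)Ho * Wo * ((size_t)C * n + c);
                    op[o] = best;
                    ip[o] = (int)besti;
                    ++m;
                }
            }
        }
    }
    (void)m;
    return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector gout, IntegerVector xdim) {
    NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
    dx.attr("dim") = xdim;
    double* dp = dx.begin();
    const double* gp = gout.begin();
    const int* ip = idx.begin();
    const R_xlen_t m = gout.size();
    for (R_xlen_t t = 0; t < m; ++t) dp[ip[t]] += gp[t];
    return dx;
}
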