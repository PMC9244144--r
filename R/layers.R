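# Internal batched layer primitives.  Feature maps are [H, W, C, N] arrays
# (column-major), conv weights [k, k, Cin, Cout]; convolutions are stride-1
# same-padding (compiled, see src/conv_ops.cpp).  Every forward returns what
# its backward needs; backwards return dx plus parameter gradients.

.conv_fwd <- function(x, p) conv2d_fwd_cpp(x, p$w, p$b)
.conv_bwd <- function(x, p, g) conv2d_bwd_cpp(x, p$w, g)

.relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}
.relu_bwd <- function(g, mask) g * mask

.pool2_fwd <- function(x) maxpool_fwd_cpp(x, 2L, 2L, 0L)
.pool3s1_fwd <- function(x) maxpool_fwd_cpp(x, 3L, 1L, 1L)
.pool_bwd <- function(g, idx, xdim) maxpool_bwd_cpp(idx, g, as.integer(xdim))

.dropout_fwd <- function(x, rate) {
  # inverted dropout; draws from the current RNG stream
  mask <- (array(runif(length(x)), dim(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}

.dense_fwd <- function(X, p) sweep(X %*% p$w, 2L, p$b, "+")
.dense_bwd <- function(X, p, g) {
  list(dx = g %*% t(p$w), dw = crossprod(X, g), db = colSums(g))
}

# Global average pool [H,W,C,N] -> N x C, and channel-wise sum of the same
# shape (used in the SE backward).
.gap <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}
.chansum <- function(x) {
  d <- dim(x)
  t(matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# Expand an N x C per-channel matrix to [H, W, C, N] for broadcasting.
.bcast_ch <- function(e, H, W) {
  array(rep(as.vector(t(e)), each = H * W), dim = c(H, W, ncol(e), nrow(e)))
}

.concat_ch <- function(parts) {
  d <- dim(parts[[1]])
  Cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , at + seq_len(cp), ] <- p
    at <- at + cp
  }
  out
}

.split_ch <- function(g, Cs) {
  at <- 0L
  out <- vector("list", length(Cs))
  for (i in seq_along(Cs)) {
    out[[i]] <- g[, , at + seq_len(Cs[i]), , drop = FALSE]
    at <- at + Cs[i]
  }
  out
}

# He-scaled initializers (draw from the current RNG stream).
.init_conv <- function(k, cin, cout) {
  list(w = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout)),
       b = numeric(cout))
}
.init_dense <- function(cin, cout) {
  list(w = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}
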