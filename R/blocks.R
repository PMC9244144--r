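# Squeeze-and-excitation, inception and RISE block operations.  The
# exported functions operate on a single feature map ([H, W, C] array) with
# explicit weights, so their arithmetic can be checked against independent
# loop implementations; the batched internals below them are what the
# training loop uses.

as_fmap4 <- function(f) {
  d <- dim(f)
  if (length(d) == 3L) array(f, c(d, 1L))
  else if (length(d) == 4L) f
  else value_error("feature maps must be [H, W, C] or [H, W, C, N] arrays")
}

#' Squeeze: per-channel global average pooling
#'
#' Reduces each channel of a feature map to its spatial mean
#' \eqn{S_n = \frac{1}{HW}\sum_i\sum_j I_n(i,j)}, the descriptor that drives
#' channel recalibration.
#'
#' @param f `[H, W, C]` numeric array with `H, W >= 1`.
#' @return Numeric vector of length `C`.
#' @export
squeeze <- function(f) {
  f <- as_fmap4(f)
  if (dim(f)[1] < 1 || dim(f)[2] < 1 || dim(f)[1] * dim(f)[2] == 0)
    value_error("feature map has zero spatial extent")
  as.numeric(.gap(f)[1, ])
}

#' Initialise excitation weights
#'
#' Two affine maps `C -> C/g -> C` (with biases); the reduction ratio `g`
#' bottlenecks the channel descriptor for parameter economy and
#' generalization.
#'
#' @param C Channel count; must be divisible by `g`.
#' @param g Reduction ratio (the paper's best value is 8).
#' @param seed Integer seed.
#' @return List with `w1` (`C x C/g`), `b1`, `w2` (`C/g x C`), `b2`.
#' @export
init_excite <- function(C, g = 8L, seed = 1L) {
  if (C %% g != 0)
    config_error(sprintf("channel count %d not divisible by se ratio g = %d", C, g))
  with_seed(seed, {
    w1 <- .init_dense(C, C %/% g)
    w2 <- .init_dense(C %/% g, C)
  })
  list(w1 = w1$w, b1 = w1$b, w2 = w2$w, b2 = w2$b)
}

#' Excite: bottlenecked channel gating
#'
#' Maps a squeezed channel descriptor through `C -> C/g` (rectifier) and
#' back `C/g -> C` (sigmoid), yielding one attention weight per channel,
#' each strictly in (0, 1).
#'
#' @param s Numeric channel descriptor of length `C`.
#' @param g Reduction ratio; `C` must be divisible by `g`.
#' @param weights Excitation parameters as from [init_excite()].
#' @return Numeric vector of length `C` with values in (0, 1).
#' @export
excite <- function(s, g, weights) {
  C <- length(s)
  if (C %% g != 0)
    config_error(sprintf("channel count %d not divisible by se ratio g = %d", C, g))
  if (!identical(dim(weights$w1), c(C, C %/% as.integer(g))))
    config_error("excitation weights do not match channel count and g")
  z1 <- pmax(as.numeric(s %*% weights$w1) + weights$b1, 0)
  plogis(as.numeric(z1 %*% weights$w2) + weights$b2)
}

#' Scale: per-channel recalibration
#'
#' Multiplies every channel of a feature map by its excitation weight,
#' preserving shape.
#'
#' @param f `[H, W, C]` numeric array.
#' @param e Numeric vector of length `C`.
#' @return Array of the same shape as `f`.
#' @export
se_scale <- function(f, e) {
  d <- dim(f)
  C <- if (length(d) == 3L) d[3] else d[3]
  if (length(e) != C)
    value_error("excitation vector length must equal the channel count")
  if (length(d) == 3L) f * .bcast_ch(matrix(e, 1L), d[1], d[2])[, , , 1]
  else f * .bcast_ch(matrix(e, 1L), d[1], d[2])
}

#' Initialise inception block weights
#'
#' @param c_in Input channel count.
#' @param out_channels Output channel count, divisible by 4 (equal-width
#'   paths).
#' @param seed Integer seed.
#' @return Parameter list with one conv per path stage (`p1`, `p2a`, `p2b`,
#'   `p3a`, `p3b`, `p4`).
#' @export
init_inception <- function(c_in, out_channels, seed = 1L) {
  if (out_channels %% 4 != 0)
    config_error(sprintf("inception out_channels %d not divisible by 4", out_channels))
  q <- out_channels %/% 4L
  with_seed(seed, list(
    p1 = .init_conv(1L, c_in, q),
    p2a = .init_conv(1L, c_in, q), p2b = .init_conv(3L, q, q),
    p3a = .init_conv(1L, c_in, q), p3b = .init_conv(5L, q, q),
    p4 = .init_conv(1L, c_in, q)))
}

# Batched inception forward with cache.  Paths: 1x1 | 1x1-3x3 | 1x1-5x5 |
# 3x3 maxpool - 1x1; each path contributes out_channels/4 maps, concatenated
# in path order; ReLU after every convolution; spatial dims preserved.
.inception_fwd <- function(x, p) {
  r1 <- .relu_fwd(.conv_fwd(x, p$p1))
  r2a <- .relu_fwd(.conv_fwd(x, p$p2a))
  r2b <- .relu_fwd(.conv_fwd(r2a$out, p$p2b))
  r3a <- .relu_fwd(.conv_fwd(x, p$p3a))
  r3b <- .relu_fwd(.conv_fwd(r3a$out, p$p3b))
  mp <- .pool3s1_fwd(x)
  r4 <- .relu_fwd(.conv_fwd(mp$out, p$p4))
  out <- .concat_ch(list(r1$out, r2b$out, r3b$out, r4$out))
  list(out = out,
       cache = list(x = x, r1 = r1, r2a = r2a, r2b = r2b, r3a = r3a,
                    r3b = r3b, mp_idx = mp$idx, mp_out = mp$out, r4 = r4))
}

.inception_bwd <- function(g, cache, p) {
  q <- dim(cache$r1$out)[3]
  gs <- .split_ch(g, rep(q, 4L))
  x <- cache$x
  # path 1
  g1 <- .relu_bwd(gs[[1]], cache$r1$mask)
  b1 <- .conv_bwd(x, p$p1, g1)
  # path 2
  g2b <- .relu_bwd(gs[[2]], cache$r2b$mask)
  b2b <- .conv_bwd(cache$r2a$out, p$p2b, g2b)
  g2a <- .relu_bwd(b2b$dx, cache$r2a$mask)
  b2a <- .conv_bwd(x, p$p2a, g2a)
  # path 3
  g3b <- .relu_bwd(gs[[3]], cache$r3b$mask)
  b3b <- .conv_bwd(cache$r3a$out, p$p3b, g3b)
  g3a <- .relu_bwd(b3b$dx, cache$r3a$mask)
  b3a <- .conv_bwd(x, p$p3a, g3a)
  # path 4
  g4 <- .relu_bwd(gs[[4]], cache$r4$mask)
  b4 <- .conv_bwd(cache$mp_out, p$p4, g4)
  dmp <- .pool_bwd(b4$dx, cache$mp_idx, dim(x))
  dx <- b1$dx + b2a$dx + b3a$dx + dmp
  list(dx = dx,
       grads = list(p1 = list(w = b1$dw, b = b1$db),
                    p2a = list(w = b2a$dw, b = b2a$db),
                    p2b = list(w = b2b$dw, b = b2b$db),
                    p3a = list(w = b3a$dw, b = b3a$db),
                    p3b = list(w = b3b$dw, b = b3b$db),
                    p4 = list(w = b4$dw, b = b4$db)))
}

#' Inception transform of a feature map
#'
#' Four parallel convolution paths (1x1; 1x1 then 3x3; 1x1 then 5x5; 3x3
#' max-pool then 1x1) of equal width, concatenated along channels in path
#' order.  Spatial dimensions are preserved (same padding).
#'
#' @param f `[H, W, C]` numeric array.
#' @param params Weights from [init_inception()].
#' @return `[H, W, out_channels]` array.
#' @export
inception_block <- function(f, params) {
  single <- length(dim(f)) == 3L
  out <- .inception_fwd(as_fmap4(f), params)$out
  if (single) array(out, dim(out)[1:3]) else out
}

# SE forward/backward over a batch.
.se_fwd <- function(x, p) {
  d <- dim(x)
  s <- .gap(x)
  z1 <- sweep(s %*% p$w1, 2L, p$b1, "+")
  a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% p$w2, 2L, p$b2, "+")
  e <- plogis(z2)
  list(out = x * .bcast_ch(e, d[1], d[2]),
       cache = list(x = x, s = s, z1 = z1, a1 = a1, e = e))
}

.se_bwd <- function(g, cache, p) {
  x <- cache$x
  d <- dim(x)
  dx1 <- g * .bcast_ch(cache$e, d[1], d[2])
  de <- .chansum(g * x)
  dz2 <- de * cache$e * (1 - cache$e)
  da1 <- dz2 %*% t(p$w2)
  dz1 <- da1 * (cache$z1 > 0)
  ds <- dz1 %*% t(p$w1)
  dx2 <- .bcast_ch(ds, d[1], d[2]) / (d[1] * d[2])
  list(dx = dx1 + dx2,
       grads = list(w1 = crossprod(cache$s, dz1), b1 = colSums(dz1),
                    w2 = crossprod(cache$a1, dz2), b2 = colSums(dz2)))
}

#' Initialise a RISE block's weights
#'
#' @param c_in,c_out Input and output channel counts.
#' @param g SE reduction ratio.
#' @param use_se,use_skip,use_inception Ablation toggles: replace the
#'   inception transform by a single 3x3 convolution, drop the SE
#'   recalibration, or drop the residual addition.
#' @param seed Integer seed.
#' @return Parameter list with `main` (inception or conv weights), `se`
#'   (or NULL) and `proj` (1x1 projection conv when `c_in != c_out` and the
#'   skip is active, else NULL).
#' @export
init_rise_block <- function(c_in, c_out, g = 8L, use_se = TRUE,
                            use_skip = TRUE, use_inception = TRUE, seed = 1L) {
  if (use_se && c_out %% g != 0)
    config_error(sprintf("block channels %d not divisible by se ratio g = %d", c_out, g))
  seeds <- derive_seeds(seed, 3L)
  main <- if (use_inception) init_inception(c_in, c_out, seeds[1])
          else with_seed(seeds[1], .init_conv(3L, c_in, c_out))
  se <- if (use_se) init_excite(c_out, g, seeds[2]) else NULL
  proj <- if (use_skip && c_in != c_out)
    with_seed(seeds[3], .init_conv(1L, c_in, c_out)) else NULL
  list(main = main, se = se, proj = proj)
}

.rise_fwd <- function(x, bp, use_se, use_skip, use_inception) {
  if (use_inception) {
    main <- .inception_fwd(x, bp$main)
  } else {
    cv <- .conv_fwd(x, bp$main)
    rl <- .relu_fwd(cv)
    main <- list(out = rl$out, cache = list(x = x, mask = rl$mask))
  }
  branch <- main$out
  se <- NULL
  if (use_se) {
    se <- .se_fwd(branch, bp$se)
    branch <- se$out
  }
  out <- branch
  if (use_skip) {
    sk <- if (is.null(bp$proj)) x else .conv_fwd(x, bp$proj)
    out <- out + sk
  }
  list(out = out,
       cache = list(x = x, main = main$cache, se = if (use_se) se$cache))
}

.rise_bwd <- function(g, cache, bp, use_se, use_skip, use_inception) {
  grads <- list(main = NULL, se = NULL, proj = NULL)
  dx_skip <- NULL
  if (use_skip) {
    if (is.null(bp$proj)) dx_skip <- g
    else {
      bpj <- .conv_bwd(cache$x, bp$proj, g)
      dx_skip <- bpj$dx
      grads$proj <- list(w = bpj$dw, b = bpj$db)
    }
  }
  gb <- g
  if (use_se) {
    sb <- .se_bwd(gb, cache$se, bp$se)
    gb <- sb$dx
    grads$se <- sb$grads
  }
  if (use_inception) {
    mb <- .inception_bwd(gb, cache$main, bp$main)
    dx <- mb$dx
    grads$main <- mb$grads
  } else {
    gm <- .relu_bwd(gb, cache$main$mask)
    cb <- .conv_bwd(cache$main$x, bp$main, gm)
    dx <- cb$dx
    grads$main <- list(w = cb$dw, b = cb$db)
  }
  if (!is.null(dx_skip)) dx <- dx + dx_skip
  list(dx = dx, grads = grads)
}

#' Apply one RISE block to a feature map
#'
#' The composite unit: inception transform, SE channel recalibration, then
#' residual addition of the block input (through a 1x1 projection when the
#' channel counts differ).  The ablation toggles reduce the block to its
#' standalone counterparts; with all three off it is a single 3x3
#' convolution (plus rectifier).
#'
#' @param f `[H, W, C]` numeric array.
#' @param params Weights from [init_rise_block()] (built with matching
#'   toggles).
#' @param use_se,use_skip,use_inception Ablation toggles.
#' @return `[H, W, c_out]` array; spatial dimensions preserved.
#' @export
rise_block <- function(f, params, use_se = TRUE, use_skip = TRUE,
                       use_inception = TRUE) {
  single <- length(dim(f)) == 3L
  out <- .rise_fwd(as_fmap4(f), params, use_se, use_skip, use_inception)$out
  if (single) array(out, dim(out)[1:3]) else out
}
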