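#' Architecture configuration for the RISE networks
#'
#' Collects every architecture hyperparameter.  The canonical published
#' configuration is 6 RISE blocks with SE ratio `g = 8`, a 512-unit dense
#' layer and a 4-way sigmoid (classifier) or 3-way linear (regressor) head;
#' stem depth/width, per-block channel widths and inter-block downsampling
#' are this package's defaults, all overridable.  The spatial plan is:
#' one 2x2 max-pool per stem stage and one after every second RISE block,
#' then global average pooling into the dense head (so any remaining
#' spatial size is admissible).
#'
#' @param input_size Side length of the (square) network input.
#' @param stem_channels,stem_stages Stem width and number of
#'   conv-dropout-pool stages.
#' @param dropout_rate Stem dropout rate in `[0, 1)` (train time only).
#' @param n_rise_blocks Number of stacked RISE blocks (published value 6).
#' @param block_channels Output channels per block, length
#'   `n_rise_blocks`; default a doubling ladder capped at 256.
#' @param se_ratio SE reduction ratio `g` (published best value 8); every
#'   block channel count must be divisible by it when `use_se`.
#' @param use_se,use_skip,use_inception Ablation toggles (all TRUE for the
#'   full RISE block).
#' @param n_classes Classifier head width (4: motion, chemical shift,
#'   radio-frequency, normal).
#' @param n_severities Regressor head width (3 artifact severities).
#' @param dense_units Width of the penultimate dense layer (published 512).
#' @return Object of class `rise_config`.
#' @examples
#' cfg <- rise_config(input_size = 64, stem_channels = 8,
#'                    block_channels = c(8, 16, 16, 32, 32, 32))
#' @export
rise_config <- function(input_size = 512L, stem_channels = 32L,
                        stem_stages = 2L, dropout_rate = 0.25,
                        n_rise_blocks = 6L, block_channels = NULL,
                        se_ratio = 8L, use_se = TRUE, use_skip = TRUE,
                        use_inception = TRUE, n_classes = 4L,
                        n_severities = 3L, dense_units = 512L) {
  if (!is_count(input_size) || input_size < 8)
    config_error("`input_size` must be a positive integer >= 8")
  if (!is_count(stem_channels) || !is_count(stem_stages))
    config_error("`stem_channels` and `stem_stages` must be positive integers")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    config_error("`dropout_rate` must be in [0, 1)")
  if (!is_count(n_rise_blocks))
    config_error("`n_rise_blocks` must be a positive integer")
  if (is.null(block_channels)) {
    block_channels <- pmin(stem_channels * 2^(seq_len(n_rise_blocks) - 1), 256L)
  }
  if (length(block_channels) != n_rise_blocks)
    config_error("`block_channels` must have one entry per RISE block")
  if (!is_count(se_ratio))
    config_error("`se_ratio` must be a positive integer")
  if (use_se && any(block_channels %% se_ratio != 0))
    config_error(sprintf(
      "every entry of `block_channels` (%s) must be divisible by `se_ratio` g = %d when SE is enabled",
      paste(block_channels, collapse = ", "), se_ratio))
  if (use_inception && any(block_channels %% 4 != 0))
    config_error("every entry of `block_channels` must be divisible by 4 when the inception transform is enabled (equal-width paths)")
  n_pools <- stem_stages + n_rise_blocks %/% 2
  if (input_size %/% 2^n_pools < 1)
    config_error(sprintf(
      "input_size %d collapses below 1 pixel after %d pooling stages; enlarge the input or shrink the network",
      input_size, n_pools))
  structure(list(input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 stem_stages = as.integer(stem_stages),
                 dropout_rate = as.numeric(dropout_rate),
                 n_rise_blocks = as.integer(n_rise_blocks),
                 block_channels = as.integer(block_channels),
                 se_ratio = as.integer(se_ratio),
                 use_se = isTRUE(use_se), use_skip = isTRUE(use_skip),
                 use_inception = isTRUE(use_inception),
                 n_classes = as.integer(n_classes),
                 n_severities = as.integer(n_severities),
                 dense_units = as.integer(dense_units)),
            class = "rise_config")
}

#' @export
print.rise_config <- function(x, ...) {
  cat("RISE network configuration\n")
  cat(sprintf("  input %dx%d, stem %d stage(s) x %d ch (dropout %.2f)\n",
              x$input_size, x$input_size, x$stem_stages, x$stem_channels,
              x$dropout_rate))
  cat(sprintf("  %d RISE blocks, channels: %s\n", x$n_rise_blocks,
              paste(x$block_channels, collapse = " ")))
  cat(sprintf("  SE ratio g = %d; se=%s skip=%s inception=%s\n",
              x$se_ratio, x$use_se, x$use_skip, x$use_inception))
  cat(sprintf("  head: dense %d -> %d (classifier) / %d (regressor)\n",
              x$dense_units, x$n_classes, x$n_severities))
  invisible(x)
}

# Initialise all network parameters for a task.
.init_net <- function(cfg, task, seed) {
  n_out <- if (task == "classification") cfg$n_classes else cfg$n_severities
  seeds <- derive_seeds(seed, cfg$stem_stages + cfg$n_rise_blocks + 2L)
  si <- 0L
  stem <- vector("list", cfg$stem_stages)
  cin <- 1L
  for (s in seq_len(cfg$stem_stages)) {
    si <- si + 1L
    stem[[s]] <- with_seed(seeds[si], .init_conv(3L, cin, cfg$stem_channels))
    cin <- cfg$stem_channels
  }
  blocks <- vector("list", cfg$n_rise_blocks)
  for (b in seq_len(cfg$n_rise_blocks)) {
    si <- si + 1L
    blocks[[b]] <- init_rise_block(cin, cfg$block_channels[b], cfg$se_ratio,
                                   cfg$use_se, cfg$use_skip,
                                   cfg$use_inception, seed = seeds[si])
    cin <- cfg$block_channels[b]
  }
  fc1 <- with_seed(seeds[si + 1L], .init_dense(cin, cfg$dense_units))
  fc2 <- with_seed(seeds[si + 2L], .init_dense(cfg$dense_units, n_out))
  list(stem = stem, blocks = blocks, fc1 = fc1, fc2 = fc2)
}

# Full forward pass over a batch.  x4 is [H, W, 1, N].  Returns the head
# output (N x n_out), pre-activation logits, and (when `train`) the caches
# the backward pass needs.  Dropout is active only when `train` is TRUE.
.net_fwd <- function(x4, params, cfg, task, train = FALSE) {
  cache <- list(stem = vector("list", cfg$stem_stages),
                blocks = vector("list", cfg$n_rise_blocks))
  h <- x4
  for (s in seq_len(cfg$stem_stages)) {
    cv <- .conv_fwd(h, params$stem[[s]])
    rl <- .relu_fwd(cv)
    if (train && cfg$dropout_rate > 0) dp <- .dropout_fwd(rl$out, cfg$dropout_rate)
    else dp <- list(out = rl$out, mask = NULL)
    pl <- .pool2_fwd(dp$out)
    cache$stem[[s]] <- list(x = h, relu_mask = rl$mask, drop_mask = dp$mask,
                            pool_idx = pl$idx, pre_pool_dim = dim(dp$out))
    h <- pl$out
  }
  for (b in seq_len(cfg$n_rise_blocks)) {
    rb <- .rise_fwd(h, params$blocks[[b]], cfg$use_se, cfg$use_skip,
                    cfg$use_inception)
    h <- rb$out
    bc <- rb$cache
    if (b %% 2L == 0L && dim(h)[1] >= 2L) {
      pl <- .pool2_fwd(h)
      bc$pool_idx <- pl$idx
      bc$pre_pool_dim <- dim(h)
      h <- pl$out
    }
    cache$blocks[[b]] <- bc
  }
  cache$gap_in_dim <- dim(h)
  s <- .gap(h)
  z1 <- .dense_fwd(s, params$fc1)
  a1 <- pmax(z1, 0)
  z2 <- .dense_fwd(a1, params$fc2)
  out <- if (task == "classification") plogis(z2) else z2
  cache$head <- list(s = s, z1 = z1, a1 = a1)
  list(out = out, logits = z2, cache = if (train) cache else NULL)
}

# Backward pass from dz2 (gradient of the loss wrt the head pre-activation).
.net_bwd <- function(dz2, cache, params, cfg) {
  hb2 <- .dense_bwd(cache$head$a1, params$fc2, dz2)
  da1 <- hb2$dx * (cache$head$z1 > 0)
  hb1 <- .dense_bwd(cache$head$s, params$fc1, da1)
  d <- cache$gap_in_dim
  g <- .bcast_ch(hb1$dx, d[1], d[2]) / (d[1] * d[2])
  gblocks <- vector("list", cfg$n_rise_blocks)
  for (b in rev(seq_len(cfg$n_rise_blocks))) {
    bc <- cache$blocks[[b]]
    if (!is.null(bc$pool_idx)) g <- .pool_bwd(g, bc$pool_idx, bc$pre_pool_dim)
    rb <- .rise_bwd(g, bc, params$blocks[[b]], cfg$use_se, cfg$use_skip,
                    cfg$use_inception)
    g <- rb$dx
    gblocks[[b]] <- rb$grads
  }
  gstem <- vector("list", cfg$stem_stages)
  for (s in rev(seq_len(cfg$stem_stages))) {
    sc <- cache$stem[[s]]
    g <- .pool_bwd(g, sc$pool_idx, sc$pre_pool_dim)
    if (!is.null(sc$drop_mask)) g <- g * sc$drop_mask
    g <- .relu_bwd(g, sc$relu_mask)
    cb <- .conv_bwd(sc$x, params$stem[[s]], g)
    g <- cb$dx
    gstem[[s]] <- list(w = cb$dw, b = cb$db)
  }
  list(grads = list(stem = gstem, blocks = gblocks,
                    fc1 = list(w = hb1$dw, b = hb1$db),
                    fc2 = list(w = hb2$dw, b = hb2$db)),
       dx = g)
}

# --- Adam over the nested parameter list ---------------------------------

.zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, .zeros_like))
  p * 0
}

.adam_update <- function(p, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
  if (is.list(p)) {
    for (nm in seq_along(p)) {
      r <- .adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], t, lr, b1, b2, eps)
      if (!is.null(r$p)) {
        p[[nm]] <- r$p
        m[[nm]] <- r$m
        v[[nm]] <- r$v
      }
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# Count scalar parameters in a nested parameter list.
.n_params <- function(p) {
  if (is.null(p)) return(0L)
  if (is.list(p)) return(sum(vapply(p, .n_params, numeric(1))))
  length(p)
}
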