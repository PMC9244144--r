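# The SE, inception and RISE block operations checked against independent
# loop-based oracles on small random tensors.

test_that("squeeze equals the per-channel double-loop mean", {
  f22 <- array(c(1, 2, 3, 4), c(2, 2, 1))
  expect_equal(squeeze(f22), 2.5)
  expect_equal(squeeze(array(0.7, c(3, 5, 2))), c(0.7, 0.7))
  set.seed(10)
  f <- array(rnorm(5 * 7 * 3), c(5, 7, 3))
  oracle <- numeric(3)
  for (n in 1:3) {
    acc <- 0
    for (i in 1:5) for (j in 1:7) acc <- acc + f[i, j, n]
    oracle[n] <- acc / (5 * 7)
  }
  expect_equal(squeeze(f), oracle, tolerance = 1e-12)
})

test_that("excitation is a bottlenecked gate with outputs strictly in (0,1)", {
  set.seed(11)
  s <- rnorm(16)
  w <- init_excite(16, 8, seed = 2)
  expect_identical(dim(w$w1), c(16L, 2L))     # bottleneck width C/g
  e <- excite(s, 8, w)
  expect_true(all(e > 0 & e < 1))
  # zero weights and biases: sigmoid(0) = 0.5 everywhere
  w0 <- lapply(w, function(x) x * 0)
  expect_equal(excite(s, 8, w0), rep(0.5, 16))
  # C = g gives bottleneck width 1
  expect_identical(dim(init_excite(8, 8)$w1), c(8L, 1L))
  expect_error(init_excite(10, 8), class = "riseqc_config_error")
  expect_error(excite(rnorm(10), 8, w), class = "riseqc_config_error")
})

test_that("excite matches a hand computation through both affine maps", {
  set.seed(12)
  s <- rnorm(8)
  w <- init_excite(8, 4, seed = 3)
  z1 <- as.numeric(s %*% w$w1) + w$b1
  a1 <- ifelse(z1 > 0, z1, 0)
  z2 <- as.numeric(a1 %*% w$w2) + w$b2
  expect_equal(excite(s, 4, w), 1 / (1 + exp(-z2)), tolerance = 1e-12)
})

test_that("the scale layer multiplies each channel by its scalar weight", {
  set.seed(13)
  f <- array(rnorm(4 * 6 * 8), c(4, 6, 8))
  expect_equal(se_scale(f, rep(1, 8)), f)
  expect_true(all(se_scale(f, rep(0, 8)) == 0))
  e <- runif(8)
  out <- se_scale(f, e)
  oracle <- f
  for (n in 1:8) for (i in 1:4) for (j in 1:6) oracle[i, j, n] <- f[i, j, n] * e[n]
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(se_scale(f, rep(1, 5)), class = "riseqc_value_error")
})

test_that("squeeze/excite/scale composition matches the loop oracle end to end", {
  set.seed(14)
  for (rep in 1:5) {
    C <- sample(c(8, 16), 1)
    f <- array(rnorm(4 * 4 * C), c(4, 4, C))
    w <- init_excite(C, 8, seed = rep)
    s_o <- vapply(seq_len(C), function(n) mean(f[, , n]), numeric(1))
    e_o <- plogis(as.numeric(pmax(as.numeric(s_o %*% w$w1) + w$b1, 0) %*% w$w2) + w$b2)
    o_o <- f
    for (n in seq_len(C)) o_o[, , n] <- f[, , n] * e_o[n]
    got <- se_scale(f, excite(squeeze(f), 8, w))
    expect_equal(got, o_o, tolerance = 1e-9)
  }
})

test_that("inception preserves spatial dims and stacks equal-width paths in order", {
  set.seed(15)
  f <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  p <- init_inception(3, 32, seed = 4)
  out <- inception_block(f, p)
  expect_identical(dim(out), c(6L, 6L, 32L))
  # zero input with zero biases gives zero output
  z <- inception_block(array(0, c(6, 6, 3)), p)
  expect_true(all(z == 0))
  expect_error(init_inception(3, 30), class = "riseqc_config_error")
})

test_that("each inception path owns its contiguous channel block", {
  set.seed(16)
  f <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  p <- init_inception(4, 32, seed = 5)
  base <- inception_block(f, p)
  paths <- list(c("p1"), c("p2a", "p2b"), c("p3a", "p3b"), c("p4"))
  for (path_i in seq_along(paths)) {
    p2 <- p
    for (nm in paths[[path_i]]) p2[[nm]]$w <- p2[[nm]]$w + 0.5
    alt <- inception_block(f, p2)
    changed <- vapply(1:32, function(ch) any(alt[, , ch] != base[, , ch]), logical(1))
    block <- (path_i - 1) * 8 + (1:8)
    expect_true(all(which(changed) %in% block))
    expect_true(any(changed[block]))
  }
})

test_that("a RISE block with zero branch weights and matching channels is the identity", {
  set.seed(17)
  f <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  p <- init_rise_block(8, 8, g = 8, seed = 6)
  p$main <- rapply(p$main, function(x) x * 0, how = "replace")
  p$se <- lapply(p$se, function(x) x * 0)
  expect_null(p$proj)  # identity skip when channels match
  expect_equal(rise_block(f, p), f, tolerance = 1e-12)
})

test_that("the full RISE block equals the manual composition of its parts", {
  set.seed(18)
  f <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  p <- init_rise_block(4, 8, g = 8, seed = 7)
  got <- rise_block(f, p)
  branch <- inception_block(f, p$main)
  branch <- se_scale(branch, excite(squeeze(branch), 8, p$se))
  skip <- array(0, c(6, 6, 8))
  for (co in 1:8) {
    acc <- matrix(p$proj$b[co], 6, 6)
    for (ci in 1:4) acc <- acc + f[, , ci] * p$proj$w[1, 1, ci, co]
    skip[, , co] <- acc
  }
  expect_equal(got, branch + skip, tolerance = 1e-9)
})

test_that("ablation toggles reduce the block to its standalone counterparts", {
  set.seed(19)
  f <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  # all ablations: a single (rectified) 3x3 convolution
  p <- init_rise_block(4, 8, use_se = FALSE, use_skip = FALSE,
                       use_inception = FALSE, seed = 8)
  out <- rise_block(f, p, use_se = FALSE, use_skip = FALSE, use_inception = FALSE)
  expect_identical(dim(out), c(8L, 8L, 8L))
  expect_identical(dim(p$main$w), c(3L, 3L, 4L, 8L))
  expect_null(p$se)
  expect_null(p$proj)
  expect_true(all(out >= 0))  # rectified
  # no SE: output is inception + projected skip exactly
  p2 <- init_rise_block(4, 8, use_se = FALSE, seed = 9)
  out2 <- rise_block(f, p2, use_se = FALSE)
  skip <- array(0, c(8, 8, 8))
  for (co in 1:8) {
    acc <- matrix(p2$proj$b[co], 8, 8)
    for (ci in 1:4) acc <- acc + f[, , ci] * p2$proj$w[1, 1, ci, co]
    skip[, , co] <- acc
  }
  expect_equal(out2, inception_block(f, p2$main) + skip, tolerance = 1e-9)
  # no skip: output is the (SE-recalibrated) branch alone
  p3 <- init_rise_block(4, 8, use_skip = FALSE, seed = 10)
  out3 <- rise_block(f, p3, use_skip = FALSE)
  br <- inception_block(f, p3$main)
  expect_equal(out3, se_scale(br, excite(squeeze(br), 8, p3$se)),
               tolerance = 1e-9)
})

test_that("conv kernels match a direct convolution oracle", {
  set.seed(20)
  x <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  got <- riseqc:::conv2d_fwd_cpp(x, w, b)
  oracle <- array(0, c(5, 6, 3, 2))
  for (n in 1:2) for (co in 1:3) for (i in 1:5) for (j in 1:6) {
    acc <- b[co]
    for (ci in 1:2) for (di in 1:3) for (dj in 1:3) {
      si <- i + di - 2; sj <- j + dj - 2
      if (si >= 1 && si <= 5 && sj >= 1 && sj <= 6)
        acc <- acc + x[si, sj, ci, n] * w[di, dj, ci, co]
    }
    oracle[i, j, co, n] <- acc
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})
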