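test_that("binarize applies a strict threshold", {
  expect_identical(binarize(c(0.9, 0.1, 0.6, 0.4)), c(1L, 0L, 1L, 0L))
  expect_identical(binarize(rep(0.5, 4)), rep(0L, 4))  # ties go to 0
  # raising the threshold never turns a 0 into a 1
  set.seed(70)
  p <- runif(50)
  expect_true(all(binarize(p, 0.7) <= binarize(p, 0.3)))
})

test_that("exact-match accuracy counts whole-vector agreement", {
  y <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_identical(exact_match_accuracy(y, y), 1)
  y2 <- y
  y2[4, 1] <- 1  # one flag wrong in one item
  expect_identical(exact_match_accuracy(y, y2), 0.75)
  expect_error(exact_match_accuracy(y, y[1:3, ]), class = "riseqc_value_error")
})

test_that("exact-match accuracy equals the brute-force indicator mean", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    t <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
    p <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
    acc <- 0
    for (r in seq_len(n)) acc <- acc + as.integer(all(t[r, ] == p[r, ]))
    expect_equal(exact_match_accuracy(t, p), acc / n, tolerance = 1e-12)
  }
})

test_that("per-class confusion counts match a hand tally", {
  t <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 0), c(1, 1), c(0, 1))
  p <- rbind(c(1, 0), c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0, 0))
  cc <- per_class_confusion(t, p)
  # class 1: items with truth 1 = {1,2,5}, pred 1 = {1,4,5}
  expect_identical(cc$tp, c(2L, 2L))
  expect_identical(cc$fp, c(1L, 0L))
  expect_identical(cc$fn, c(1L, 1L))
  expect_identical(cc$tn, c(2L, 3L))
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 6L))
  cc2 <- per_class_confusion(t, t)
  expect_true(all(cc2$fp == 0L) && all(cc2$fn == 0L))
})

test_that("precision/recall/F1 follow their closed forms, undefined stays NA", {
  cc <- data.frame(class = "a", tp = 10L, fp = 0L, fn = 0L, tn = 5L)
  m <- precision_recall_f1(cc)
  expect_equal(unlist(m[, c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))
  # P = 1, R = 0.5 gives the harmonic mean 2/3
  cc2 <- data.frame(class = "a", tp = 5L, fp = 0L, fn = 5L, tn = 0L)
  expect_equal(precision_recall_f1(cc2)$f1, 2 / 3, tolerance = 1e-12)
  # zero denominator: explicit undefined, never 0
  cc3 <- data.frame(class = "a", tp = 0L, fp = 0L, fn = 2L, tn = 4L)
  m3 <- precision_recall_f1(cc3)
  expect_true(is.na(m3$precision))
  expect_identical(m3$recall, 0)
  expect_true(is.na(m3$f1))
})

test_that("F1 sits between precision and recall and is symmetric", {
  set.seed(72)
  for (i in 1:50) {
    cc <- data.frame(class = "x", tp = sample(1:20, 1), fp = sample(0:20, 1),
                     fn = sample(0:20, 1), tn = sample(0:20, 1))
    m <- precision_recall_f1(cc)
    if (!is.na(m$f1)) {
      expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
      expect_lte(m$f1 - 1e-12, max(m$precision, m$recall))
    }
  }
})

test_that("severity MSE aggregates per class and overall as the mean", {
  t <- matrix(0, 3, 3)
  p <- matrix(0, 3, 3)
  expect_identical(severity_mse(t, p)$overall, 0)
  set.seed(73)
  t <- matrix(sample(0:3, 30, TRUE), 10, 3)
  p <- t + matrix(rnorm(30, 0, 0.3), 10, 3)
  m <- severity_mse(t, p)
  oracle <- numeric(3)
  for (k in 1:3) {
    acc <- 0
    for (i in 1:10) acc <- acc + (t[i, k] - p[i, k])^2
    oracle[k] <- acc / 10
  }
  expect_equal(unname(m$per_class), oracle, tolerance = 1e-12)
  expect_equal(m$overall, mean(oracle), tolerance = 1e-12)
})

test_that("published per-class severity errors aggregate to the published overall", {
  # construct predictions whose per-class MSEs are exactly 0.097/0.079/0.073
  t <- matrix(0, 1, 3)
  p <- matrix(sqrt(c(0.097, 0.079, 0.073)), 1, 3)
  m <- severity_mse(t, p)
  expect_equal(unname(m$per_class), c(0.097, 0.079, 0.073), tolerance = 1e-12)
  expect_equal(round(m$overall, 3), 0.083)
})

test_that("exact-match accuracy never exceeds any per-class binary accuracy", {
  set.seed(74)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    t <- matrix(rbinom(n * 4, 1, runif(1, 0.2, 0.8)), n, 4)
    p <- matrix(rbinom(n * 4, 1, runif(1, 0.2, 0.8)), n, 4)
    em <- exact_match_accuracy(t, p)
    pc <- precision_recall_f1(per_class_confusion(t, p))$accuracy
    expect_lte(em, min(pc) + 1e-12)
  }
})

test_that("metrics are invariant under item permutation", {
  set.seed(75)
  t <- matrix(rbinom(80, 1, 0.5), 20, 4)
  p <- matrix(rbinom(80, 1, 0.5), 20, 4)
  o <- sample(20)
  expect_identical(exact_match_accuracy(t, p), exact_match_accuracy(t[o, ], p[o, ]))
  expect_identical(per_class_confusion(t, p)$tp, per_class_confusion(t[o, ], p[o, ])$tp)
})

test_that("the classifier report wires threshold, confusion and summaries together", {
  set.seed(76)
  t <- matrix(rbinom(40, 1, 0.5), 10, 4)
  probs <- matrix(runif(40), 10, 4)
  rep <- metrics_report(t, probs)
  expect_identical(rep$exact_match_accuracy,
                   exact_match_accuracy(t, binarize(probs)))
  expect_identical(nrow(rep$per_class), 4L)
})
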