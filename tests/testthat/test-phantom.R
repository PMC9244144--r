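test_that("phantom spec rejects invalid configurations", {
  expect_error(phantom_spec(image_size = 16), class = "riseqc_config_error")
  expect_error(phantom_spec(n_blobs = 0), class = "riseqc_config_error")
  expect_error(phantom_spec(intensity_range = c(0.9, 0.4)),
               class = "riseqc_config_error")
})

test_that("phantom generation is deterministic and mask-consistent", {
  sp <- phantom_spec(image_size = 64, seed = 7)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a, b)
  expect_true(all(a$image >= 0 & a$image <= 1))
  # nonzero pixel set equals mask support, counted directly
  expect_identical(sum(a$image > 0), sum(a$mask == 1L))
  expect_true(all(a$image[a$mask == 0L] == 0))
})

test_that("zero-severity injections are exact identities for any seed", {
  ph <- test_phantom()
  for (sd in c(1L, 99L, 12345L)) {
    expect_identical(inject_motion(ph$image, 0, sd), ph$image)
    expect_identical(inject_chemical_shift(ph$image, ph$mask, 0, sd), ph$image)
    expect_identical(inject_rf(ph$image, 0, sd), ph$image)
  }
})

test_that("severity outside 0..3 is a value error", {
  ph <- test_phantom()
  expect_error(inject_motion(ph$image, 4, 1), class = "riseqc_value_error")
  expect_error(inject_rf(ph$image, -1, 1), class = "riseqc_value_error")
  expect_error(inject_chemical_shift(ph$image, ph$mask[1:10, 1:10], 1, 1),
               class = "riseqc_value_error")
})

test_that("corruption magnitude is monotone in severity at fixed seed", {
  ph <- test_phantom()
  mad <- function(img) mean(abs(img - ph$image))
  for (op in list(function(k) inject_motion(ph$image, k, 3),
                  function(k) inject_rf(ph$image, k, 3),
                  function(k) inject_rf(ph$image, k, 3, mode = "zipper"),
                  function(k) inject_chemical_shift(ph$image, ph$mask, k, 3))) {
    devs <- vapply(0:3, function(k) mad(op(k)), numeric(1))
    expect_true(all(diff(devs) >= 0))
    expect_gt(devs[4], 0)
  }
})

test_that("all corruption operators preserve shape and the [0,1] range", {
  ph <- test_phantom()
  for (k in 1:3) {
    for (out in list(inject_motion(ph$image, k, 5),
                     inject_chemical_shift(ph$image, ph$mask, k, 5),
                     inject_rf(ph$image, k, 5),
                     inject_rf(ph$image, k, 5, mode = "zipper"))) {
      expect_identical(dim(out), dim(ph$image))
      expect_gte(min(out), 0)
      expect_lte(max(out), 1)
    }
  }
})

test_that("chemical-shift band widens with severity and stays near the boundary", {
  ph <- test_phantom()
  n_dark <- function(k) sum(inject_chemical_shift(ph$image, ph$mask, k, 1) < ph$image)
  expect_gt(n_dark(3), n_dark(1))
  # pixels farther than the max band width from the boundary are unchanged
  m <- ph$mask > 0
  S <- nrow(m)
  interior <- m
  for (d in 1:3) {
    sh_r <- cbind(matrix(FALSE, S, d), m[, 1:(S - d)])
    sh_l <- cbind(m[, (1 + d):S], matrix(FALSE, S, d))
    interior <- interior & sh_r & sh_l
  }
  out <- inject_chemical_shift(ph$image, ph$mask, 3, 1)
  expect_identical(out[interior], ph$image[interior])
  expect_identical(out[!m], ph$image[!m])
})

test_that("rf streak bookkeeping and positions are reproducible", {
  ph <- test_phantom()
  counts <- vapply(1:3, function(k)
    attr(inject_rf(ph$image, k, 9, mode = "zipper"), "n_streaks"), integer(1))
  expect_identical(counts, 1:3)
  expect_identical(inject_rf(ph$image, 2, 9), inject_rf(ph$image, 2, 9))
  expect_false(identical(inject_rf(ph$image, 2, 9), inject_rf(ph$image, 2, 10)))
})

test_that("generated datasets satisfy the label-consistency invariant", {
  d <- cached_dataset(60, 32, 5)
  expect_length(d, 60)
  for (it in d) {
    f <- it$artifact_flags
    s <- it$severities
    expect_identical(unname(f[1:3]), as.integer(s > 0))
    expect_identical(unname(f[4]), as.integer(all(s == 0)))
    expect_true(all(s %in% 0:3))
  }
})

test_that("a degenerate class mix produces only normal slices", {
  d <- generate_dataset(25, phantom_spec(image_size = 32),
                        class_mix = c(0, 0, 0, 1), seed = 3)
  expect_true(all(vapply(d, function(it) it$artifact_flags[["normal"]], integer(1)) == 1L))
  expect_true(all(vapply(d, function(it) all(it$severities == 0L), logical(1))))
})

test_that("class-mix weights must sum to one", {
  expect_error(generate_dataset(5, phantom_spec(image_size = 32),
                                class_mix = c(0.5, 0.5, 0.5, 0.5), seed = 1),
               class = "riseqc_config_error")
})

test_that("dataset generation is deterministic under a fixed seed", {
  a <- generate_dataset(6, phantom_spec(image_size = 32), seed = 21)
  b <- generate_dataset(6, phantom_spec(image_size = 32), seed = 21)
  expect_identical(a, b)
})
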