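# Shared fixtures, all generated in code at test time.

tiny_cfg <- function(size = 16L, ...) {
  rise_config(input_size = size, stem_channels = 4L, stem_stages = 1L,
              n_rise_blocks = 2L, block_channels = c(8L, 8L),
              dense_units = 8L, dropout_rate = 0, ...)
}

desk_cfg <- function(size = 64L, ...) {
  rise_config(input_size = size, stem_channels = 8L, stem_stages = 2L,
              n_rise_blocks = 6L, block_channels = c(8L, 16L, 16L, 32L, 32L, 32L),
              dense_units = 64L, dropout_rate = 0.1, ...)
}

.fixture_env <- new.env(parent = emptyenv())

cached_dataset <- function(n = 40L, size = 32L, seed = 42L) {
  key <- paste(n, size, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    gen_size <- max(size, 32L)  # phantoms have a 32-pixel minimum
    d <- generate_dataset(n, phantom_spec(image_size = gen_size), seed = seed)
    if (size < gen_size)
      d <- lapply(d, function(it) {
        labeled_slice(resize_slice(it$image, size),
                      resize_slice(it$mask, size, method = "nearest"),
                      it$severities, id = it$id)
      })
    .fixture_env[[key]] <- d
  }
  .fixture_env[[key]]
}

test_phantom <- function(size = 64L, seed = 7L) {
  key <- paste("ph", size, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_phantom(phantom_spec(image_size = size, seed = seed))
  .fixture_env[[key]]
}
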