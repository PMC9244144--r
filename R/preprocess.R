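#' Overlay a segmentation mask onto a slice
#'
#' Zeroes every pixel outside the mask so only the segmented tissue is
#' visible — the representation the networks are trained on.
#'
#' @param image Numeric matrix.
#' @param mask 0/1 matrix of the same shape.
#' @return Matrix of the same shape: `image` where `mask == 1`, 0 elsewhere.
#' @export
overlay_mask <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    value_error("`mask` shape must match `image`")
  image * (mask > 0)
}

#' Max-intensity normalization
#'
#' Divides every pixel by the image maximum, giving values in `[0, 1]` with
#' ratios between pixels preserved.  Idempotent.  An all-zero image (empty
#' mask) is rejected: the operation is undefined and such a slice carries no
#' tissue.
#'
#' @param image Numeric matrix with at least one positive pixel.
#' @return Matrix with maximum exactly 1.
#' @export
normalize_slice <- function(image) {
  m <- max(image)
  if (!is.finite(m) || m <= 0)
    value_error("cannot normalize an image with no positive pixel (empty mask?)")
  image / m
}

#' Resize a slice to a fixed square size
#'
#' Bilinear interpolation for images, nearest-neighbour for masks (so masks
#' stay binary).  Networks require a single input size; the canonical target
#' is 512.
#'
#' @param image Numeric matrix.
#' @param target Side length of the square output; at least 8.
#' @param method `"bilinear"` (default, images) or `"nearest"` (masks).
#' @return `target` x `target` matrix, clipped to `[0, 1]`.
#' @export
resize_slice <- function(image, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!is_count(target) || target < 8)
    config_error("`target` must be a single integer >= 8")
  if (nrow(image) == target && ncol(image) == target) return(image)
  out <- EBImage::resize(image, w = target, h = target,
                         filter = if (method == "bilinear") "bilinear" else "none")
  out <- matrix(as.numeric(EBImage::imageData(out)), nrow = target)
  if (method == "nearest") out <- round(out)
  clip01(out)
}

#' Split item identifiers 80:10:10
#'
#' Deterministic seeded shuffle, then floor-sized validation and test
#' partitions with the remainder to training (for 2,250 items this gives
#' exactly 1,800 / 225 / 225).  Splitting is at the slice level.
#'
#' @param ids Vector of identifiers (nonempty).
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer seed.
#' @return Object of class `split_assignment`: list with `train_ids`,
#'   `val_ids`, `test_ids` — disjoint, jointly covering `ids`.
#' @examples
#' s <- split_dataset(seq_len(2250), seed = 1)
#' lengths(s)
#' @export
split_dataset <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ids) == 0L) value_error("`ids` must be nonempty")
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-6)
    config_error("`ratios` must be 3 nonnegative proportions summing to 1")
  n <- length(ids)
  perm <- with_seed(seed, sample(n))
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  val <- perm[seq_len(n_val)]
  test <- perm[n_val + seq_len(n_test)]
  train <- perm[-seq_len(n_val + n_test)]
  structure(list(train_ids = ids[train], val_ids = ids[val],
                 test_ids = ids[test]),
            class = "split_assignment")
}

#' Up-sample minority classes in a training partition
#'
#' Groups items by their 4-flag pattern and duplicates items of
#' under-represented patterns (sampling with replacement, seeded) until
#' every pattern reaches the majority count.  Apply to the training
#' partition only — never to validation or test data.
#'
#' @param train_items List of [labeled_slice()].
#' @param seed Integer seed.
#' @return List of labeled slices: the originals followed by duplicates.
#' @export
upsample_minority <- function(train_items, seed = 1L) {
  if (length(train_items) == 0L) value_error("empty training set")
  key <- vapply(train_items, function(s) paste(s$artifact_flags, collapse = ""),
                character(1))
  counts <- table(key)
  target <- max(counts)
  extra_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(k) {
      need <- target - counts[[k]]
      if (need == 0L) return(integer(0))
      pool <- which(key == k)
      sample(pool, need, replace = TRUE)
    }))
  })
  c(train_items, train_items[extra_idx])
}

#' Preprocess one raw slice for the networks
#'
#' The fixed pipeline: mask overlay, then max-intensity normalization, then
#' resize to the target square size.
#'
#' @param image Numeric matrix (raw intensities, any scale).
#' @param mask 0/1 matrix, same shape.
#' @param target Output side length.
#' @return `target` x `target` matrix in `[0, 1]`.
#' @export
preprocess_slice <- function(image, mask, target = 512L) {
  resize_slice(normalize_slice(overlay_mask(image, mask)), target)
}
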