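#' Specification for a synthetic fetal-like phantom slice
#'
#' Describes a square 2D phantom built from smooth elliptical structures on a
#' black background, emulating a masked fetal MR slice after segmentation
#' overlay (only tissue visible, zero elsewhere).
#'
#' @param image_size Side length in pixels (square image), at least 32.
#' @param n_blobs Number of smooth elliptical structures composing the
#'   "fetus"; at least 1.
#' @param intensity_range Length-2 numeric in `[0, 1]`, `low < high`: the
#'   range of peak intensities drawn per blob.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(image_size = 128L, n_blobs = 5L,
                         intensity_range = c(0.35, 0.95), seed = 1L) {
  if (!is_count(image_size) || image_size < 32)
    config_error("`image_size` must be a single integer >= 32")
  if (!is_count(n_blobs))
    config_error("`n_blobs` must be a single positive integer")
  if (length(intensity_range) != 2L || !is.numeric(intensity_range) ||
      any(intensity_range < 0) || any(intensity_range > 1) ||
      intensity_range[1] >= intensity_range[2])
    config_error("`intensity_range` must be (low, high) with 0 <= low < high <= 1")
  if (length(seed) != 1L || !is.finite(seed))
    config_error("`seed` must be a single integer")
  structure(list(image_size = as.integer(image_size),
                 n_blobs = as.integer(n_blobs),
                 intensity_range = as.numeric(intensity_range),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic masked phantom slice
#'
#' Draws `n_blobs` ellipses with random centres, axes, orientations and peak
#' intensities, shades each with a smooth radial falloff, overlays a gentle
#' low-frequency texture, and returns the image together with its binary
#' tissue mask.  The image is zero exactly where the mask is zero, mirroring
#' the mask-overlay representation the networks consume.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `mask`
#'   (integer 0/1 matrix of the same shape).
#' @examples
#' ph <- make_phantom(phantom_spec(image_size = 64, seed = 7))
#' range(ph$image)
#' all(ph$image[ph$mask == 0] == 0)
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    config_error("`spec` must be a phantom_spec object")
  S <- spec$image_size
  with_seed(spec$seed, {
    img <- matrix(0, S, S)
    xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
    ys <- matrix(rep(seq_len(S), times = S), S, S)  # row index
    for (b in seq_len(spec$n_blobs)) {
      cx <- runif(1, 0.3, 0.7) * S
      cy <- runif(1, 0.3, 0.7) * S
      a  <- runif(1, 0.08, 0.22) * S
      bb <- runif(1, 0.08, 0.22) * S
      th <- runif(1, 0, pi)
      v  <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
      dx <- xs - cx
      dy <- ys - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      w <- (-dx * sin(th) + dy * cos(th)) / bb
      q <- u^2 + w^2
      blob <- ifelse(q < 1, v * (1 - q)^0.25, 0)
      img <- pmax(img, blob)
    }
    # mild smooth texture; factor in [0.8, 1] keeps positivity and the range
    tex <- 0.9 + 0.1 * sin(2 * pi * 3 * xs / S) * cos(2 * pi * 2 * ys / S)
    img <- img * tex
    mask <- matrix(as.integer(img > 0), S, S)
    list(image = clip01(img), mask = mask)
  })
}

check_severity <- function(severity) {
  if (length(severity) != 1L || !is.numeric(severity) ||
      !(severity %in% 0:3))
    value_error("`severity` must be a single integer in {0, 1, 2, 3}")
  as.integer(severity)
}

#' Inject a motion artifact (k-space line phase corruption)
#'
#' Models bulk fetal motion as phase errors on a subset of phase-encode
#' (row-frequency) lines of the slice's 2D discrete Fourier transform,
#' producing the blur/ghosting phenotype.  Severity `k > 0` corrupts a
#' fraction `0.1 * k` of all lines, excluding the lowest spatial
#' frequencies so gross structure survives.  The corrupted line set is
#' nested across severities at a fixed seed (severity 3 corrupts a superset
#' of severity 1's lines with identical phases), so image deviation grows
#' monotonically with severity by construction.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param severity Integer in 0..3; 0 returns the input unchanged.
#' @param seed Integer seed controlling line choice and phases.
#' @return Corrupted image, same shape, clipped to `[0, 1]`.
#' @export
inject_motion <- function(image, severity, seed = 1L) {
  severity <- check_severity(severity)
  if (severity == 0L) return(image)
  H <- nrow(image)
  K <- stats::fft(image)
  # frequency index of each row in unshifted layout
  f <- c(0:(ceiling(H / 2) - 1), -(floor(H / 2):1))
  candidates <- which(abs(f) > H / 16)
  with_seed(seed, {
    perm <- sample(candidates)
    phases <- runif(length(perm), -pi, pi)
  })
  n_corrupt <- min(ceiling(0.1 * severity * H), length(perm))
  lines <- perm[seq_len(n_corrupt)]
  K[lines, ] <- K[lines, ] * exp(1i * phases[seq_len(n_corrupt)])
  out <- Mod(stats::fft(K, inverse = TRUE)) / length(K)
  clip01(matrix(out, nrow = H))
}

#' Inject a chemical-shift artifact (boundary band displacement)
#'
#' Paints a dark band of width `severity` pixels along one side of the
#' tissue boundary and a matched bright band on the opposite side, along
#' the horizontal axis taken as the nominal frequency-encode direction.
#' This emulates the thin dark outline produced by fat/water spatial
#' misregistration.  Pixels farther than `severity` pixels from the mask
#' boundary are untouched.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask 0/1 matrix, same shape as `image`.
#' @param severity Integer in 0..3; 0 is the identity.
#' @param seed Accepted for interface uniformity; the operator is
#'   deterministic given image and mask.
#' @return Corrupted image, same shape, in `[0, 1]`.
#' @export
inject_chemical_shift <- function(image, mask, severity, seed = 1L) {
  severity <- check_severity(severity)
  if (!identical(dim(image), dim(mask)))
    value_error("`mask` shape must match `image`")
  if (severity == 0L) return(image)
  k <- severity
  m <- mask > 0
  shift_cols <- function(m, by) {
    # positive `by` moves content right (toward higher column index)
    out <- matrix(FALSE, nrow(m), ncol(m))
    if (by > 0) out[, (by + 1):ncol(m)] <- m[, 1:(ncol(m) - by)]
    else out[, 1:(ncol(m) + by)] <- m[, (1 - by):ncol(m)]
    out
  }
  dark <- m & !shift_cols(m, k)     # within k of the left tissue boundary
  bright <- m & !shift_cols(m, -k)  # within k of the right tissue boundary
  out <- image
  out[dark] <- out[dark] * 0.15
  out[bright] <- pmin(1, out[bright] + 0.35)
  out
}

#' Inject a radio-frequency interference artifact
#'
#' Two modes, selected by `mode`:
#' \describe{
#'   \item{`"spike"`}{adds `severity` spikes at mid/high spatial frequencies
#'     of the slice's k-space, each producing a coherent stripe pattern
#'     (default).}
#'   \item{`"zipper"`}{draws `severity` short alternating bright-pixel line
#'     segments, the classic zipper appearance.}
#' }
#' Spike/segment positions are drawn once per seed and used in nested order,
#' so corruption grows monotonically with severity.  The number of injected
#' streaks is recorded in the `n_streaks` attribute.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param severity Integer in 0..3; 0 is the identity.
#' @param seed Integer seed.
#' @param mode `"spike"` or `"zipper"`.
#' @return Corrupted image with attribute `n_streaks`.
#' @export
inject_rf <- function(image, severity, seed = 1L, mode = c("spike", "zipper")) {
  severity <- check_severity(severity)
  mode <- match.arg(mode)
  if (severity == 0L) return(image)
  S <- nrow(image)
  if (mode == "spike") {
    K <- stats::fft(image)
    with_seed(seed, {
      ky <- sample(seq(round(S / 8), round(S / 3)), 3, replace = TRUE)
      kx <- sample(seq(round(S / 8), round(S / 3)), 3, replace = TRUE)
      sgn <- sample(c(-1, 1), 3, replace = TRUE)
    })
    amp <- 0.25 * S * S
    for (j in seq_len(severity)) {
      K[ky[j] + 1L, kx[j] + 1L] <- K[ky[j] + 1L, kx[j] + 1L] +
        amp * exp(1i * sgn[j] * pi / 4)
    }
    out <- Mod(stats::fft(K, inverse = TRUE)) / length(K)
    out <- clip01(matrix(out, nrow = S))
  } else {
    out <- image
    with_seed(seed, {
      rows <- sample(seq_len(S), 3, replace = TRUE)
      starts <- sample(seq_len(max(1L, S - round(S / 4))), 3, replace = TRUE)
    })
    len <- max(4L, round(S / 4))
    for (j in seq_len(severity)) {
      cols <- seq(starts[j], min(S, starts[j] + len - 1L))
      cols <- cols[seq(1, length(cols), by = 2)]  # alternating pixels
      out[rows[j], cols] <- 1
    }
  }
  attr(out, "n_streaks") <- severity
  out
}
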