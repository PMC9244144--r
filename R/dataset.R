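#' Construct a labeled slice
#'
#' Bundles an image, its tissue mask, the 4 one-hot artifact-presence flags
#' (motion, chemical_shift, radiofrequency, normal) and the 3 severity
#' grades (each 0 = none .. 3 = severe), enforcing label consistency:
#' an artifact flag is 1 exactly when its severity is positive, and the
#' normal flag is 1 exactly when all severities are 0.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask 0/1 matrix, same shape.
#' @param severities Integer vector of length 3 (motion, chemical_shift,
#'   radiofrequency), values in 0..3.  Flags are derived from it.
#' @param id Optional identifier string.
#' @return An object of class `labeled_slice` with fields `image`, `mask`,
#'   `artifact_flags`, `severities`, `id`.
#' @export
labeled_slice <- function(image, mask, severities, id = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    value_error("`image` must be a numeric matrix")
  if (!identical(dim(image), dim(mask)))
    value_error("`mask` shape must match `image`")
  if (length(severities) != 3L || !all(severities %in% 0:3))
    value_error("`severities` must be 3 integers in {0, 1, 2, 3}")
  severities <- as.integer(severities)
  flags <- c(as.integer(severities > 0), as.integer(all(severities == 0)))
  names(flags) <- c("motion", "chemical_shift", "radiofrequency", "normal")
  names(severities) <- c("motion", "chemical_shift", "radiofrequency")
  structure(list(image = image, mask = matrix(as.integer(mask > 0), nrow(mask)),
                 artifact_flags = flags, severities = severities, id = id),
            class = "labeled_slice")
}

#' @export
print.labeled_slice <- function(x, ...) {
  cat(sprintf("<labeled_slice %s  %dx%d  flags: %s  severities: %s>\n",
              if (is.null(x$id)) "" else x$id,
              nrow(x$image), ncol(x$image),
              paste(x$artifact_flags, collapse = ""),
              paste(x$severities, collapse = "")),
      sep = "")
  invisible(x)
}

#' Generate a synthetic labeled dataset
#'
#' Draws `n` phantom slices and corrupts each according to a recipe sampled
#' from `class_mix`, the target frequencies of the four classes
#' (motion, chemical_shift, radiofrequency, normal).  An item of an
#' artifact class receives that artifact at a severity drawn uniformly from
#' \{1, 2, 3\}; with probability `multi_prob` one additional artifact type
#' is added (slices can carry several artifacts, which is what makes the
#' detection task multi-label).  Normal items have all severities 0.
#' Corruption order is chemical shift (boundary), then motion (k-space),
#' then RF.
#'
#' @param n Number of slices, at least 1.
#' @param spec A [phantom_spec()]; its seed is re-derived per item so every
#'   slice has its own anatomy.
#' @param class_mix 4 nonnegative weights summing to 1 (tolerance 1e-6).
#' @param seed Integer seed determining everything.
#' @param multi_prob Probability of a second artifact on artifact items.
#' @param rf_mode Passed to [inject_rf()].
#' @param out_dir Optional directory; if given the dataset is also written
#'   via [write_dataset()].
#' @return List of [labeled_slice()] objects, length `n`.
#' @examples
#' d <- generate_dataset(4, phantom_spec(image_size = 32), seed = 1)
#' vapply(d, function(s) s$artifact_flags[["normal"]], integer(1))
#' @export
generate_dataset <- function(n, spec = phantom_spec(),
                             class_mix = c(0.3, 0.25, 0.25, 0.2),
                             seed = 1L, multi_prob = 0.25,
                             rf_mode = c("spike", "zipper"), out_dir = NULL) {
  if (!is_count(n)) value_error("`n` must be a positive integer")
  if (length(class_mix) != 4L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-6)
    config_error("`class_mix` must be 4 nonnegative weights summing to 1")
  rf_mode <- match.arg(rf_mode)
  seeds <- derive_seeds(seed, 5L)
  item_seeds <- matrix(with_seed(seeds[1],
                                 sample.int(2147483646L, 4L * n, replace = TRUE)),
                       ncol = 4L)
  recipes <- with_seed(seeds[2], {
    cls <- sample.int(4L, n, replace = TRUE, prob = class_mix)
    lapply(seq_len(n), function(i) {
      sev <- c(0L, 0L, 0L)
      if (cls[i] < 4L) {
        sev[cls[i]] <- sample(1:3, 1)
        if (runif(1) < multi_prob) {
          other <- if (cls[i] == 1L) sample(2:3, 1)
                   else sample((1:3)[-cls[i]], 1)
          sev[other] <- sample(1:3, 1)
        }
      }
      sev
    })
  })
  items <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- item_seeds[i, 1]
    ph <- make_phantom(sp)
    sev <- recipes[[i]]
    img <- inject_chemical_shift(ph$image, ph$mask, sev[2], item_seeds[i, 2])
    img <- inject_motion(img, sev[1], item_seeds[i, 3])
    img <- inject_rf(img, sev[3], item_seeds[i, 4], mode = rf_mode)
    attr(img, "n_streaks") <- NULL
    items[[i]] <- labeled_slice(img, ph$mask, sev,
                                id = sprintf("slice%05d", i))
  }
  if (!is.null(out_dir)) write_dataset(items, out_dir, spec = spec, seed = seed)
  items
}

#' Write a labeled dataset to disk
#'
#' One 8-bit grayscale PNG per slice and per mask, a `labels.csv` table
#' (filename, the 4 flags, the 3 severities) and a `manifest.json`
#' recording the generating spec and seed.
#'
#' @param items List of [labeled_slice()].
#' @param dir Output directory (created if needed).
#' @param spec,seed Optional provenance recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(items, dir, spec = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(items, function(it) {
    fn <- paste0(it$id, ".png")
    png::writePNG(clip01(it$image), file.path(dir, fn))
    png::writePNG(it$mask + 0, file.path(dir, paste0(it$id, "_mask.png")))
    data.frame(filename = fn,
               motion_flag = it$artifact_flags[[1]],
               cs_flag = it$artifact_flags[[2]],
               rf_flag = it$artifact_flags[[3]],
               normal_flag = it$artifact_flags[[4]],
               motion_sev = it$severities[[1]],
               cs_sev = it$severities[[2]],
               rf_sev = it$severities[[3]])
  })
  write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
            row.names = FALSE)
  manifest <- list(n = length(items), seed = seed,
                   spec = if (!is.null(spec)) unclass(spec),
                   package_version = as.character(utils::packageVersion("riseqc")),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a labeled dataset directory
#'
#' Pairs the rows of `labels.csv` with their PNG images (and `_mask.png`
#' siblings when present).  Per-file failures are collected in a rejects
#' report instead of aborting the batch.
#'
#' @param dir Directory written by [write_dataset()] or laid out the same
#'   way.
#' @return List of [labeled_slice()]; attribute `rejects` is a character
#'   vector of filenames that failed to load, with reasons.
#' @export
read_labeled_dir <- function(dir) {
  tab_path <- file.path(dir, "labels.csv")
  if (!file.exists(tab_path)) value_error(paste("no labels.csv in", dir))
  tab <- read.csv(tab_path)
  items <- list()
  rejects <- character(0)
  for (r in seq_len(nrow(tab))) {
    fn <- tab$filename[r]
    res <- tryCatch({
      img <- png::readPNG(file.path(dir, fn))
      if (length(dim(img)) == 3L) img <- img[, , 1]
      mask_fn <- file.path(dir, sub("\\.png$", "_mask.png", fn))
      mask <- if (file.exists(mask_fn)) {
        m <- png::readPNG(mask_fn)
        if (length(dim(m)) == 3L) m <- m[, , 1]
        matrix(as.integer(m > 0.5), nrow(m))
      } else matrix(1L, nrow(img), ncol(img))
      labeled_slice(img, mask,
                    c(tab$motion_sev[r], tab$cs_sev[r], tab$rf_sev[r]),
                    id = sub("\\.png$", "", fn))
    }, error = function(e) paste0(fn, ": ", conditionMessage(e)))
    if (is.character(res)) rejects <- c(rejects, res)
    else items[[length(items) + 1L]] <- res
  }
  attr(items, "rejects") <- rejects
  items
}

# Stack a list of labeled slices into the arrays the fitting function
# consumes: x is [H, W, N]; flags is N x 4; severities is N x 3.
#' Stack labeled slices into model arrays
#'
#' @param items List of [labeled_slice()] with equal image sizes.
#' @return List with `x` (H x W x N array), `flags` (N x 4 matrix) and
#'   `severities` (N x 3 matrix).
#' @export
stack_slices <- function(items) {
  if (length(items) == 0L) value_error("empty slice list")
  H <- nrow(items[[1]]$image)
  W <- ncol(items[[1]]$image)
  x <- array(0, dim = c(H, W, length(items)))
  for (i in seq_along(items)) {
    if (!identical(dim(items[[i]]$image), c(H, W)))
      value_error("all slices must share one image size; resize first")
    x[, , i] <- items[[i]]$image
  }
  flags <- t(vapply(items, function(s) as.numeric(s$artifact_flags), numeric(4)))
  sev <- t(vapply(items, function(s) as.numeric(s$severities), numeric(3)))
  colnames(flags) <- c("motion", "chemical_shift", "radiofrequency", "normal")
  colnames(sev) <- c("motion", "chemical_shift", "radiofrequency")
  list(x = x, flags = flags, severities = sev)
}
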