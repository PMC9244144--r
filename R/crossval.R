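#' k-fold cross-validation of a RISE network
#'
#' Partitions the supplied items into `n_folds` disjoint validation folds
#' (seeded shuffle; every item is validated exactly once), trains a fresh
#' network on each complement and evaluates on the held-out fold.  Hold any
#' final test split out *before* calling this: the published protocol
#' reports a separate test set, so cross-validation runs over the remaining
#' data only.
#'
#' @param x `[H, W, N]` array of slices or list of [labeled_slice()].
#' @param y Label matrix (may be omitted when `x` is a slice list).
#' @param task `"classification"` or `"regression"`.
#' @param config A [rise_config()].
#' @param control A [train_config()]; `n_folds` and `seed` come from here.
#' @param upsample Balance each training fold with [upsample_minority()]
#'   style duplication (flag patterns for classification); default FALSE.
#' @return Object of class `rise_cv`: per-fold metric values, fold
#'   assignments, and a `mean`/`sd` summary.
#' @export
cross_validate <- function(x, y = NULL, task = c("classification", "regression"),
                           config = rise_config(), control = train_config(),
                           upsample = FALSE) {
  task <- match.arg(task)
  if (is.list(x) && is.null(y)) {
    st <- stack_slices(x)
    y <- if (task == "classification") st$flags else st$severities
    x <- st$x
  }
  x4 <- .as_x4(x)
  n <- dim(x4)[4]
  y <- as.matrix(y)
  k <- control$n_folds
  if (k > n) config_error("`n_folds` exceeds the dataset size")
  folds <- fold_assignment(n, k, control$seed)
  per_fold <- numeric(k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    val_idx <- which(folds == f)
    tr_idx <- which(folds != f)
    if (upsample && task == "classification") {
      key <- apply(y[tr_idx, , drop = FALSE], 1, paste, collapse = "")
      counts <- table(key)
      extra <- with_seed(control$seed + f, unlist(lapply(names(counts), function(kk) {
        need <- max(counts) - counts[[kk]]
        if (need == 0) integer(0) else sample(tr_idx[key == kk], need, TRUE)
      })))
      tr_idx <- c(tr_idx, extra)
    }
    fit <- rise_net(x4[, , 1, tr_idx, drop = TRUE], y[tr_idx, , drop = FALSE],
                    task = task, config = config, control = control)
    pred <- predict(fit, x4[, , 1, val_idx, drop = TRUE])
    if (task == "classification") {
      rep <- metrics_report(y[val_idx, , drop = FALSE], pred)
      per_fold[f] <- rep$exact_match_accuracy
    } else {
      rep <- severity_mse(y[val_idx, , drop = FALSE], pred)
      per_fold[f] <- rep$overall
    }
    reports[[f]] <- rep
  }
  structure(list(task = task, folds = folds, per_fold = per_fold,
                 reports = reports,
                 summary = c(mean = mean(per_fold), sd = sd(per_fold))),
            class = "rise_cv")
}

# Disjoint fold labels 1..k for n items, each item in exactly one fold,
# fold sizes differing by at most one.
fold_assignment <- function(n, k, seed) {
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' @export
print.rise_cv <- function(x, ...) {
  metric <- if (x$task == "classification") "exact-match accuracy" else "overall MSE"
  cat(sprintf("%d-fold cross-validation (%s)\n", length(x$per_fold), x$task))
  cat(sprintf("  per fold %s: %s\n", metric,
              paste(sprintf("%.4f", x$per_fold), collapse = " ")))
  cat(sprintf("  %s: %.4f +/- %.4f\n", metric, x$summary["mean"], x$summary["sd"]))
  invisible(x)
}
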