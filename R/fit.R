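#' Training configuration
#'
#' The published protocol is Adam with learning rate 1e-5 (other Adam
#' constants at their conventional defaults), 100 epochs, batch size 8 and
#' 5-fold cross-validation; these are the defaults here.  Early stopping is
#' off by default (the published runs completed all epochs).
#'
#' @param learning_rate Positive Adam step size.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param n_folds Folds for [cross_validate()]; at least 2.
#' @param seed Integer seed for shuffling, initialisation and dropout.
#' @param task `"classification"` or `"regression"`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 100L, batch_size = 8L,
                         n_folds = 5L, seed = 1L,
                         task = c("classification", "regression")) {
  task <- match.arg(task)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    config_error("`learning_rate` must be positive")
  if (!is_count(epochs) || !is_count(batch_size))
    config_error("`epochs` and `batch_size` must be positive integers")
  if (!is_count(n_folds) || n_folds < 2)
    config_error("`n_folds` must be an integer >= 2")
  structure(list(learning_rate = as.numeric(learning_rate),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 task = task),
            class = "train_config")
}

.as_x4 <- function(x, n_expected = NULL) {
  d <- dim(x)
  if (is.list(x)) {
    x <- stack_slices(x)$x
    d <- dim(x)
  }
  if (length(d) == 2L) x <- array(x, c(d, 1L))
  d <- dim(x)
  if (length(d) != 3L) value_error("`x` must be an [H, W, N] array of slices")
  array(x, c(d[1], d[2], 1L, d[3]))
}

#' Build an untrained artifact classifier
#'
#' Stem (conv/dropout/max-pool stages), the stack of RISE blocks, global
#' average pooling, a dense layer and a sigmoid head of `n_classes`
#' independent probabilities (multi-label: no normalisation across classes).
#'
#' @param config A [rise_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An untrained object of class `rise_net` (task
#'   `"classification"`); use [predict()] for forward passes and
#'   [rise_net()] to train.
#' @export
build_classifier <- function(config = rise_config(), seed = 1L) {
  new_rise_net(config, "classification", seed)
}

#' Build an untrained severity regressor
#'
#' Identical architecture to [build_classifier()] except the head: 3 linear
#' (unconstrained) severity outputs, no sigmoid.
#'
#' @inheritParams build_classifier
#' @return An untrained `rise_net` with task `"regression"`.
#' @export
build_regressor <- function(config = rise_config(), seed = 1L) {
  new_rise_net(config, "regression", seed)
}

new_rise_net <- function(config, task, seed) {
  if (!inherits(config, "rise_config"))
    config_error("`config` must be a rise_config object")
  structure(list(config = config, task = task,
                 params = .init_net(config, task, seed),
                 history = NULL, seed = as.integer(seed), trained = FALSE,
                 fitted.values = NULL, y = NULL, call = sys.call(-1)),
            class = "rise_net")
}

#' Fit a RISE network
#'
#' Trains an artifact classifier (4 sigmoid outputs, binary cross-entropy)
#' or severity regressor (3 linear outputs, mean squared error) with Adam,
#' recording per-epoch loss and metric traces for the training and, when
#' supplied, validation data.  The classification metric is exact-match
#' accuracy (a prediction counts as correct only when the whole thresholded
#' 4-flag vector matches); the regression metric is MSE.
#'
#' @param x Training slices: `[H, W, N]` array, or a list of
#'   [labeled_slice()] (labels are then taken from the slices and `y` may
#'   be omitted).
#' @param y Label matrix: `N x 4` binary flags (classification) or `N x 3`
#'   severities (regression).
#' @param task `"classification"` or `"regression"`.
#' @param config A [rise_config()]; its `input_size` must match `x`.
#' @param control A [train_config()]; its `task` field is ignored in favour
#'   of `task`.
#' @param validation Optional `list(x =, y =)` in the same format, used only
#'   for monitoring.
#' @param verbose Print per-epoch progress.
#' @return Object of class `rise_net` with components `params`, `config`,
#'   `task` and `history` (a data frame of per-epoch traces).  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @examples
#' \donttest{
#' d <- generate_dataset(24, phantom_spec(image_size = 32), seed = 1)
#' s <- stack_slices(d)
#' cfg <- rise_config(input_size = 32, stem_channels = 4, stem_stages = 1,
#'                    n_rise_blocks = 2, block_channels = c(8, 8),
#'                    dense_units = 16)
#' fit <- rise_net(s$x, s$flags, "classification", cfg,
#'                 train_config(learning_rate = 1e-3, epochs = 2))
#' predict(fit, s$x[, , 1:2])
#' }
#' @export
rise_net <- function(x, y = NULL, task = c("classification", "regression"),
                     config = rise_config(), control = train_config(),
                     validation = NULL, verbose = FALSE) {
  task <- match.arg(task)
  if (is.list(x) && is.null(y)) {
    st <- stack_slices(x)
    y <- if (task == "classification") st$flags else st$severities
    x <- st$x
  }
  x4 <- .as_x4(x)
  n <- dim(x4)[4]
  if (n == 0L) value_error("empty training set")
  y <- as.matrix(y)
  if (nrow(y) != n) value_error("`y` must have one row per slice")
  n_out <- if (task == "classification") config$n_classes else config$n_severities
  if (ncol(y) != n_out)
    value_error(sprintf("`y` must have %d columns for task '%s'", n_out, task))
  if (dim(x4)[1] != config$input_size || dim(x4)[2] != config$input_size)
    config_error(sprintf("slices are %dx%d but config$input_size is %d; resize first",
                         dim(x4)[1], dim(x4)[2], config$input_size))
  if (!is.null(validation)) {
    vx4 <- .as_x4(validation$x)
    vy <- as.matrix(validation$y)
    if (dim(vx4)[4] == 0L) value_error("empty validation set")
  }

  object <- new_rise_net(config, task, control$seed)
  object$call <- match.call()
  params <- object$params
  m <- .zeros_like(params)
  v <- .zeros_like(params)
  t_step <- 0L

  epoch_seeds <- derive_seeds(control$seed + 1L, control$epochs)
  hist_rows <- vector("list", control$epochs)
  n_steps <- 0L
  for (ep in seq_len(control$epochs)) {
    with_seed(epoch_seeds[ep], {
      order <- sample(n)
      ep_loss <- 0
      ep_n <- 0L
      for (start in seq(1, n, by = control$batch_size)) {
        idx <- order[start:min(start + control$batch_size - 1L, n)]
        xb <- x4[, , , idx, drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        fw <- .net_fwd(xb, params, config, task, train = TRUE)
        if (task == "classification") {
          loss <- bce_loss(fw$out, yb)
          dz2 <- (fw$out - yb) / length(yb)
        } else {
          loss <- mse_loss(fw$out, yb)
          dz2 <- 2 * (fw$out - yb) / length(yb)
        }
        if (!is.finite(loss))
          value_error(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        bw <- .net_bwd(dz2, fw$cache, params, config)
        t_step <- t_step + 1L
        upd <- .adam_update(params, bw$grads, m, v, t_step,
                            control$learning_rate)
        params <- upd$p
        m <- upd$m
        v <- upd$v
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
        n_steps <- n_steps + 1L
      }
    })
    tr <- .eval_net(params, config, task, x4, y)
    row <- data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                      train_metric = tr$metric)
    if (!is.null(validation)) {
      vl <- .eval_net(params, config, task, vx4, vy)
      row$val_loss <- vl$loss
      row$val_metric <- vl$metric
    }
    hist_rows[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  metric %.4f%s", ep,
                      row$train_loss, row$train_metric,
                      if (!is.null(validation))
                        sprintf("  val %.4f", row$val_metric) else ""))
  }
  object$params <- params
  object$history <- do.call(rbind, hist_rows)
  object$n_steps <- n_steps
  object$trained <- TRUE
  object$y <- y
  object$fitted.values <- .predict_params(params, config, task, x4)
  object
}

# Chunked inference forward pass.
.predict_params <- function(params, config, task, x4, chunk = 32L) {
  n <- dim(x4)[4]
  out <- NULL
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- .net_fwd(x4[, , , idx, drop = FALSE], params, config, task,
                   train = FALSE)
    out <- rbind(out, fw$out)
  }
  colnames(out) <- if (task == "classification")
    c("motion", "chemical_shift", "radiofrequency", "normal")[seq_len(ncol(out))]
  else c("motion", "chemical_shift", "radiofrequency")[seq_len(ncol(out))]
  out
}

.eval_net <- function(params, config, task, x4, y) {
  pred <- .predict_params(params, config, task, x4)
  if (task == "classification") {
    list(loss = bce_loss(pred, y),
         metric = exact_match_accuracy(y, binarize(pred)))
  } else {
    list(loss = mse_loss(pred, y), metric = mse_loss(pred, y))
  }
}

#' Predict from a fitted (or freshly built) RISE network
#'
#' @param object A `rise_net`.
#' @param newdata Slices as an `[H, W, N]` array, a single `H x W` matrix,
#'   or a list of [labeled_slice()].
#' @param ... Unused.
#' @return `N x 4` matrix of independent per-artifact probabilities
#'   (classification) or `N x 3` matrix of raw severities (regression;
#'   unconstrained — clamped to `[0, 3]` only at report time, see
#'   [make_report()]).
#' @export
predict.rise_net <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata[[1]]$image))
    newdata <- stack_slices(newdata)$x
  x4 <- .as_x4(newdata)
  if (dim(x4)[1] != object$config$input_size)
    config_error("newdata size does not match the network input size; resize first")
  .predict_params(object$params, object$config, object$task, x4)
}

#' @export
print.rise_net <- function(x, ...) {
  cat(sprintf("RISE %s network (%s)\n",
              if (x$task == "classification") "artifact classification"
              else "severity regression",
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %s parameters; input %dx%d; %d RISE blocks (g = %d)\n",
              format(.n_params(x$params), big.mark = ","),
              x$config$input_size, x$config$input_size,
              x$config$n_rise_blocks, x$config$se_ratio))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epochs: train loss %.5f, train %s %.4f\n",
                nrow(x$history), last$train_loss,
                if (x$task == "classification") "exact-match" else "MSE",
                last$train_metric))
  }
  invisible(x)
}

#' @export
summary.rise_net <- function(object, ...) {
  print(object)
  print(object$config)
  if (!is.null(object$history)) {
    cat("history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.rise_net <- function(object, ...) object$params

#' @export
residuals.rise_net <- function(object, ...) {
  if (!object$trained) value_error("network is untrained; no residuals")
  object$y - object$fitted.values
}

#' Plot training history
#'
#' Loss (and, when recorded, validation loss) against epoch.
#'
#' @param x A trained `rise_net`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rise_net <- function(x, ...) {
  if (is.null(x$history)) value_error("no training history to plot")
  h <- x$history
  cols <- intersect(c("train_loss", "val_loss"), names(h))
  graphics::matplot(h$epoch, as.matrix(h[cols]), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}

#' Save / load a fitted network
#'
#' The weights go into an RDS container and the architecture configuration
#' into a JSON sidecar (`<path>.json`), so a checkpoint is self-describing.
#'
#' @param object A `rise_net`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `rise_net` (load).
#' @export
save_rise_net <- function(object, path) {
  saveRDS(object, path)
  cfgj <- c(unclass(object$config), list(task = object$task))
  jsonlite::write_json(cfgj, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_rise_net
#' @export
load_rise_net <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "rise_net")) value_error("file does not contain a rise_net")
  obj
}
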