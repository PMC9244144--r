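#' Binary cross-entropy over independent output nodes
#'
#' Mean over nodes of \eqn{-[y \log p + (1-y)\log(1-p)]}, the multi-label
#' loss paired with the classifier's sigmoid head (every node is an
#' independent binary problem).  Probabilities are clamped to
#' `[eps, 1 - eps]` for numerical stability.
#'
#' @param pred Numeric probabilities (vector or matrix, values in `[0, 1]`).
#' @param truth Binary flags, same shape.
#' @param eps Clamping constant.
#' @return Nonnegative scalar.
#' @examples
#' bce_loss(rep(0.5, 4), c(1, 0, 1, 0))  # log(2)
#' @export
bce_loss <- function(pred, truth, eps = 1e-7) {
  if (length(pred) != length(truth))
    value_error("`pred` and `truth` must have equal length")
  if (any(pred < 0 | pred > 1))
    value_error("`pred` must contain probabilities in [0, 1]")
  p <- pmin(pmax(pred, eps), 1 - eps)
  mean(-(truth * log(p) + (1 - truth) * log(1 - p)))
}

#' Mean squared error
#'
#' Mean of squared differences between predicted and true severities.
#'
#' @param pred,truth Numeric vectors/matrices of equal shape.
#' @return Nonnegative scalar; 0 iff `pred == truth`.
#' @export
mse_loss <- function(pred, truth) {
  if (length(pred) != length(truth))
    value_error("`pred` and `truth` must have equal length")
  mean((pred - truth)^2)
}
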