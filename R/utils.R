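#' @useDynLib riseqc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis runif rnorm sd predict coef residuals
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Condition helpers: configuration errors (bad specs/configs) vs value errors
# (bad data passed to an operation).  Both carry "riseqc_error".
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("riseqc_config_error", "riseqc_error", "error")))
}

value_error <- function(msg) {
  stop(errorCondition(msg, class = c("riseqc_value_error", "riseqc_error", "error")))
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream.  Everything stochastic in the package funnels through this, which
# is what makes (spec, recipe, seed) fully determine every output bit.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Fan one user-facing seed out into k independent sub-seeds (one flag
# controls full reproducibility; sub-seeds stay below 2^31 - 1).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(2147483646L, k, replace = FALSE))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
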