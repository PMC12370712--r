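# Internal helpers shared across the package.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so that
# (seed, config, data) fully determines the output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Elementwise nonlinearities
#'
#' `sigmoid()` is the logistic squashing function used by the adaptive
#' retention gate; `relu()` is the rectifier used between the fully
#' connected layers.
#'
#' @param x numeric vector or matrix.
#' @return Object of the same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname sigmoid
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Numerically stable row-wise softmax.
softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
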