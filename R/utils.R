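#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @keywords internal
geomean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

## stop() with a consistent prefix so callers can grep error classes
abort_format <- function(msg) stop("format error: ", msg, call. = FALSE)
abort_config <- function(msg) stop("configuration error: ", msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

#' Derive a reproducible child seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range whatever the base is.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
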