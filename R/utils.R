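# Internal helpers shared across modules.

#' @importFrom stats rnbinom rbeta rexp runif median sd setNames
#' @importFrom utils read.table write.table head
NULL

ds_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

ds_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

#' Quantize scores to 4 decimal places
#'
#' Fixed-point quantization used throughout score tracks so that values
#' round-trip bit-exactly through their text serialization.
#'
#' @param x numeric vector in `[0, 1]`.
#' @return numeric vector, each value an exact multiple of 1e-4.
#' @keywords internal
quantize_score <- function(x) {
  round(x * 1e4) / 1e4
}

# Lexicographic row order of a numeric matrix; makes seeded sampling
# invariant to the order training rows arrive in.
canonical_row_order <- function(mat) {
  do.call(order, as.data.frame(mat))
}

# Clamp into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
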