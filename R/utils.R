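#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used when converting per-segment log2 ratios into integer
#' copy-number differences. (Base `round()` rounds half to even.)
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_away(c(0.5, -0.5, 1.49))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Draw n sub-seeds (< 2^31) from the current stream; used to give each
# sample/curve its own reproducible substream.
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

assert_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
  invisible(as.integer(x))
}

assert_nonneg <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name))
  }
  invisible(as.numeric(x))
}

new_result_tbl <- function(x, subclass) {
  structure(x, class = c(subclass, class(tibble())))
}
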