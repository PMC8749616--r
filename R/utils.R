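#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.5 -> 1, -0.5 -> -1, 0.125 -> 0.13 at two digits), the rounding
#' convention used throughout the pipeline for gray levels and reported
#' accuracy metrics. Base [round()] rounds half to even and is not used
#' for reported values.
#'
#' @param x numeric vector or matrix.
#' @param digits number of decimal places (default 0).
#' @return numeric of the same shape as `x`.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))   # 1  2 -1
#' round_half_away(0.125, 2)            # 0.13
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
is_rgb_array <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
}

assert_rgb <- function(img) {
  if (!is_rgb_array(img)) {
    stop("input must be an 8-bit RGB image: numeric H x W x 3 array with values in 0..255",
         call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 255) {
    stop("RGB values must lie in [0, 255]", call. = FALSE)
  }
  invisible(img)
}
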