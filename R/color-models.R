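#' Color-transform configuration
#'
#' Controls the RGB-to-component conversions. `theta` is the intensity
#' offset added to the chrominance numerators so that each component's
#' full range maps onto `[0, 255]`; for 8-bit images theta = 2^8 - 1 = 255
#' is the only value with that property. `corrected_signs` selects the
#' internally consistent reading of the Q and H/S chroma terms
#' (B coefficient of Q positive, R coefficient of the v chroma positive),
#' under which the chroma terms cancel exactly on the gray axis; setting
#' it to `FALSE` applies the literal textbook-transcription signs for
#' comparison.
#'
#' @param theta intensity offset (default 255).
#' @param corrected_signs use the gray-axis-consistent sign reading
#'   (default `TRUE`).
#' @param rounding `"half_away"` (default) or `"floor"`.
#' @return an object of class `color_config`.
#' @export
color_config <- function(theta = 255, corrected_signs = TRUE,
                         rounding = c("half_away", "floor")) {
  stopifnot_scalar_number(theta, "theta")
  if (theta <= 0) stop("`theta` must be positive", call. = FALSE)
  rounding <- match.arg(rounding)
  structure(list(theta = theta, corrected_signs = corrected_signs,
                 rounding = rounding),
            class = "color_config")
}

quantize_plane <- function(x, cfg) {
  x <- if (cfg$rounding == "floor") floor(x) else round_half_away(x)
  clip_range(x, 0, 255)
}

component_plane <- function(values, id) {
  structure(list(values = values, component_id = id), class = "component_plane")
}

#' @export
print.component_plane <- function(x, ...) {
  cat(sprintf("<component_plane %s: %d x %d, range %d..%d>\n",
              x$component_id, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

chan <- function(img, k) {
  matrix(img[, , k], dim(img)[1], dim(img)[2])
}

#' Split an RGB image into its R, G, B planes
#'
#' The three primaries are taken channel-wise without any conversion.
#'
#' @param image numeric H x W x 3 array with values in 0..255.
#' @return named list of three `component_plane` objects (`R`, `G`, `B`).
#' @export
split_rgb <- function(image) {
  assert_rgb(image)
  list(R = component_plane(chan(image, 1), "R"),
       G = component_plane(chan(image, 2), "G"),
       B = component_plane(chan(image, 3), "B"))
}

#' Luma and chrominance component planes
#'
#' Per-pixel integer transforms from RGB to the brightness (Y) and
#' chrominance components of the YUV and YIQ models and the hue/saturation
#' components of the HSB model:
#' \deqn{Y = (299R + 587G + 114B)/1000}
#' \deqn{U = (886B - 587G - 299R + 886\Theta)/1772}
#' \deqn{V = (-114B - 587G + 701R + 701\Theta)/1402}
#' \deqn{I = (-3213B - 2744G + 5957R + 5958\Theta)/11916}
#' \deqn{Q = (3111B - 5226G + 2115R + 5226\Theta)/10452}
#' H and S are derived from the centered chroma pair
#' \eqn{u = (886B - 587G - 299R)/886}, \eqn{v = (701R - 587G - 114B)/701}:
#' \eqn{H = \Theta\,\mathrm{arg}(u + jv)/2\pi} with the argument in
#' \eqn{[0, 2\pi)} and achromatic pixels mapped to 0, and
#' \eqn{S = 0.937\sqrt{u^2 + v^2}} (0.937 normalises the maximum-chroma
#' magenta corner to 255). All planes are rounded and clipped to `[0, 255]`.
#'
#' @param image numeric H x W x 3 RGB array, values 0..255.
#' @param cfg a [color_config()].
#' @return a `component_plane`.
#' @name chrominance
NULL

#' @rdname chrominance
#' @export
to_Y <- function(image, cfg = color_config()) {
  assert_rgb(image)
  y <- (299 * chan(image, 1) + 587 * chan(image, 2) + 114 * chan(image, 3)) / 1000
  component_plane(quantize_plane(y, cfg), "Y")
}

#' @rdname chrominance
#' @export
to_U <- function(image, cfg = color_config()) {
  assert_rgb(image)
  u <- (886 * chan(image, 3) - 587 * chan(image, 2) - 299 * chan(image, 1) +
          886 * cfg$theta) / 1772
  component_plane(quantize_plane(u, cfg), "U")
}

#' @rdname chrominance
#' @export
to_V <- function(image, cfg = color_config()) {
  assert_rgb(image)
  v <- (-114 * chan(image, 3) - 587 * chan(image, 2) + 701 * chan(image, 1) +
          701 * cfg$theta) / 1402
  component_plane(quantize_plane(v, cfg), "V")
}

#' @rdname chrominance
#' @export
to_I <- function(image, cfg = color_config()) {
  assert_rgb(image)
  i <- (-3213 * chan(image, 3) - 2744 * chan(image, 2) + 5957 * chan(image, 1) +
          5958 * cfg$theta) / 11916
  component_plane(quantize_plane(i, cfg), "I")
}

#' @rdname chrominance
#' @export
to_Q <- function(image, cfg = color_config()) {
  assert_rgb(image)
  b_sign <- if (cfg$corrected_signs) 3111 else -3111
  q <- (b_sign * chan(image, 3) - 5226 * chan(image, 2) + 2115 * chan(image, 1) +
          5226 * cfg$theta) / 10452
  component_plane(quantize_plane(q, cfg), "Q")
}

chroma_uv <- function(image, cfg) {
  r_sign <- if (cfg$corrected_signs) 701 else -701
  list(u = (886 * chan(image, 3) - 587 * chan(image, 2) - 299 * chan(image, 1)) / 886,
       v = (r_sign * chan(image, 1) - 587 * chan(image, 2) - 114 * chan(image, 3)) / 701)
}

#' @rdname chrominance
#' @export
to_H <- function(image, cfg = color_config()) {
  assert_rgb(image)
  uv <- chroma_uv(image, cfg)
  ang <- atan2(uv$v, uv$u)
  ang[ang < 0] <- ang[ang < 0] + 2 * pi
  ang[uv$u == 0 & uv$v == 0] <- 0
  component_plane(quantize_plane(cfg$theta * ang / (2 * pi), cfg), "H")
}

#' @rdname chrominance
#' @export
to_S <- function(image, cfg = color_config()) {
  assert_rgb(image)
  uv <- chroma_uv(image, cfg)
  s <- 0.937 * sqrt(uv$u^2 + uv$v^2)
  component_plane(quantize_plane(s, cfg), "S")
}

#' All ten color-component planes
#'
#' Decomposes an RGB thermogram into the ten grayscale component planes
#' used for texture extraction: the three primaries (R, G, B), the shared
#' brightness plane Y, the YUV chrominance planes U and V, the YIQ
#' chrominance planes I and Q, and the HSB hue and saturation planes
#' (brightness in HSB equals Y and is not duplicated).
#'
#' @inheritParams to_Y
#' @return named list of 10 `component_plane` objects, in the order
#'   R, G, B, Y, U, V, I, Q, H, S.
#' @export
#' @examples
#' img <- array(128, dim = c(4, 4, 3))
#' names(transform_all(img))
transform_all <- function(image, cfg = color_config()) {
  assert_rgb(image)
  c(split_rgb(image),
    list(Y = to_Y(image, cfg), U = to_U(image, cfg), V = to_V(image, cfg),
         I = to_I(image, cfg), Q = to_Q(image, cfg),
         H = to_H(image, cfg), S = to_S(image, cfg)))
}

#' Canonical component identifiers
#'
#' @return character vector of the ten component ids in pipeline order.
#' @export
component_ids <- function() c("R", "G", "B", "Y", "U", "V", "I", "Q", "H", "S")
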