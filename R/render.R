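#' Parula-style colormap
#'
#' A 128-level perceptually ordered blue-green-yellow colormap built by
#' piecewise-linear interpolation of 16 anchor colors, matching the look
#' of the colormap conventionally used to display scalograms.
#'
#' @param n number of levels (default 128).
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
parula_colors <- function(n = 128) {
  anchors <- matrix(c(
    0.2422, 0.1504, 0.6603,
    0.2667, 0.2028, 0.8087,
    0.2786, 0.2668, 0.9221,
    0.2710, 0.3301, 0.9832,
    0.2441, 0.3919, 0.9983,
    0.2005, 0.4556, 0.9828,
    0.1574, 0.5185, 0.9417,
    0.1319, 0.5768, 0.8914,
    0.1060, 0.6301, 0.8393,
    0.0771, 0.6796, 0.7858,
    0.0498, 0.7295, 0.7076,
    0.1545, 0.7740, 0.5970,
    0.3597, 0.8060, 0.4464,
    0.6048, 0.8180, 0.2937,
    0.8389, 0.8166, 0.1890,
    0.9763, 0.9831, 0.0538
  ), ncol = 3, byrow = TRUE)
  xi <- seq(0, 1, length.out = nrow(anchors))
  xo <- seq(0, 1, length.out = n)
  cbind(
    stats::approx(xi, anchors[, 1], xo)$y,
    stats::approx(xi, anchors[, 2], xo)$y,
    stats::approx(xi, anchors[, 3], xo)$y
  )
}

# separable bilinear resize of a matrix to (h, w)
bilinear_resize <- function(m, h, w) {
  src_h <- nrow(m); src_w <- ncol(m)
  yi <- if (h == 1) 1 else seq(1, src_h, length.out = h)
  xi <- if (w == 1) 1 else seq(1, src_w, length.out = w)
  y0 <- pmin(floor(yi), src_h - 1L); fy <- yi - y0
  x0 <- pmin(floor(xi), src_w - 1L); fx <- xi - x0
  if (src_h == 1) { y0 <- rep(1, h); fy <- rep(0, h) }
  if (src_w == 1) { x0 <- rep(1, w); fx <- rep(0, w) }
  a <- m[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx)) +
    m[pmin(y0 + 1, src_h), x0, drop = FALSE] * (fy %o% (1 - fx)) +
    m[y0, pmin(x0 + 1, src_w), drop = FALSE] * ((1 - fy) %o% fx) +
    m[pmin(y0 + 1, src_h), pmin(x0 + 1, src_w), drop = FALSE] * (fy %o% fx)
  a
}

#' Render a scalogram as an image tensor
#'
#' Min-max normalizes the magnitude to `[0, 1]` per segment and resizes
#' (bilinear) to the requested shape. `GRAY_1CH` returns an
#' `H x W x 1` tensor (default 600 x 800, the custom CNN's input);
#' `PARULA_RGB` maps values through a 128-level parula-style lookup and
#' returns `H x W x 3` (default 224 x 224, the transfer-learning input).
#'
#' @param scalogram a `scalogram`.
#' @param mode `"GRAY_1CH"` or `"PARULA_RGB"`.
#' @param out_shape `(H, W)`; defaults depend on `mode`.
#' @return numeric array `H x W x 1` or `H x W x 3` with values in
#'   `[0, 1]`. An all-constant scalogram degenerates to an all-zero
#'   image with a warning.
#' @export
render_image <- function(scalogram, mode = c("GRAY_1CH", "PARULA_RGB"),
                         out_shape = NULL) {
  stopifnot(inherits(scalogram, "scalogram"))
  mode <- match.arg(mode)
  if (is.null(out_shape)) {
    out_shape <- if (mode == "GRAY_1CH") c(600, 800) else c(224, 224)
  }
  stopifnot(length(out_shape) == 2, all(out_shape >= 1))
  m <- scalogram$magnitude
  rng <- range(m)
  if (diff(rng) == 0) {
    warn("all-constant scalogram; returning an all-zero image")
    norm <- matrix(0, nrow(m), ncol(m))
  } else {
    norm <- (m - rng[1]) / diff(rng)
  }
  r <- bilinear_resize(norm, out_shape[1], out_shape[2])
  r <- pmin(pmax(r, 0), 1)
  if (mode == "GRAY_1CH") {
    array(r, dim = c(out_shape, 1))
  } else {
    pal <- parula_colors(128)
    idx <- pmin(floor(r * 128) + 1, 128)
    out <- array(0, dim = c(out_shape, 3))
    for (c3 in 1:3) out[, , c3] <- matrix(pal[idx, c3], out_shape[1])
    out
  }
}
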