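#' Layer specifications
#'
#' Lightweight, framework-independent layer descriptions used by the
#' shape/parameter calculator and the built-in trainer. All convolutions
#' and poolings use VALID padding (no zero padding).
#'
#' @param filters number of convolution filters.
#' @param kernel_hw kernel size `(kh, kw)`.
#' @param stride_hw stride `(sh, sw)`; pooling defaults to its kernel.
#' @param fun activation name (`"relu"` or `"sigmoid"`).
#' @param units dense layer width.
#' @return a `layer_spec` list.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
conv2d_layer <- function(filters, kernel_hw, stride_hw = c(1, 1)) {
  stopifnot(filters >= 1, all(kernel_hw >= 1), all(stride_hw >= 1))
  structure(list(kind = "CONV2D", filters = filters,
                 kernel_hw = as.integer(kernel_hw),
                 stride_hw = as.integer(stride_hw), padding = "VALID"),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
activation_layer <- function(fun = "relu") {
  stopifnot(fun %in% c("relu", "sigmoid"))
  structure(list(kind = "ACTIVATION", fun = fun), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
maxpool2d_layer <- function(kernel_hw, stride_hw = kernel_hw) {
  stopifnot(all(kernel_hw >= 1), all(stride_hw >= 1))
  structure(list(kind = "MAXPOOL2D", kernel_hw = as.integer(kernel_hw),
                 stride_hw = as.integer(stride_hw), padding = "VALID"),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
flatten_layer <- function() {
  structure(list(kind = "FLATTEN"), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
dense_layer <- function(units) {
  stopifnot(units >= 1)
  structure(list(kind = "DENSE", units = as.integer(units)),
            class = "layer_spec")
}

new_architecture_spec <- function(input_hwc, layers) {
  structure(list(input_hwc = as.integer(input_hwc), layers = layers),
            class = "architecture_spec")
}

#' The custom scalogram CNN architecture
#'
#' The compact 2-D CNN used for single-channel scalogram images:
#' Conv(5, 3x3) - ReLU - Conv(5, 2x2) - ReLU - MaxPool(2x2, stride 2) -
#' Conv(5, 3x3) - ReLU - Conv(5, 5x5) - ReLU - MaxPool(5x5, stride 5) -
#' Flatten - Dense(256) - ReLU - Dense(32) - ReLU - Dense(1) - sigmoid,
#' VALID padding throughout. At the default 600 x 800 x 1 input the
#' parameter total is 5,800,248; the input may be scaled down (e.g.
#' 60 x 80) for desk-scale training, with shapes re-inferred.
#'
#' @param input_hwc input shape `(H, W, C)`; default `c(600, 800, 1)`.
#' @return an `architecture_spec`.
#' @examples
#' spec <- build_custom_architecture()
#' glance(spec)$total_params  # 5800248
#' @export
build_custom_architecture <- function(input_hwc = c(600, 800, 1)) {
  new_architecture_spec(input_hwc, list(
    conv2d_layer(5, c(3, 3)),
    activation_layer("relu"),
    conv2d_layer(5, c(2, 2)),
    activation_layer("relu"),
    maxpool2d_layer(c(2, 2)),
    conv2d_layer(5, c(3, 3)),
    activation_layer("relu"),
    conv2d_layer(5, c(5, 5)),
    activation_layer("relu"),
    maxpool2d_layer(c(5, 5)),
    flatten_layer(),
    dense_layer(256),
    activation_layer("relu"),
    dense_layer(32),
    activation_layer("relu"),
    dense_layer(1),
    activation_layer("sigmoid")
  ))
}

#' Infer per-layer output shapes and parameter counts
#'
#' Pure integer arithmetic, independent of any training framework:
#' VALID convolution output is `(H - kh)/sh + 1` (floored), pooling the
#' same; convolution parameters are `kh*kw*C_in*filters + filters`;
#' dense parameters are `in*units + units`; activation, pooling and
#' flatten carry none.
#'
#' @param spec an `architecture_spec`.
#' @return tibble with one row per layer: `layer`, `kind`,
#'   `output_shape` (string `HxWxC` or unit count), `out_h`, `out_w`,
#'   `out_c`, `params`; total in attribute `total_params` (also via
#'   [glance()]).
#' @export
infer_shapes_and_params <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  h <- spec$input_hwc[1]; w <- spec$input_hwc[2]; c_in <- spec$input_hwc[3]
  flat <- NA_integer_
  rows <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    params <- 0L
    switch(ly$kind,
      CONV2D = {
        kh <- ly$kernel_hw[1]; kw <- ly$kernel_hw[2]
        sh <- ly$stride_hw[1]; sw <- ly$stride_hw[2]
        nh <- floor((h - kh) / sh) + 1
        nw <- floor((w - kw) / sw) + 1
        if (nh < 1 || nw < 1) {
          abort(sprintf("layer %d (%s): output shape underflow", i, ly$kind),
                class = "cardiowave_shape_underflow")
        }
        params <- kh * kw * c_in * ly$filters + ly$filters
        h <- nh; w <- nw; c_in <- ly$filters
      },
      MAXPOOL2D = {
        kh <- ly$kernel_hw[1]; kw <- ly$kernel_hw[2]
        sh <- ly$stride_hw[1]; sw <- ly$stride_hw[2]
        nh <- floor((h - kh) / sh) + 1
        nw <- floor((w - kw) / sw) + 1
        if (nh < 1 || nw < 1) {
          abort(sprintf("layer %d (%s): output shape underflow", i, ly$kind),
                class = "cardiowave_shape_underflow")
        }
        h <- nh; w <- nw
      },
      ACTIVATION = NULL,
      FLATTEN = {
        if (is.na(flat)) {
          flat <- h * w * c_in
        }
      },
      DENSE = {
        d_in <- if (!is.na(flat)) flat else h * w * c_in
        params <- d_in * ly$units + ly$units
        flat <- ly$units
      }
    )
    rows[[i]] <- tibble(
      layer = i,
      kind = ly$kind,
      output_shape = if (!is.na(flat)) as.character(flat) else
        sprintf("%dx%dx%d", h, w, c_in),
      out_h = if (!is.na(flat)) NA_integer_ else as.integer(h),
      out_w = if (!is.na(flat)) NA_integer_ else as.integer(w),
      out_c = if (!is.na(flat)) as.integer(flat) else as.integer(c_in),
      params = as.integer(params)
    )
  }
  out <- bind_rows(rows)
  attr(out, "total_params") <- sum(out$params)
  class(out) <- c("architecture_summary", class(out))
  out
}

#' @export
tidy.architecture_spec <- function(x, ...) {
  infer_shapes_and_params(x)
}

#' @export
glance.architecture_spec <- function(x, ...) {
  s <- infer_shapes_and_params(x)
  tibble(n_layers = length(x$layers),
         total_params = attr(s, "total_params"))
}

#' @export
print.architecture_spec <- function(x, ...) {
  s <- infer_shapes_and_params(x)
  cat(sprintf("<architecture_spec> input %s\n",
              paste(x$input_hwc, collapse = "x")))
  print(as_tibble(s), n = Inf)
  cat(sprintf("Total parameters: %s\n",
              format(attr(s, "total_params"), big.mark = ",")))
  invisible(x)
}

#' Classification head for a pretrained backbone
#'
#' The three appended layers used for transfer learning on scalogram
#' images: two fully connected layers and a final single-unit sigmoid
#' layer. Backbone weights are external and never bundled.
#'
#' @param backbone_output_dim flattened output width of the backbone.
#' @param d1,d2 hidden widths (defaults 256 and 32, mirroring the custom
#'   CNN's dense stack).
#' @return an `architecture_spec` whose input is the backbone output
#'   vector.
#' @examples
#' glance(build_transfer_head(1024))$total_params
#' @export
build_transfer_head <- function(backbone_output_dim, d1 = 256, d2 = 32) {
  stopifnot(backbone_output_dim > 0, d1 >= 1, d2 >= 1)
  new_architecture_spec(c(1, 1, backbone_output_dim), list(
    flatten_layer(),
    dense_layer(d1),
    activation_layer("relu"),
    dense_layer(d2),
    activation_layer("relu"),
    dense_layer(1),
    activation_layer("sigmoid")
  ))
}
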