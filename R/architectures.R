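layer_spec <- function(kind, filter_size = NA_integer_, num_filters = NA_integer_,
                       stride = 1L, groups = 1L, out_units = NA_integer_,
                       slope = 0.01, prob = 0.5) {
  if (stride < 1) abort("`stride` must be >= 1.")
  if (groups < 1) abort("`groups` must be >= 1.")
  if (kind == "grouped_conv" && !is.na(num_filters) && num_filters %% groups != 0) {
    abort("Grouped convolution requires `num_filters` divisible by `groups`.")
  }
  list(kind = kind, filter_size = as.integer(filter_size),
       num_filters = as.integer(num_filters), stride = as.integer(stride),
       groups = as.integer(groups), out_units = as.integer(out_units),
       slope = slope, prob = prob)
}

conv_l <- function(f, n, stride = 1L, groups = 1L) {
  layer_spec(if (groups > 1) "grouped_conv" else "conv", f, n, stride, groups)
}
pool_l <- function(p) layer_spec("max_pool", p, stride = p)
relu_l <- function() layer_spec("relu")
lrelu_l <- function(slope = 0.01) layer_spec("leaky_relu", slope = slope)
drop_l <- function(prob = 0.5) layer_spec("dropout", prob = prob)
fc_l <- function(units) layer_spec("fully_connected", out_units = units)

new_architecture <- function(id, layers, embedding_dim, input_size = 224,
                             name = paste0("network_", id)) {
  structure(
    list(id = id, name = name, input_size = as.integer(input_size),
         layers = layers, embedding_dim = as.integer(embedding_dim)),
    class = "snn_architecture"
  )
}

#' @export
print.snn_architecture <- function(x, ...) {
  cat(sprintf("<snn_architecture> %s: input %d x %d, embedding %d, %d layers\n",
              x$name, x$input_size, x$input_size, x$embedding_dim,
              length(x$layers)))
  print(architecture_table(x), n = Inf)
  invisible(x)
}

#' Catalogue of the eight Siamese backbone architectures
#'
#' Returns the layer sequences of the eight convolutional backbones used as
#' twin subnetworks. Convolutions use valid (no-padding) arithmetic; strides
#' are 1 except the first convolution of network 3 and the second of network 5
#' (stride 4), and the third of network 5 (stride 2); pooling stride equals
#' the pool size. The grouped convolutions of network 8 use 2 groups. The
#' embedding (final fully-connected) dimension is 2048 for network 2 and 4096
#' otherwise.
#'
#' @param id Backbone id in 1..8; `NULL` returns the list of all eight.
#' @param input_size Input side in pixels (default 224).
#' @return An `snn_architecture`, or a list of eight when `id` is `NULL`.
#' @export
snn_architecture <- function(id = NULL, input_size = 224) {
  if (is.null(id)) {
    return(lapply(1:8, snn_architecture, input_size = input_size))
  }
  if (!id %in% 1:8) abort("`id` must be in 1..8.")
  layers <- switch(as.character(id),
    "1" = list(conv_l(10, 64), relu_l(), pool_l(2),
               conv_l(7, 128), relu_l(), pool_l(2),
               conv_l(4, 128), relu_l(), pool_l(2),
               conv_l(5, 64), relu_l(), fc_l(4096)),
    "2" = list(conv_l(5, 64), lrelu_l(), conv_l(5, 64), lrelu_l(), pool_l(2),
               conv_l(3, 128), lrelu_l(), conv_l(3, 128), lrelu_l(), pool_l(2),
               conv_l(4, 128), lrelu_l(), pool_l(2),
               conv_l(5, 64), lrelu_l(), fc_l(2048)),
    "3" = list(conv_l(7, 128, stride = 4), pool_l(2),
               conv_l(5, 256), relu_l(),
               conv_l(5, 128), pool_l(2),
               conv_l(3, 64), relu_l(), pool_l(2), fc_l(4096)),
    "4" = list(conv_l(7, 128), pool_l(4), relu_l(),
               conv_l(5, 256), relu_l(),
               conv_l(3, 64), pool_l(2),
               conv_l(3, 128), relu_l(),
               conv_l(5, 64), fc_l(4096)),
    "5" = list(conv_l(10, 64), pool_l(2), relu_l(),
               conv_l(7, 128, stride = 4), relu_l(),
               conv_l(5, 128, stride = 2), relu_l(),
               conv_l(4, 64), relu_l(), fc_l(4096)),
    "6" = list(conv_l(7, 64), pool_l(2), relu_l(),
               conv_l(3, 128), pool_l(2), relu_l(),
               conv_l(1, 64), relu_l(),
               conv_l(3, 128), relu_l(), pool_l(2),
               conv_l(1, 128), relu_l(),
               conv_l(4, 64), pool_l(2), relu_l(), fc_l(4096)),
    "7" = list(drop_l(0.5), conv_l(7, 64), pool_l(2),
               conv_l(5, 128), pool_l(2),
               conv_l(5, 64), pool_l(2),
               conv_l(3, 256), pool_l(2),
               conv_l(3, 256), fc_l(4096)),
    "8" = list(conv_l(10, 32), pool_l(2), relu_l(),
               conv_l(7, 64, groups = 2), conv_l(5, 128), pool_l(2), relu_l(),
               conv_l(3, 256, groups = 2), fc_l(4096))
  )
  embedding <- if (id == 2) 2048L else 4096L
  new_architecture(id, layers, embedding, input_size)
}

#' Activation shapes of an architecture
#'
#' Walks the layer sequence with valid-convolution arithmetic
#' `out = floor((in - filter) / stride) + 1` (pooling uses the same rule) and
#' returns the output shape after every layer.
#'
#' @param arch An `snn_architecture`.
#' @param input_size Optional input side overriding the architecture's.
#' @return Tibble with one row per layer (input layer included): `layer`,
#'   `kind`, `out_h`, `out_w`, `channels` (`NA` for the fully-connected
#'   output, reported in `units`).
#' @export
infer_shapes <- function(arch, input_size = NULL) {
  stopifnot(inherits(arch, "snn_architecture"))
  side <- as.integer(input_size %||% arch$input_size)
  ch <- 1L
  rows <- list(tibble(layer = 0L, kind = "input", out_h = side, out_w = side,
                      channels = ch, units = NA_integer_))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    units <- NA_integer_
    if (l$kind %in% c("conv", "grouped_conv", "max_pool")) {
      if (side < l$filter_size) {
        abort(sprintf("Layer %d (%s %dx%d) does not fit input %d.",
                      i, l$kind, l$filter_size, l$filter_size, side))
      }
      side <- (side - l$filter_size) %/% l$stride + 1L
      if (side < 1) abort(sprintf("Layer %d collapses the spatial extent.", i))
      if (l$kind != "max_pool") ch <- l$num_filters
    } else if (l$kind == "fully_connected") {
      units <- l$out_units
      side <- NA_integer_
      ch <- NA_integer_
    }
    rows[[i + 1L]] <- tibble(layer = i, kind = l$kind, out_h = side,
                             out_w = side, channels = ch, units = units)
  }
  dplyr::bind_rows(rows)
}

#' Learnable-parameter count of a single layer
#'
#' Convolution: `f^2 * (c_in / groups) * n_filters + n_filters` (weights plus
#' biases); fully connected: `in_shape^2 * c_in * out_units + out_units`;
#' activation, pooling and dropout layers have no learnable parameters.
#'
#' @param layer A layer spec from an `snn_architecture`'s `layers` list.
#' @param in_channels Input channel count.
#' @param in_shape Input spatial side in pixels (needed for fully connected).
#' @return Parameter count (double, to hold counts above 2^31).
#' @export
count_parameters <- function(layer, in_channels, in_shape = NA) {
  kind <- layer$kind
  if (kind %in% c("conv", "grouped_conv")) {
    f <- as.numeric(layer$filter_size)
    n <- as.numeric(layer$num_filters)
    f * f * (in_channels / layer$groups) * n + n
  } else if (kind == "fully_connected") {
    if (is.na(in_shape)) abort("Fully-connected layer needs a resolved `in_shape`.")
    as.numeric(in_shape)^2 * in_channels * layer$out_units + layer$out_units
  } else {
    0
  }
}

#' Per-layer shape and parameter table of an architecture
#'
#' The table a practitioner would compare against a published layer listing:
#' one row per layer with the activation shape from [infer_shapes()] and the
#' learnable-parameter count from [count_parameters()].
#'
#' @inheritParams infer_shapes
#' @return Tibble with `layer`, `kind`, `out_h`, `out_w`, `channels`, `units`,
#'   `params`.
#' @export
architecture_table <- function(arch, input_size = NULL) {
  shapes <- infer_shapes(arch, input_size)
  params <- numeric(nrow(shapes))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    params[i + 1L] <- count_parameters(l, shapes$channels[i], shapes$out_h[i])
  }
  shapes$params <- params
  shapes
}

#' Total learnable parameters of an architecture
#'
#' @inheritParams infer_shapes
#' @return Total parameter count of one twin branch (head excluded).
#' @export
total_parameters <- function(arch, input_size = NULL) {
  sum(architecture_table(arch, input_size)$params)
}

#' Reference per-layer activation shapes and parameter counts
#'
#' The published layer listing the backbone catalogue was transcribed from,
#' kept in the package as a regression oracle: `out_size`/`channels` are the
#' listed activation shapes and `learnable` the listed per-layer parameter
#' counts. Two listed entries are internally inconsistent and are flagged by
#' `discrepant = TRUE`: network 5's 26 -> 9 transition (a 5x5 valid
#' convolution admits no integer stride mapping 26 to 9; the catalogue uses
#' stride 2) together with its downstream shapes, and network 7's
#' fully-connected count (16,781,312 implies a 4096-dim input, inconsistent
#' with the preceding 9 x 9 x 256 activation).
#'
#' @return Tibble: `network`, `layer`, `kind`, `out_size`, `channels`,
#'   `learnable`, `discrepant`.
#' @export
backbone_reference <- function() {
  r <- function(network, layer, kind, out_size, channels, learnable, discrepant = FALSE) {
    tibble(network = network, layer = layer, kind = kind, out_size = out_size,
           channels = channels, learnable = learnable, discrepant = discrepant)
  }
  dplyr::bind_rows(
    # Network 1
    r(1, 1, "conv", 215, 64, 6464), r(1, 2, "relu", 215, 64, 0),
    r(1, 3, "max_pool", 107, 64, 0), r(1, 4, "conv", 101, 128, 401536),
    r(1, 5, "relu", 101, 128, 0), r(1, 6, "max_pool", 50, 128, 0),
    r(1, 7, "conv", 47, 128, 262272), r(1, 8, "relu", 47, 128, 0),
    r(1, 9, "max_pool", 23, 128, 0), r(1, 10, "conv", 19, 64, 204864),
    r(1, 11, "relu", 19, 64, 0), r(1, 12, "fully_connected", NA, 4096, 94638080),
    # Network 2
    r(2, 1, "conv", 220, 64, 1664), r(2, 2, "leaky_relu", 220, 64, 0),
    r(2, 3, "conv", 216, 64, 102464), r(2, 4, "leaky_relu", 216, 64, 0),
    r(2, 5, "max_pool", 108, 64, 0), r(2, 6, "conv", 106, 128, 73856),
    r(2, 7, "leaky_relu", 106, 128, 0), r(2, 8, "conv", 104, 128, 147584),
    r(2, 9, "leaky_relu", 104, 128, 0), r(2, 10, "max_pool", 52, 128, 0),
    r(2, 11, "conv", 49, 128, 262272), r(2, 12, "leaky_relu", 49, 128, 0),
    r(2, 13, "max_pool", 24, 128, 0), r(2, 14, "conv", 20, 64, 204864),
    r(2, 15, "leaky_relu", 20, 64, 0), r(2, 16, "fully_connected", NA, 2048, 52430848),
    # Network 3
    r(3, 1, "conv", 55, 128, 6400), r(3, 2, "max_pool", 27, 128, 0),
    r(3, 3, "conv", 23, 256, 819456), r(3, 4, "relu", 23, 256, 0),
    r(3, 5, "conv", 19, 128, 819328), r(3, 6, "max_pool", 9, 128, 0),
    r(3, 7, "conv", 7, 64, 73792), r(3, 8, "relu", 7, 64, 0),
    r(3, 9, "max_pool", 3, 64, 0), r(3, 10, "fully_connected", NA, 4096, 2363392),
    # Network 4
    r(4, 1, "conv", 218, 128, 6400), r(4, 2, "max_pool", 54, 128, 0),
    r(4, 3, "relu", 54, 128, 0), r(4, 4, "conv", 50, 256, 819456),
    r(4, 5, "relu", 50, 256, 0), r(4, 6, "conv", 48, 64, 147520),
    r(4, 7, "max_pool", 24, 64, 0), r(4, 8, "conv", 22, 128, 73856),
    r(4, 9, "relu", 22, 128, 0), r(4, 10, "conv", 18, 64, 204864),
    r(4, 11, "fully_connected", NA, 4096, 84938752),
    # Network 5 (layers 6..9 carry the inconsistent 26 -> 9 shapes)
    r(5, 1, "conv", 215, 64, 6464), r(5, 2, "max_pool", 107, 64, 0),
    r(5, 3, "relu", 107, 64, 0), r(5, 4, "conv", 26, 128, 401536),
    r(5, 5, "relu", 26, 128, 0), r(5, 6, "conv", 9, 128, 409728, TRUE),
    r(5, 7, "relu", 9, 128, 0, TRUE), r(5, 8, "conv", 6, 64, 131136, TRUE),
    r(5, 9, "relu", 6, 64, 0, TRUE), r(5, 10, "fully_connected", NA, 4096, 9441280),
    # Network 6
    r(6, 1, "conv", 218, 64, 3200), r(6, 2, "max_pool", 109, 64, 0),
    r(6, 3, "relu", 109, 64, 0), r(6, 4, "conv", 107, 128, 73856),
    r(6, 5, "max_pool", 53, 128, 0), r(6, 6, "relu", 53, 128, 0),
    r(6, 7, "conv", 53, 64, 8256), r(6, 8, "relu", 53, 64, 0),
    r(6, 9, "conv", 51, 128, 73856), r(6, 10, "relu", 51, 128, 0),
    r(6, 11, "max_pool", 25, 128, 0), r(6, 12, "conv", 25, 128, 16512),
    r(6, 13, "relu", 25, 128, 0), r(6, 14, "conv", 22, 64, 131136),
    r(6, 15, "max_pool", 11, 64, 0), r(6, 16, "relu", 11, 64, 0),
    r(6, 17, "fully_connected", NA, 4096, 31723520),
    # Network 7 (the listed FC count is inconsistent with its input shape)
    r(7, 1, "dropout", 224, 1, 0), r(7, 2, "conv", 218, 64, 3200),
    r(7, 3, "max_pool", 109, 64, 0), r(7, 4, "conv", 105, 128, 204928),
    r(7, 5, "max_pool", 52, 128, 0), r(7, 6, "conv", 48, 64, 204864),
    r(7, 7, "max_pool", 24, 64, 0), r(7, 8, "conv", 22, 256, 147712),
    r(7, 9, "max_pool", 11, 256, 0), r(7, 10, "conv", 9, 256, 590080),
    r(7, 11, "fully_connected", NA, 4096, 16781312, TRUE),
    # Network 8
    r(8, 1, "conv", 215, 32, 3232), r(8, 2, "max_pool", 107, 32, 0),
    r(8, 3, "relu", 107, 32, 0), r(8, 4, "grouped_conv", 101, 64, 50240),
    r(8, 5, "conv", 97, 128, 204928), r(8, 6, "max_pool", 48, 128, 0),
    r(8, 7, "relu", 48, 128, 0), r(8, 8, "grouped_conv", 46, 256, 147712),
    r(8, 9, "fully_connected", NA, 4096, 2218790912)
  )
}

#' Reduced network-3 backbone for small inputs
#'
#' A scaled-down variant of backbone 3 for fast CPU experiments on small
#' images: the same layer pattern (strided first convolution, alternating
#' convolution / pooling nonlinearities, single fully-connected embedding)
#' with the first stride relaxed to 2, filter counts scaled by `filter_scale`
#' and the trailing pool dropped so the spatial extent survives an
#' `input_size` as small as 48. The activations are leaky ReLU (slope 0.01)
#' rather than the full-size network's plain ReLU: at these narrow widths a
#' plain-ReLU variant is prone to irrecoverable dying-unit collapse (an
#' entire layer's pre-activations driven negative early in training kills
#' the gradient permanently), which the leaky slope rules out.
#'
#' @param input_size Input side in pixels (default 64).
#' @param filter_scale Multiplier on the filter counts (default 1/8).
#' @param embedding_dim Embedding size (default 64).
#' @return An `snn_architecture`.
#' @export
reduced_network3 <- function(input_size = 64, filter_scale = 1 / 8,
                             embedding_dim = 64) {
  f <- function(n) max(4L, as.integer(round(n * filter_scale)))
  layers <- list(
    conv_l(7, f(128), stride = 2), pool_l(2),
    conv_l(5, f(256)), lrelu_l(0.01),
    conv_l(5, f(128)), pool_l(2),
    conv_l(3, f(64)), lrelu_l(0.01), fc_l(embedding_dim)
  )
  arch <- new_architecture(3L, layers, embedding_dim, input_size,
                           name = "network_3_reduced")
  infer_shapes(arch) # validates that every layer fits
  arch
}
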