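#' Backbone layer specification
#'
#' Names the layers used for the content and style representations and the
#' per-channel preprocessing applied before feature extraction. The defaults
#' are the classical choice for style transfer with a 19-layer VGG extractor:
#' content from `"Conv4_2"`, style from the five rectified layers
#' `"ReLU1_1"` ... `"ReLU5_1"` (shallow to deep).
#'
#' @param content_layer layer name used for the content representation.
#' @param style_layers ordered (shallow to deep) distinct layer names used for
#'   the style representation.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(content_layer = "Conv4_2",
                          style_layers = c("ReLU1_1", "ReLU2_1", "ReLU3_1",
                                           "ReLU4_1", "ReLU5_1")) {
  stopifnot(is.character(content_layer), length(content_layer) == 1L,
            is.character(style_layers), length(style_layers) >= 1L)
  if (anyDuplicated(style_layers)) {
    abort("style layers must be distinct", class = "hestain_config_error")
  }
  structure(list(content_layer = content_layer, style_layers = style_layers),
            class = "backbone_spec")
}

new_backbone <- function(layers, preprocess, kind, seed = NULL) {
  structure(list(layers = layers, preprocess = preprocess, kind = kind,
                 seed = seed),
            class = "stain_backbone")
}

#' @export
print.stain_backbone <- function(x, ...) {
  cat(sprintf("<stain_backbone> kind '%s', %d layers\n", x$kind, length(x$layers)))
  cat("  layers:", paste(backbone_layers(x), collapse = ", "), "\n")
  invisible(x)
}

#' Registered layer names of a backbone
#' @param backbone a backbone built by [build_test_backbone()] or
#'   [load_pretrained_backbone()].
#' @return Character vector of layer names, input to output.
#' @export
backbone_layers <- function(backbone) {
  vapply(backbone$layers, `[[`, character(1), "name")
}

run_with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

conv_layer <- function(name, wmat, in_channels, bias = NULL) {
  list(name = name, type = "conv", wmat = wmat, bias = bias,
       in_channels = in_channels, out_channels = ncol(wmat))
}

#' Build the seeded test backbone
#'
#' A small fixed-architecture extractor used for all algorithmic work and
#' testing without any pretrained weights: five conv blocks of 3x3 zero-padded
#' convolutions with rectification after each conv and 2x average pooling
#' between blocks. Block 4 holds two convolutions so the canonical content
#' layer name `"Conv4_2"` exists; layer names match the production naming
#' scheme (`Conv<block>_<k>`, `ReLU<block>_<k>`), so a [transfer_config()] is
#' interchangeable between backbones. Convolutions are bias-free and weights
#' are drawn deterministically from `seed` (He-scaled Gaussian); preprocessing
#' is the identity.
#'
#' @param seed integer; same seed gives bit-identical weights.
#' @param channels number of feature channels per block (length 5).
#' @return A `stain_backbone`.
#' @export
build_test_backbone <- function(seed = 0L, channels = c(8L, 8L, 8L, 8L, 8L)) {
  stopifnot(length(channels) == 5L, all(channels >= 1L))
  run_with_preserved_rng(seed, {
    draw <- function(cin, cout) {
      matrix(rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
             nrow = 9L * cin, ncol = cout)
    }
    layers <- list()
    cin <- 3L
    for (b in 1:5) {
      n_convs <- if (b == 4L) 2L else 1L
      for (k in seq_len(n_convs)) {
        layers[[length(layers) + 1L]] <-
          conv_layer(sprintf("Conv%d_%d", b, k), draw(cin, channels[b]), cin)
        layers[[length(layers) + 1L]] <-
          list(name = sprintf("ReLU%d_%d", b, k), type = "relu")
        cin <- channels[b]
      }
      if (b < 5L) {
        layers[[length(layers) + 1L]] <- list(name = sprintf("pool%d", b),
                                              type = "pool")
      }
    }
    new_backbone(layers,
                 preprocess = list(mean = c(0, 0, 0), sd = c(1, 1, 1)),
                 kind = "test", seed = as.integer(seed))
  })
}

# VGG-19 feature-extractor layout: conv counts and widths per block
vgg19_layout <- function() {
  list(widths = c(64L, 128L, 256L, 512L, 512L),
       n_convs = c(2L, 2L, 4L, 4L, 4L))
}

#' Load a pretrained 19-layer backbone from a weights file
#'
#' Builds the 19-layer VGG feature extractor (16 convolutional layers in five
#' blocks) from a weights file supplied by the user: an RDS file holding a
#' named list with one entry per conv layer (`Conv1_1`, `Conv1_2`, ...,
#' `Conv5_4`), each a list with a `3 x 3 x Cin x Cout` array `kernel` and an
#' optional length-`Cout` numeric `bias`. Preprocessing is per-channel
#' standardization with the ImageNet means and standard deviations. There is
#' no download and never a silent fallback to random weights: a missing or
#' malformed file is an error.
#'
#' @param weights_path path to the RDS weights file.
#' @return A `stain_backbone` exposing `"Conv4_2"` and `"ReLU1_1"` ...
#'   `"ReLU5_1"` among its registered layers.
#' @export
load_pretrained_backbone <- function(weights_path) {
  if (!is.character(weights_path) || length(weights_path) != 1L ||
      !file.exists(weights_path)) {
    abort(paste0(
      "pretrained backbone weights not found at '", weights_path, "'.\n",
      "Supply an RDS file holding a named list with one entry per conv layer\n",
      "(Conv1_1 ... Conv5_4), each list(kernel = 3x3xCinxCout array,\n",
      "bias = numeric Cout), e.g. converted from published VGG-19 weights.\n",
      "For download-free work use build_test_backbone() instead."),
      class = "hestain_io_error")
  }
  wl <- tryCatch(readRDS(weights_path), error = function(e) {
    abort(sprintf("failed to read backbone weights '%s': %s",
                  weights_path, conditionMessage(e)),
          class = "hestain_io_error")
  })
  lay <- vgg19_layout()
  layers <- list()
  cin <- 3L
  for (b in 1:5) {
    for (k in seq_len(lay$n_convs[b])) {
      nm <- sprintf("Conv%d_%d", b, k)
      entry <- wl[[nm]]
      if (is.null(entry) || is.null(entry$kernel) ||
          !identical(dim(entry$kernel)[1:3], c(3L, 3L, cin)) ||
          dim(entry$kernel)[4] != lay$widths[b]) {
        abort(sprintf(
          "weights file '%s' lacks a valid kernel for layer %s (expected 3x3x%dx%d)",
          weights_path, nm, cin, lay$widths[b]), class = "hestain_format_error")
      }
      layers[[length(layers) + 1L]] <-
        conv_layer(nm, pack_kernel(entry$kernel), cin, bias = entry$bias)
      layers[[length(layers) + 1L]] <-
        list(name = sprintf("ReLU%d_%d", b, k), type = "relu")
      cin <- lay$widths[b]
    }
    if (b < 5L) {
      layers[[length(layers) + 1L]] <- list(name = sprintf("pool%d", b),
                                            type = "pool")
    }
  }
  new_backbone(layers,
               preprocess = list(mean = c(0.485, 0.456, 0.406),
                                 sd = c(0.229, 0.224, 0.225)),
               kind = "pretrained")
}

check_layers_registered <- function(backbone, wanted) {
  reg <- backbone_layers(backbone)
  missing <- setdiff(wanted, reg)
  if (length(missing)) {
    abort(sprintf("unknown backbone layer(s) %s; registered layers: %s",
                  paste(missing, collapse = ", "),
                  paste(reg, collapse = ", ")),
          class = "hestain_config_error")
  }
  invisible(TRUE)
}

# image (stain_image or HxWx3 array) -> preprocessed N x 3 matrix plus dims
image_to_input <- function(img, backbone) {
  px <- unclass(img)
  h <- dim(px)[1]; w <- dim(px)[2]
  x <- matrix(px, nrow = h * w, ncol = 3L)
  pp <- backbone$preprocess
  x <- sweep(sweep(x, 2L, pp$mean, "-"), 2L, pp$sd, "/")
  list(x = x, h = h, w = w)
}

#' Extract named-layer feature maps from an image
#'
#' Runs the backbone forward and captures the activations at the requested
#' layers. Extraction is a pure function of the pixels and the backbone
#' weights: repeated calls are bit-identical.
#'
#' @param img a [stain_image()].
#' @param backbone a `stain_backbone`.
#' @param layers character vector of layer names to capture; defaults to the
#'   content and style layers of `spec`.
#' @param spec a [backbone_spec()] (used when `layers` is not given).
#' @return An object of class `feature_map_set`: a named list of
#'   `H' x W' x C` activation arrays with attribute `image_id`.
#' @export
extract_features <- function(img, backbone, layers = NULL,
                             spec = backbone_spec()) {
  if (is.null(layers)) layers <- union(spec$content_layer, spec$style_layers)
  check_layers_registered(backbone, layers)
  inp <- image_to_input(img, backbone)
  fw <- net_forward(backbone$layers, inp$x, inp$h, inp$w, record = layers)
  maps <- lapply(fw$captured, function(m) {
    array(m, dim = c(attr(m, "h"), attr(m, "w"), ncol(m)))
  })
  structure(maps[layers], image_id = attr(img, "source_id") %||% "image",
            class = "feature_map_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
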