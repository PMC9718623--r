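#' Reference DarkNet19 backbone specification
#'
#' Builds the layer table of the DarkNet19 classification network: 19
#' convolutional layers interleaved with 5 max-pooling layers, alternating
#' 3x3 convolutions with 1x1 bottlenecks, a 1x1 head convolution carrying
#' `num_classes` filters and a global softmax. All 3x3 convolutions use
#' padding 1 (spatial size preserved), 1x1 convolutions padding 0, and the
#' 2x2/2 max-pools halve the spatial size.
#'
#' @param num_classes Number of output classes (>= 2).
#' @return A `backbone_spec`: list with `name`, `layers` (a tibble of layer
#'   rows), `input_hw`, `num_classes` and `tap_layer` (the layer whose
#'   globally pooled activation is exported as the feature vector — the last
#'   1024-channel convolution before the head).
#' @export
build_darknet19_spec <- function(num_classes = 5L) {
  if (!is.numeric(num_classes) || num_classes < 2) stop("num_classes must be >= 2")
  conv <- function(name, filters, k, pad) {
    tibble::tibble(name = name, kind = "conv", filters = as.integer(filters),
                   kernel = as.integer(k), stride = 1L, pad = as.integer(pad),
                   squeeze = NA_integer_, expand1 = NA_integer_,
                   expand3 = NA_integer_)
  }
  mp <- function(name) {
    tibble::tibble(name = name, kind = "maxpool", filters = NA_integer_,
                   kernel = 2L, stride = 2L, pad = 0L,
                   squeeze = NA_integer_, expand1 = NA_integer_,
                   expand3 = NA_integer_)
  }
  layers <- dplyr::bind_rows(
    conv("conv1", 34, 3, 1), mp("maxpool1"),
    conv("conv2", 64, 3, 1), mp("maxpool2"),
    conv("conv3", 128, 3, 1), conv("conv4", 64, 1, 0),
    conv("conv5", 128, 3, 1), mp("maxpool3"),
    conv("conv6", 256, 3, 1), conv("conv7", 128, 1, 0),
    conv("conv8", 256, 3, 1), mp("maxpool4"),
    conv("conv9", 512, 3, 1), conv("conv10", 256, 1, 0),
    conv("conv11", 512, 3, 1), conv("conv12", 256, 1, 0),
    conv("conv13", 512, 3, 1), mp("maxpool5"),
    conv("conv14", 1024, 3, 1), conv("conv15", 512, 1, 0),
    conv("conv16", 1024, 3, 1), conv("conv17", 512, 1, 0),
    conv("conv18", 1024, 3, 1),
    conv("head_conv", num_classes, 1, 0),
    tibble::tibble(name = "softmax", kind = "global_softmax",
                   filters = NA_integer_, kernel = NA_integer_,
                   stride = NA_integer_, pad = NA_integer_,
                   squeeze = NA_integer_, expand1 = NA_integer_,
                   expand3 = NA_integer_)
  )
  new_backbone_spec("darknet19", layers, input_hw = 224L,
                    num_classes = as.integer(num_classes),
                    tap_layer = which(layers$name == "conv18"))
}

#' Reference SqueezeNet backbone specification
#'
#' Builds the SqueezeNet layer table: a 7x7/2 stem convolution, eight fire
#' modules (1x1 squeeze followed by parallel 1x1 and 3x3 expands whose
#' outputs are channel-concatenated) with max-pools after the stem, fire 4
#' and fire 8, a 1x1 head convolution with `num_classes` filters and a
#' global average pool. The printed 111x111 stem output corresponds to a
#' 227-pixel input under valid padding; see [infer_shapes()].
#'
#' @param num_classes Number of output classes (>= 2).
#' @return A `backbone_spec`; the tap layer is fire 9 (512 channels after
#'   global pooling).
#' @export
build_squeezenet_spec <- function(num_classes = 5L) {
  if (!is.numeric(num_classes) || num_classes < 2) stop("num_classes must be >= 2")
  fire <- function(name, s, e1, e3) {
    tibble::tibble(name = name, kind = "fire", filters = NA_integer_,
                   kernel = NA_integer_, stride = NA_integer_,
                   pad = NA_integer_, squeeze = as.integer(s),
                   expand1 = as.integer(e1), expand3 = as.integer(e3))
  }
  mp3 <- function(name) {
    tibble::tibble(name = name, kind = "maxpool", filters = NA_integer_,
                   kernel = 3L, stride = 2L, pad = 0L,
                   squeeze = NA_integer_, expand1 = NA_integer_,
                   expand3 = NA_integer_)
  }
  layers <- dplyr::bind_rows(
    tibble::tibble(name = "conv1", kind = "conv", filters = 96L, kernel = 7L,
                   stride = 2L, pad = 0L, squeeze = NA_integer_,
                   expand1 = NA_integer_, expand3 = NA_integer_),
    mp3("maxpool1"),
    fire("fire2", 16, 64, 64), fire("fire3", 16, 64, 64),
    fire("fire4", 32, 128, 128), mp3("maxpool4"),
    fire("fire5", 32, 128, 128), fire("fire6", 48, 192, 192),
    fire("fire7", 48, 192, 192), fire("fire8", 64, 256, 256),
    mp3("maxpool8"),
    fire("fire9", 64, 256, 256),
    tibble::tibble(name = "conv10", kind = "conv",
                   filters = as.integer(num_classes), kernel = 1L,
                   stride = 1L, pad = 0L, squeeze = NA_integer_,
                   expand1 = NA_integer_, expand3 = NA_integer_),
    tibble::tibble(name = "avgpool10", kind = "global_avgpool",
                   filters = NA_integer_, kernel = NA_integer_,
                   stride = NA_integer_, pad = NA_integer_,
                   squeeze = NA_integer_, expand1 = NA_integer_,
                   expand3 = NA_integer_)
  )
  new_backbone_spec("squeezenet", layers, input_hw = 224L,
                    num_classes = as.integer(num_classes),
                    tap_layer = which(layers$name == "fire9"))
}

new_backbone_spec <- function(name, layers, input_hw, num_classes, tap_layer) {
  stopifnot(tap_layer >= 1, tap_layer <= nrow(layers))
  structure(
    list(name = name, layers = layers, input_hw = input_hw,
         num_classes = num_classes, tap_layer = tap_layer),
    class = "backbone_spec"
  )
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat("<backbone_spec> ", x$name, ": ", nrow(x$layers), " layers, ",
      sum(x$layers$kind == "conv"), " conv / ",
      sum(x$layers$kind == "maxpool"), " maxpool / ",
      sum(x$layers$kind == "fire"), " fire; tap layer ",
      x$tap_layer, " (", x$layers$name[x$tap_layer], ")\n", sep = "")
  invisible(x)
}

#' Infer per-layer output shapes for a backbone specification
#'
#' Pure shape arithmetic, no weights involved. Convolutions and max-pools
#' follow `out = floor((in + 2*pad - k) / stride) + 1`; fire modules keep
#' the spatial size and output `expand1 + expand3` channels; global pools
#' collapse to 1x1.
#'
#' @param spec A `backbone_spec`.
#' @param input_hw Input spatial size in pixels (square); defaults to the
#'   spec's `input_hw`.
#' @param input_channels Input channel count; default 3.
#' @return A tibble with one row per layer: `layer`, `name`, `kind`,
#'   `out_h`, `out_w`, `out_c`.
#' @export
infer_shapes <- function(spec, input_hw = spec$input_hw, input_channels = 3L) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (!is.numeric(input_hw) || input_hw <= 0) stop("input_hw must be > 0")
  h <- as.integer(input_hw); c_in <- as.integer(input_channels)
  out <- vector("list", nrow(spec$layers))
  for (i in seq_len(nrow(spec$layers))) {
    ly <- spec$layers[i, ]
    if (ly$kind %in% c("conv", "maxpool")) {
      h_new <- floor((h + 2 * ly$pad - ly$kernel) / ly$stride) + 1
      if (h_new <= 0) {
        stop("layer '", ly$name, "' collapses the spatial size (",
             h, " -> ", h_new, ")")
      }
      h <- as.integer(h_new)
      if (ly$kind == "conv") c_in <- ly$filters
    } else if (ly$kind == "fire") {
      c_in <- ly$expand1 + ly$expand3
    } else if (ly$kind %in% c("global_avgpool", "global_softmax")) {
      h <- 1L
    } else {
      stop("unknown layer kind: ", ly$kind)
    }
    out[[i]] <- tibble::tibble(layer = i, name = ly$name, kind = ly$kind,
                               out_h = h, out_w = h, out_c = c_in)
  }
  dplyr::bind_rows(out)
}

#' Feature dimension exported by a backbone's tap layer
#'
#' @param spec A `backbone_spec`.
#' @return Integer channel count of the (globally pooled) tap layer.
#' @export
tap_dim <- function(spec) {
  shapes <- infer_shapes(spec)
  as.integer(shapes$out_c[spec$tap_layer])
}
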