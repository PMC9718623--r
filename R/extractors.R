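# Feature-extractor contract: an object with fields descriptor, out_dim,
# deterministic, plus an internal function mapping a standardized 32x32
# grayscale raster to a feature vector. Two implementations are provided:
# a deterministic mock (fixed-seed random projection) and a small trainable
# multilayer perceptron whose hidden layer is tapped.

DOWNSAMPLE_HW <- 32L

# Block-mean downsample of an H x W x 3 image to hw x hw grayscale in [0,1].
downsample_gray <- function(image, hw = DOWNSAMPLE_HW) {
  stopifnot(length(dim(image)) == 3)
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  h <- nrow(gray); w <- ncol(gray)
  ri <- pmin(floor((seq_len(h) - 1) * hw / h) + 1, hw)
  ci <- pmin(floor((seq_len(w) - 1) * hw / w) + 1, hw)
  sums <- rowsum(t(rowsum(gray, ri)), ci)
  cnts <- rowsum(t(rowsum(matrix(1, h, w), ri)), ci)
  t(sums / cnts)
}

#' Deterministic mock feature extractor
#'
#' A fixed-seed random projection of block-mean 32x32 grayscale downsamples:
#' `f = P g` with `P` drawn once from N(0, 1/1024) at the given seed.
#' Deterministic, weight-free and fast, it inherits whatever class
#' separability the raw pixels carry, which makes it the standard extractor
#' for desk-scale tests of the downstream fusion/selection/classification
#' stages.
#'
#' @param out_dim Output feature dimension; default 128.
#' @param seed Seed for the projection matrix; default 1.
#' @param name Descriptor recorded in column ids; default `"mock"`. Use two
#'   different names/seeds to emulate two feature views.
#' @return A `feature_extractor`.
#' @export
mock_extractor <- function(out_dim = 128L, seed = 1L, name = "mock") {
  d <- DOWNSAMPLE_HW^2
  proj <- with_seed(seed, matrix(stats::rnorm(out_dim * d, sd = 1 / sqrt(d)),
                                 out_dim, d))
  structure(
    list(descriptor = name, out_dim = as.integer(out_dim),
         deterministic = TRUE, tap = "proj", trainable = FALSE,
         fun = function(g) drop(proj %*% as.vector(g))),
    class = "feature_extractor"
  )
}

#' Small trainable multilayer-perceptron extractor
#'
#' A fully connected ReLU network over 32x32 grayscale downsamples whose
#' last hidden layer is tapped as the feature vector. Supports the transfer
#' workflow: [swap_head_and_finetune()] replaces the softmax head for a new
#' label set and continues training; zero epochs leaves the weights (and
#' hence the features) bit-identical.
#'
#' @param out_dim Hidden (= feature) dimension; default 64.
#' @param num_classes Head size; default 5.
#' @param seed Seed for weight initialisation.
#' @param name Descriptor recorded in column ids; default `"mlp"`.
#' @return A trainable `feature_extractor`.
#' @export
mlp_extractor <- function(out_dim = 64L, num_classes = 5L, seed = 1L,
                          name = "mlp") {
  net <- mlp_init(DOWNSAMPLE_HW^2, hidden = out_dim,
                  n_out = as.integer(num_classes), seed = seed)
  structure(
    list(descriptor = name, out_dim = as.integer(out_dim),
         deterministic = TRUE, tap = "hidden", trainable = TRUE,
         net = net, num_classes = as.integer(num_classes)),
    class = "feature_extractor"
  )
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat("<feature_extractor> ", x$descriptor, ", out_dim ", x$out_dim,
      if (x$trainable) ", trainable" else ", fixed", "\n", sep = "")
  invisible(x)
}

extractor_features_one <- function(extractor, image) {
  g <- downsample_gray(image)
  if (extractor$trainable) {
    drop(mlp_forward(extractor$net, matrix(as.vector(g), 1), tap = TRUE)$hidden)
  } else {
    extractor$fun(g)
  }
}

#' Extract a feature table from a set of images
#'
#' Applies the extractor to every image and assembles the N x out_dim
#' feature table. Column ids are `{descriptor}:{tap}:{k}`.
#'
#' @param extractor A `feature_extractor`.
#' @param samples A list of grain samples (each with `image` and optionally
#'   `label`), or a list of bare H x W x 3 arrays.
#' @return A tibble with `sample_id`, `label` (NA when unknown) and one
#'   column per feature.
#' @export
extract_features <- function(extractor, samples) {
  stopifnot(inherits(extractor, "feature_extractor"), length(samples) > 0)
  rows <- purrr::map(samples, function(s) {
    img <- if (is.list(s)) s$image else s
    f <- extractor_features_one(extractor, img)
    if (!all(is.finite(f))) stop("non-finite activation in feature extraction")
    f
  })
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("%s:%s:%04d", extractor$descriptor, extractor$tap,
                         seq_len(extractor$out_dim))
  labels <- purrr::map_int(samples, function(s) {
    if (is.list(s) && !is.null(s$label)) as.integer(s$label) else NA_integer_
  })
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s_%04d", seq_along(samples)),
                   label = labels),
    tibble::as_tibble(x)
  )
}

#' Replace the classification head and fine-tune a trainable extractor
#'
#' Re-initialises the softmax head for `num_classes` labels and continues
#' training on the supplied images; `train_layers = "head"` (the default)
#' freezes the hidden layers. The feature tap contract is unchanged: the
#' returned extractor exports the same hidden layer. Zero epochs is a no-op
#' (weights and features bit-identical apart from the fresh head).
#'
#' @param extractor A trainable `feature_extractor` (see [mlp_extractor()]);
#'   the mock extractor raises an error.
#' @param samples List of grain samples with `image` fields.
#' @param labels Integer class labels in `0:(K-1)`.
#' @param train_config List: `num_classes` (default `max(labels) + 1`),
#'   `epochs` (default 200), `lr` (default 0.01), `train_layers`
#'   (`"head"` or `"all"`), `seed` (head re-init seed, default 1).
#' @return The fine-tuned `feature_extractor`.
#' @export
swap_head_and_finetune <- function(extractor, samples, labels,
                                   train_config = list()) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (!isTRUE(extractor$trainable)) {
    stop("extractor '", extractor$descriptor,
         "' has no trainable weights; head swap unsupported")
  }
  cfg <- utils::modifyList(
    list(num_classes = max(labels) + 1L, epochs = 200L, lr = 0.01,
         train_layers = "head", seed = 1L),
    train_config
  )
  net <- extractor$net
  n_layers <- length(net$w)
  if (cfg$num_classes != ncol(net$w[[n_layers]])) {
    fan_in <- nrow(net$w[[n_layers]])
    net$w[[n_layers]] <- with_seed(
      cfg$seed,
      matrix(stats::rnorm(fan_in * cfg$num_classes, sd = sqrt(2 / fan_in)),
             fan_in, cfg$num_classes)
    )
    net$b[[n_layers]] <- numeric(cfg$num_classes)
    net$sizes[length(net$sizes)] <- cfg$num_classes
  }
  x <- do.call(rbind, purrr::map(samples, function(s) {
    img <- if (is.list(s)) s$image else s
    as.vector(downsample_gray(img))
  }))
  net <- mlp_train(net, x, mlp_onehot(as.integer(labels), cfg$num_classes),
                   epochs = cfg$epochs, lr = cfg$lr,
                   train_layers = cfg$train_layers)
  extractor$net <- net
  extractor$num_classes <- cfg$num_classes
  extractor
}
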