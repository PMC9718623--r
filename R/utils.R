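#' Min-max normalisation to \[0, 1\]
#'
#' Rescales a numeric vector linearly so its minimum maps to 0 and its
#' maximum to 1. A constant vector (no spread) maps to all zeros, which keeps
#' downstream complements well defined for degenerate saliency stages.
#'
#' @param x Numeric vector.
#' @return Numeric vector in \[0, 1\], same length as `x`.
#' @export
minmax_norm <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2]))) {
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Deterministic per-stage seed derivation: one pipeline seed fans out so each
# stage is independently reproducible. Keeps results < 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    synth = 101L, segment = 211L, extract_a = 307L, extract_b = 401L,
    fuse = 503L, select = 601L, classify = 701L, fixture = 809L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Convert an H x W x 3 array in [0,1] (sRGB) to an n x 3 CIELAB matrix for
# the pixels listed in `idx` (default all), via grDevices::convertColor.
rgb_to_lab <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  m <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}

# Otsu's threshold on values in [0, 1] using a fixed 256-bin histogram.
otsu_threshold <- function(x, n_bins = 256L) {
  stopifnot(all(is.finite(x)))
  if (diff(range(x)) < 1e-12) return(NA_real_)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # ties (a flat plateau across an empty gap) are resolved by averaging the
  # maximising bins, as in the classic discrete formulation; the threshold is
  # the upper edge of the winning bin so the whole class-1 bin stays below it
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  breaks[round(mean(best)) + 1L]
}

# Validate an N x D numeric feature matrix stored as a tibble with
# sample_id, label and f_* columns; returns list(x = matrix, labels, ids).
unpack_features <- function(features) {
  stopifnot(is.data.frame(features))
  need <- c("sample_id", "label")
  if (!all(need %in% names(features))) {
    stop("feature table must have 'sample_id' and 'label' columns")
  }
  feat_cols <- setdiff(names(features), need)
  x <- as.matrix(features[, feat_cols, drop = FALSE])
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite feature values")
  list(
    x = x,
    labels = features$label,
    ids = features$sample_id,
    feature_ids = feat_cols
  )
}
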