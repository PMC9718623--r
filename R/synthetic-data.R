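#' Rasterize a filled rotated ellipse
#'
#' Returns a binary `hw x hw` matrix with 1 inside the ellipse. Pixels are
#' tested at their centres (0-based row/col coordinates, row-major).
#'
#' @param hw Frame side length in pixels.
#' @param center Numeric length-2, (row, col) of the ellipse centre.
#' @param a,b Semi-axes in pixels (major, minor).
#' @param theta Orientation of the major axis in radians.
#' @return Integer matrix of 0/1.
#' @export
ellipse_mask <- function(hw, center, a, b, theta = 0) {
  stopifnot(hw >= 1, a > 0, b > 0, length(center) == 2)
  rr <- matrix(seq_len(hw) - 1, hw, hw) - center[1]
  cc <- matrix(seq_len(hw) - 1, hw, hw, byrow = TRUE) - center[2]
  u <- cos(theta) * cc + sin(theta) * rr
  v <- -sin(theta) * cc + cos(theta) * rr
  m <- (u / a)^2 + (v / b)^2 <= 1
  storage.mode(m) <- "integer"
  m
}

#' Generate synthetic grain images with ground-truth masks
#'
#' Emulates single-grain photographs at desk scale: one bright convex grain
#' (a rotated ellipse with a sinusoidal luminance texture along its major
#' axis) on a dark noisy background. Classes differ in ellipse size, aspect
#' ratio and texture frequency, with per-class parameter ranges disjoint
#' enough that a simple area/aspect feature already separates them. Output is
#' bit-reproducible from `seed` (pixel values are quantised to 8-bit levels).
#'
#' @param n_per_class Images per class.
#' @param n_classes Number of classes (>= 2).
#' @param hw Square frame side in pixels (>= 64).
#' @param seed Integer seed.
#' @return A list of samples; each sample is a list with `image` (hw x hw x 3
#'   array in \[0,1\]), `mask` (hw x hw 0/1 matrix), `label` (integer in
#'   `0:(n_classes-1)`) and `params` (semi-axes, orientation, texture
#'   frequency).
#' @export
gen_grain_images <- function(n_per_class, n_classes = 5L, hw = 128L, seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("n_per_class must be a positive count")
  }
  if (!is.numeric(n_classes) || n_classes < 2) stop("n_classes must be >= 2")
  if (!is.numeric(hw) || hw < 64) stop("hw must be >= 64")
  hw <- as.integer(hw)

  # class-k parameter bands (pixels / cycles-per-pixel); bands do not
  # overlap. Grains are centred and pose-aligned, emulating the auto-aligned
  # bounding-box crops single-grain datasets are built from; position jitter
  # of +-2 px and a small orientation spread remain as nuisance.
  a_mean <- 14 + 4 * (0:(n_classes - 1))
  aspect_mean <- rep(2.5, n_classes)
  tex_freq <- 0.10 + 0.06 * (0:(n_classes - 1))
  if (max(a_mean) + 5 > hw / 2) {
    stop("frame too small for ", n_classes, " size-separated classes")
  }

  with_seed(seed, {
    samples <- vector("list", n_per_class * n_classes)
    i <- 0L
    for (k in 0:(n_classes - 1)) {
      for (r in seq_len(n_per_class)) {
        a <- a_mean[k + 1] + stats::runif(1, -1, 1)
        b <- a / (aspect_mean[k + 1] + stats::runif(1, -0.1, 0.1))
        theta <- pi / 6 + stats::rnorm(1, sd = 0.05)
        ctr <- hw / 2 + stats::runif(2, -2, 2)
        mask <- ellipse_mask(hw, ctr, a, b, theta)

        # dark noisy background
        img <- array(stats::rnorm(hw * hw * 3, mean = 0.08, sd = 0.03),
                     dim = c(hw, hw, 3))

        # bright grain with sinusoidal texture anchored along the major axis
        rr <- matrix(seq_len(hw) - 1, hw, hw) - ctr[1]
        cc <- matrix(seq_len(hw) - 1, hw, hw, byrow = TRUE) - ctr[2]
        u <- cos(theta) * cc + sin(theta) * rr
        lum <- 1 - 0.15 + 0.15 * sin(2 * pi * tex_freq[k + 1] * u)
        base <- c(0.88, 0.84, 0.72)
        inside <- mask == 1L
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[inside] <- base[ch] * lum[inside] +
            stats::rnorm(sum(inside), sd = 0.015)
          img[, , ch] <- plane
        }
        img <- pmin(pmax(img, 0), 1)
        img <- round(img * 255) / 255   # 8-bit quantisation

        i <- i + 1L
        samples[[i]] <- list(
          image = img, mask = mask, label = k,
          params = list(a = a, b = b, theta = theta,
                        tex_freq = tex_freq[k + 1], center = ctr)
        )
      }
    }
    samples
  })
}

#' Specification for a synthetic labelled feature matrix
#'
#' Describes a feature matrix with planted structure: informative columns are
#' class-conditional Gaussians whose class means are `delta` apart, redundant
#' columns are linear copies of informative columns with noise solved
#' analytically so their sample correlation with the source is close to
#' `rho`, and noise columns are label-independent Gaussians.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes.
#' @param k_informative,k_redundant,k_noise Column counts by role.
#' @param delta Class-mean separation, in feature units.
#' @param sigma Within-class standard deviation (> 0).
#' @param rho Target correlation between a redundant column and its source.
#' @param seed Integer seed.
#' @return A `synthetic_feature_spec` list.
#' @export
synthetic_feature_spec <- function(n_per_class = 40L, n_classes = 5L,
                                   k_informative = 10L, k_redundant = 20L,
                                   k_noise = 30L, delta = 3, sigma = 1,
                                   rho = 0.9, seed = 1L) {
  stopifnot(n_per_class >= 2, n_classes >= 2,
            k_informative >= 1, k_redundant >= 0, k_noise >= 0)
  if (delta < 0) stop("delta must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_classes = as.integer(n_classes),
         k_informative = as.integer(k_informative),
         k_redundant = as.integer(k_redundant),
         k_noise = as.integer(k_noise),
         delta = delta, sigma = sigma, rho = rho, seed = as.integer(seed)),
    class = "synthetic_feature_spec"
  )
}

#' Generate a labelled feature matrix with planted structure
#'
#' @param spec A [synthetic_feature_spec()].
#' @return A list with `features` (tibble: `sample_id`, `label`,
#'   `f_0001`, ...), `informative_ids` (character, the ground-truth
#'   informative column names, always the first `k_informative` columns),
#'   `redundant_ids`, `noise_ids` and the `spec`.
#' @export
gen_feature_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_feature_spec"))
  K <- spec$n_classes
  n <- spec$n_per_class * K
  labels <- rep(0:(K - 1), each = spec$n_per_class)
  p <- spec$k_informative + spec$k_redundant + spec$k_noise
  ids <- sprintf("f_%04d", seq_len(p))

  with_seed(spec$seed, {
    x <- matrix(0, n, p)
    # informative: per-column random class dichotomy offset by delta, so each
    # column is individually weak and classes are told apart only jointly
    for (j in seq_len(spec$k_informative)) {
      side <- rep(0L, K)
      while (length(unique(side)) < 2) side <- stats::rbinom(K, 1, 0.5)
      x[, j] <- side[labels + 1] * spec$delta + stats::rnorm(n, sd = spec$sigma)
    }
    # redundant: copy of an informative source + analytic noise for target rho
    if (spec$k_redundant > 0) {
      for (r in seq_len(spec$k_redundant)) {
        src <- ((r - 1) %% spec$k_informative) + 1
        j <- spec$k_informative + r
        if (spec$rho >= 1) {
          x[, j] <- x[, src]
        } else if (spec$rho <= 0) {
          x[, j] <- stats::rnorm(n, sd = spec$sigma)
        } else {
          v <- stats::var(x[, src])
          s_noise <- sqrt(v * (1 / spec$rho^2 - 1))
          x[, j] <- x[, src] + stats::rnorm(n, sd = s_noise)
        }
      }
    }
    # noise: label-independent
    if (spec$k_noise > 0) {
      j0 <- spec$k_informative + spec$k_redundant
      x[, (j0 + 1):p] <- stats::rnorm(n * spec$k_noise, sd = spec$sigma)
    }
    colnames(x) <- ids
    features <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s_%04d", seq_len(n)),
                     label = as.integer(labels)),
      tibble::as_tibble(x)
    )
    list(
      features = features,
      informative_ids = ids[seq_len(spec$k_informative)],
      redundant_ids = if (spec$k_redundant > 0)
        ids[spec$k_informative + seq_len(spec$k_redundant)] else character(),
      noise_ids = if (spec$k_noise > 0)
        ids[(spec$k_informative + spec$k_redundant + 1):p] else character(),
      spec = spec
    )
  })
}

#' Write grain samples to a directory
#'
#' Writes `img_####.png`, `mask_####.png` (0/255) and a `labels.csv`
#' (`sample_id,label`) under `dir`, one subdirectory per class
#' (`class_0`, ...).
#'
#' @param samples Output of [gen_grain_images()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble of written paths and labels.
#' @export
write_grain_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::imap(samples, function(s, i) {
    cls_dir <- file.path(dir, sprintf("class_%d", s$label))
    dir.create(cls_dir, showWarnings = FALSE)
    id <- sprintf("img_%04d", i)
    img_path <- file.path(cls_dir, paste0(id, ".png"))
    mask_path <- file.path(cls_dir, paste0(id, "_mask.png"))
    png::writePNG(s$image, img_path)
    png::writePNG(s$mask + 0, mask_path)
    tibble::tibble(sample_id = id, label = s$label,
                   image = img_path, mask = mask_path)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest[, c("sample_id", "label")],
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write a feature table to CSV
#'
#' @param features Tibble with `sample_id`, `label` and feature columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_features_csv()].
#' @return A tibble with `sample_id`, `label` and feature columns.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$label <- as.integer(df$label)
  tibble::as_tibble(df)
}
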