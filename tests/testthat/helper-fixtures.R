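# Shared fixtures, built in code and memoised per test session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- get0(key, envir = fixture_cache)
  if (is.null(hit)) {
    hit <- force(expr)
    assign(key, hit, envir = fixture_cache)
  }
  hit
}

# Ten grain samples (2 per class), the standard segmentation fixture.
grain_fixture <- function() {
  cached("grains", gen_grain_images(2, 5, 128, seed = 7))
}

# Standard planted feature matrix (the selection fixture).
feature_fixture <- function(seed = 1L) {
  cached(paste0("features_", seed),
         gen_feature_matrix(synthetic_feature_spec(seed = seed)))
}

# Hand-built superpixel graph for operator-level tests: n nodes with given
# lab colours, centroids, and adjacency pairs.
toy_graph <- function(mean_lab, centroid, adjacency,
                      boundary = list(top = 1L, left = 1L, right = 1L,
                                      bottom = 1L)) {
  n <- nrow(mean_lab)
  structure(
    list(label_map = matrix(1L, 1, 1), n_nodes = n, mean_lab = mean_lab,
         centroid = centroid, sizes = rep(1L, n),
         adjacency = adjacency, boundary = boundary),
    class = "superpixel_graph"
  )
}

# Random symmetric nonnegative affinity matrix with zero diagonal.
random_affinity <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  w[up] <- vals
  w <- w + t(w)
  # ensure no isolated node so degree normalisation is well defined
  for (i in seq_len(n)) {
    if (sum(w[i, ]) == 0) {
      j <- if (i == 1) 2L else 1L
      w[i, j] <- w[j, i] <- stats::runif(1, 0.2, 1)
    }
  }
  w
}

# Independent dense solve of the manifold-ranking closed form.
brute_force_rank <- function(w, y, alpha, normalization = "symmetric") {
  n <- nrow(w)
  deg <- rowSums(w)
  if (normalization == "symmetric") {
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (deg[i] > 0 && deg[j] > 0) {
          s[i, j] <- w[i, j] / sqrt(deg[i] * deg[j])
        }
      }
    }
    solve(diag(n) - alpha * s) %*% y
  } else {
    solve(diag(pmax(deg, 1e-300)) - alpha * w) %*% y
  }
}

# Independent exhaustive implementation of the two fusion rules.
brute_force_fuse <- function(x, view, tau_high, tau_low) {
  p <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  cm <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j && sds[i] > 0 && sds[j] > 0) {
        cm[i, j] <- abs(stats::cor(x[, i], x[, j]))
      }
    }
  }
  kept <- rep(TRUE, p)
  for (i in seq_len(p)) {
    if (!kept[i]) next
    for (j in seq_len(p)) {
      if (j > i && kept[j] && cm[i, j] >= tau_high) kept[j] <- FALSE
    }
  }
  for (i in which(kept)) {
    other <- which(view != view[i])
    if (max(c(cm[i, other], 0)) <= tau_low) kept[i] <- FALSE
  }
  colnames(x)[kept]
}

# Wrap a plain matrix as a feature tibble.
as_feature_tibble <- function(x, labels = rep(0:1, length.out = nrow(x)),
                              prefix = "v") {
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("%s_%03d", prefix, seq_len(ncol(x)))
  }
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s_%04d", seq_len(nrow(x))),
                   label = as.integer(labels)),
    tibble::as_tibble(x)
  )
}

# Shuffle labels under a local seed.
with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}
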