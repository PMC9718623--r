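#' First-stage affinity matrix over a superpixel graph
#'
#' Colour affinity `w_ij = exp(-||lab_i - lab_j|| / sigma_c)` on a sparsity
#' pattern of: directly adjacent node pairs, neighbours-of-neighbours, and
#' all pairs of image-border nodes (the usual closure for boundary-seeded
#' manifold ranking). Diagonal is zero; off-pattern entries are zero.
#'
#' @param graph A `superpixel_graph`.
#' @param sigma_c Colour bandwidth in Lab units (> 0); default 10.
#' @param connect_boundary Connect all border-node pairs; default TRUE.
#' @return An `affinity` object: list with `weights` (dense symmetric
#'   matrix), `pattern` (logical matrix), `sigma_c`, `stage = "J1"`.
#' @export
build_affinity <- function(graph, sigma_c = 10, connect_boundary = TRUE) {
  stopifnot(inherits(graph, "superpixel_graph"))
  if (!is.numeric(sigma_c) || sigma_c <= 0) stop("sigma_c must be > 0")
  n <- graph$n_nodes
  adj <- matrix(FALSE, n, n)
  adj[graph$adjacency] <- TRUE
  adj[graph$adjacency[, 2:1, drop = FALSE]] <- TRUE
  # neighbours of neighbours
  pattern <- adj | ((adj %*% adj) > 0)
  if (connect_boundary) {
    bn <- unique(unlist(graph$boundary))
    pattern[bn, bn] <- TRUE
  }
  diag(pattern) <- FALSE
  d <- as.matrix(stats::dist(graph$mean_lab))
  weights <- matrix(0, n, n)
  weights[pattern] <- exp(-d[pattern] / sigma_c)
  structure(
    list(weights = weights, pattern = pattern, sigma_c = sigma_c,
         stage = "J1"),
    class = "affinity"
  )
}

#' Manifold ranking on an affinity matrix
#'
#' Solves the closed-form graph ranking
#' `r = (I - alpha * D^{-1/2} W D^{-1/2})^{-1} y` (`normalization =
#' "symmetric"`, the default) or `r = (D - alpha * W)^{-1} y`
#' (`"random_walk"`), where `D` is the degree matrix of `W` and `y` the seed
#' vector. The two forms are related by `r_rw = D^{-1/2} r_sym(D^{-1/2} y)`;
#' the random-walk form is the one used in practice by boundary-seeded
#' saliency ranking because its leading term as `alpha -> 1` is constant in
#' the node, whereas the symmetric form is then dominated by its degree
#' eigenvector (scores proportional to sqrt(degree) regardless of seeds).
#' The pipeline stages therefore rank with `"random_walk"`. No normalisation
#' is applied to the result; callers normalise per their stage's definition.
#'
#' @param W An `affinity` object or a plain symmetric nonnegative matrix.
#' @param seeds Numeric seed vector `y` (length = number of nodes).
#' @param alpha Ranking parameter in `[0, 1)`; default 0.99.
#' @param normalization `"symmetric"` or `"random_walk"`.
#' @return Numeric ranking vector.
#' @export
manifold_rank <- function(W, seeds, alpha = 0.99,
                          normalization = c("symmetric", "random_walk")) {
  normalization <- match.arg(normalization)
  wm <- if (inherits(W, "affinity")) W$weights else W
  stopifnot(is.matrix(wm), nrow(wm) == ncol(wm))
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("alpha must lie in [0, 1)")
  }
  if (length(seeds) != nrow(wm)) stop("seed length must match node count")
  if (any(wm < 0)) stop("affinity weights must be nonnegative")
  deg <- rowSums(wm)
  if (normalization == "symmetric") {
    inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    s <- wm * (inv_sqrt %o% inv_sqrt)
    a <- diag(nrow(wm)) - alpha * s
  } else {
    # isolated nodes keep their seed value (degree floored at 1)
    a <- diag(pmax(deg, ifelse(deg > 0, deg, 1))) - alpha * wm
  }
  drop(solve(a, seeds))
}

#' Background saliency from three border seed sets
#'
#' Ranks the graph three times with seeds set to 1 on the top, left and
#' right border nodes respectively (labelled nodes 1, unlabelled 0),
#' multiplies the three rankings elementwise, min-max normalises the
#' product, and returns its complement: nodes that look unlike every border
#' get a score near 1.
#'
#' @param graph A `superpixel_graph`.
#' @param W First-stage `affinity`.
#' @param alpha Ranking parameter; default 0.99.
#' @return Numeric vector in \[0,1\] (the background-complement saliency).
#' @export
background_saliency <- function(graph, W, alpha = 0.99,
                                normalization = "random_walk") {
  stopifnot(inherits(graph, "superpixel_graph"))
  sides <- c("top", "left", "right")
  n <- graph$n_nodes
  prod_rank <- rep(1, n)
  for (side in sides) {
    nodes <- graph$boundary[[side]]
    if (!length(nodes)) stop("empty border seed set: ", side)
    y <- numeric(n)
    y[nodes] <- 1
    prod_rank <- prod_rank * manifold_rank(W, y, alpha, normalization)
  }
  1 - minmax_norm(prod_rank)
}

#' Diffusion-based compactness saliency
#'
#' For each node `p`, computes the score-weighted spatial variance of the
#' nodes with high affinity to `p` (`I_v`) and the distance of `p`'s
#' centroid to the score-weighted image centre (`I_d`), using the diffused
#' scores from the previous stage as weights. The sum is min-max normalised
#' and complemented, so spatially compact, centrally supported regions score
#' near 1.
#'
#' When `W` is an `affinity` object the colour kernel
#' `exp(-||lab_i - lab_j|| / sigma_c)` is evaluated densely (all node pairs):
#' compactness is a global property of a colour cluster's spatial support,
#' so restricting it to the ranking pattern would flatten the contrast. A
#' plain matrix `W` is used as given.
#'
#' @param graph A `superpixel_graph`.
#' @param W First-stage `affinity` (or plain matrix).
#' @param scores Diffused per-node scores (weights), nonnegative.
#' @return Numeric vector in \[0,1\].
#' @export
compactness_saliency <- function(graph, W, scores) {
  stopifnot(inherits(graph, "superpixel_graph"))
  n <- graph$n_nodes
  if (n == 1L) return(1)
  wm <- if (inherits(W, "affinity")) {
    d <- as.matrix(stats::dist(graph$mean_lab))
    exp(-d / W$sigma_c)
  } else {
    W
  }
  stopifnot(length(scores) == n, all(scores >= 0))
  pos <- graph$centroid
  cw <- wm * rep(scores, each = n)            # c_pq = w_pq * score_q
  diag(cw) <- diag(cw) + scores * 1e-9        # guard all-zero rows
  tot <- rowSums(cw)
  tot[tot == 0] <- 1
  mu_r <- (cw %*% pos[, 1]) / tot
  mu_c <- (cw %*% pos[, 2]) / tot
  i_v <- (cw %*% (pos[, 1]^2) / tot - mu_r^2) +
    (cw %*% (pos[, 2]^2) / tot - mu_c^2)
  i_v <- pmax(drop(i_v), 0)
  sw <- sum(scores)
  ctr <- if (sw > 0) colSums(pos * scores) / sw else colMeans(pos)
  i_d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
  1 - minmax_norm(i_v + i_d)
}

#' Coarse-to-fine refinement of the combined saliency
#'
#' Combines background and compactness saliency as `I_1 = norm(I_b + I_f)`,
#' augments the first-stage affinity with a saliency-similarity kernel
#' `exp(-|I_1(i) - I_1(j)| / sigma_s)` on the same sparsity pattern, re-ranks
#' with `I_1` as the seed, and min-max normalises the result.
#'
#' @param i_b Background saliency (normalised).
#' @param i_f Compactness saliency (normalised).
#' @param graph A `superpixel_graph`.
#' @param W First-stage `affinity`.
#' @param alpha Ranking parameter; default 0.99.
#' @param sigma_s Saliency bandwidth (unitless); default 0.1.
#' @param z Exponent applied to the saliency kernel; default 1.
#' @return A list with `i_1`, `i_2` (both in \[0,1\]) and `W_j2` (the
#'   second-stage `affinity`).
#' @export
combine_and_refine <- function(i_b, i_f, graph, W, alpha = 0.99,
                               sigma_s = 0.1, z = 1,
                               normalization = "random_walk") {
  stopifnot(inherits(W, "affinity"))
  i_1 <- minmax_norm(i_b + i_f)
  n <- graph$n_nodes
  sal_kernel <- matrix(0, n, n)
  d1 <- abs(outer(i_1, i_1, "-"))
  sal_kernel[W$pattern] <- exp(-d1[W$pattern] / sigma_s)^z
  w2 <- W$weights + sal_kernel
  W_j2 <- structure(
    list(weights = w2, pattern = W$pattern, sigma_c = W$sigma_c,
         sigma_s = sigma_s, stage = "J2"),
    class = "affinity"
  )
  i_2 <- minmax_norm(manifold_rank(W_j2, i_1, alpha, normalization))
  list(i_1 = i_1, i_2 = i_2, W_j2 = W_j2)
}

#' Project node saliency to pixels and threshold into a mask
#'
#' Builds the per-pixel saliency raster by node lookup, thresholds it with
#' Otsu's method, and produces the CIELAB colour-mapped image of the masked
#' region (channels rescaled to \[0,1\]; pixels outside the mask are set to
#' 0). A constant saliency map yields an all-background mask with a warning.
#'
#' @param i_2 Final node saliency in \[0,1\].
#' @param graph A `superpixel_graph`.
#' @param image The original H x W x 3 image.
#' @return A `segmentation_result`: list with `saliency_raster`, `mask`
#'   (0/1 matrix), `threshold`, `colormapped`.
#' @export
saliency_to_mask <- function(i_2, graph, image) {
  stopifnot(inherits(graph, "superpixel_graph"), length(i_2) == graph$n_nodes)
  raster <- matrix(i_2[graph$label_map], nrow(graph$label_map),
                   ncol(graph$label_map))
  thr <- otsu_threshold(as.vector(raster))
  if (is.na(thr)) {
    warning("constant saliency map; returning all-background mask")
    mask <- matrix(0L, nrow(raster), ncol(raster))
    thr <- Inf
  } else {
    mask <- (raster >= thr) * 1L
  }
  lab <- rgb_to_lab(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  cm <- array(0, dim = c(h, w, 3))
  cm[, , 1] <- matrix(lab[, 1] / 100, h, w)
  cm[, , 2] <- matrix((lab[, 2] + 128) / 255, h, w)
  cm[, , 3] <- matrix((lab[, 3] + 128) / 255, h, w)
  cm <- pmin(pmax(cm, 0), 1)
  out <- mask == 0L
  for (ch in 1:3) {
    plane <- cm[, , ch]
    plane[out] <- 0
    cm[, , ch] <- plane
  }
  structure(
    list(saliency_raster = raster, mask = mask, threshold = thr,
         colormapped = cm),
    class = "segmentation_result"
  )
}

#' Saliency-based grain segmentation, end to end
#'
#' Full single-image pipeline: superpixel graph, first-stage affinity,
#' boundary-seeded background saliency, diffusion compactness, coarse-to-
#' fine re-ranking, Otsu thresholding and Lab colour mapping. The bottom
#' border is deliberately not used as a background seed.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param n_segments Superpixel count; default 200.
#' @param alpha Ranking parameter; default 0.99.
#' @param sigma_c Colour bandwidth (Lab units); default 10.
#' @param sigma_s Saliency bandwidth; default 0.1.
#' @return A `segmentation_result` with the intermediate `graph` and node
#'   saliencies (`i_b`, `i_f`, `i_1`, `i_2`) attached.
#' @export
segment_image <- function(image, n_segments = 200L, alpha = 0.99,
                          sigma_c = 10, sigma_s = 0.1,
                          normalization = "random_walk") {
  graph <- build_superpixel_graph(image, n_segments)
  W <- build_affinity(graph, sigma_c)
  i_b <- background_saliency(graph, W, alpha, normalization)
  diffused <- manifold_rank(W, i_b, alpha, normalization)
  i_f <- compactness_saliency(graph, W, pmax(diffused, 0))
  refined <- combine_and_refine(i_b, i_f, graph, W, alpha, sigma_s,
                                normalization = normalization)
  res <- saliency_to_mask(refined$i_2, graph, image)
  res$graph <- graph
  res$i_b <- i_b
  res$i_f <- i_f
  res$i_1 <- refined$i_1
  res$i_2 <- refined$i_2
  res
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b 0/1 matrices of equal dimension.
#' @return Scalar IoU in \[0,1\] (1 if both masks are empty).
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  inter <- sum(a == 1L & b == 1L)
  uni <- sum(a == 1L | b == 1L)
  if (uni == 0) return(1)
  inter / uni
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", nrow(x$mask), "x", ncol(x$mask),
      " px, threshold ", signif(x$threshold, 4),
      ", mask area ", sum(x$mask), " px\n", sep = "")
  invisible(x)
}
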