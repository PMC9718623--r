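#' Oversegment an image into superpixels and build the region graph
#'
#' Runs a SLIC-style local k-means oversegmentation in CIELAB + position
#' space (grid-seeded centres, windowed assignment, the usual compactness
#' normalisation `m/S`), splits non-contiguous clusters into connected
#' components, absorbs tiny fragments into their dominant neighbour, and
#' summarises the result as a region adjacency graph.
#'
#' @param image H x W x 3 array in \[0,1\] (sRGB).
#' @param n_segments Target number of superpixels (>= 9).
#' @param compactness SLIC compactness weight `m` (Lab units); default 10.
#' @param n_iters Assignment/update iterations; default 10.
#' @return A `superpixel_graph`: list with `label_map` (H x W integers in
#'   `1:n_nodes`), `n_nodes`, `mean_lab` (n x 3), `centroid` (n x 2,
#'   (row, col) normalised to \[0,1\]), `sizes`, `adjacency` (two-column
#'   matrix of node pairs sharing a pixel boundary, each unordered pair
#'   once), and `boundary` (list of node-id vectors `top`, `left`, `right`,
#'   `bottom`).
#' @export
build_superpixel_graph <- function(image, n_segments = 200L,
                                   compactness = 10, n_iters = 10L) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (n_segments < 9) stop("n_segments must be >= 9")
  if (n_segments > h * w) stop("n_segments exceeds pixel count")

  lab <- rgb_to_lab(image)            # (h*w) x 3, column-major pixel order
  npx <- h * w
  step <- sqrt(npx / n_segments)
  px_row <- rep(seq_len(h), times = w)
  px_col <- rep(seq_len(w), each = h)

  # grid-seeded centres
  nr <- max(2L, round(h / step)); nc <- max(2L, round(w / step))
  cr <- (seq_len(nr) - 0.5) * h / nr
  cc <- (seq_len(nc) - 0.5) * w / nc
  centers <- cbind(rep(cr, times = nc), rep(cc, each = nr))
  k <- nrow(centers)
  init_idx <- pmin(pmax(round(centers[, 1]), 1), h) +
    (pmin(pmax(round(centers[, 2]), 1), w) - 1L) * h
  cen_lab <- lab[init_idx, , drop = FALSE]

  ratio2 <- (compactness / step)^2
  assign_id <- integer(npx)
  for (it in seq_len(n_iters)) {
    best <- rep(Inf, npx)
    assign_id[] <- 0L
    for (j in seq_len(k)) {
      r0 <- max(1L, floor(centers[j, 1] - 2 * step))
      r1 <- min(h, ceiling(centers[j, 1] + 2 * step))
      c0 <- max(1L, floor(centers[j, 2] - 2 * step))
      c1 <- min(w, ceiling(centers[j, 2] + 2 * step))
      rows <- r0:r1; cols <- c0:c1
      idx <- rep(rows, times = length(cols)) +
        (rep(cols, each = length(rows)) - 1L) * h
      dl <- lab[idx, 1] - cen_lab[j, 1]
      da <- lab[idx, 2] - cen_lab[j, 2]
      db <- lab[idx, 3] - cen_lab[j, 3]
      ds <- (px_row[idx] - centers[j, 1])^2 + (px_col[idx] - centers[j, 2])^2
      d <- dl * dl + da * da + db * db + ratio2 * ds
      upd <- d < best[idx]
      if (any(upd)) {
        ii <- idx[upd]
        best[ii] <- d[upd]
        assign_id[ii] <- j
      }
    }
    # any pixel outside every window: nearest centre spatially
    miss <- which(assign_id == 0L)
    if (length(miss)) {
      for (m in miss) {
        dd <- (centers[, 1] - px_row[m])^2 + (centers[, 2] - px_col[m])^2
        assign_id[m] <- which.min(dd)
      }
    }
    # centre update (rowsum rows follow sorted unique group ids)
    cnt <- tabulate(assign_id, nbins = k)
    present <- sort(unique(assign_id))
    centers[present, 1] <- rowsum(px_row, assign_id)[, 1] / cnt[present]
    centers[present, 2] <- rowsum(px_col, assign_id)[, 1] / cnt[present]
    cen_lab[present, ] <- rowsum(lab, assign_id) / cnt[present]
  }

  lbl <- matrix(assign_id, h, w)
  lbl <- split_components(lbl)
  lbl <- absorb_small_regions(lbl, min_size = max(4L, floor(step^2 / 4)))
  superpixel_graph_from_labels(lbl, lab)
}

# Relabel so that every connected component (4-neighbourhood) of a cluster
# becomes its own region. Vectorised min-propagation of component ids.
split_components <- function(lbl) {
  h <- nrow(lbl); w <- ncol(lbl)
  comp <- matrix(seq_len(h * w), h, w)
  repeat {
    prev <- comp
    # up
    same <- lbl[-1, ] == lbl[-h, ]
    comp[-1, ][same] <- pmin(comp[-1, ][same], comp[-h, ][same])
    # down
    same <- lbl[-h, ] == lbl[-1, ]
    comp[-h, ][same] <- pmin(comp[-h, ][same], comp[-1, ][same])
    # left
    same <- lbl[, -1] == lbl[, -w]
    comp[, -1][same] <- pmin(comp[, -1][same], comp[, -w][same])
    # right
    same <- lbl[, -w] == lbl[, -1]
    comp[, -w][same] <- pmin(comp[, -w][same], comp[, -1][same])
    if (identical(prev, comp)) break
  }
  matrix(match(comp, sort(unique(as.vector(comp)))), h, w)
}

# Merge regions smaller than min_size into the neighbouring region sharing
# the longest boundary with them.
absorb_small_regions <- function(lbl, min_size) {
  repeat {
    sizes <- tabulate(lbl)
    small <- which(sizes > 0 & sizes < min_size)
    if (!length(small)) break
    pairs <- neighbor_pairs(lbl)
    changed <- FALSE
    for (s in small) {
      nb <- c(pairs[pairs[, 1] == s, 2], pairs[pairs[, 2] == s, 1])
      if (!length(nb)) next
      tgt <- as.integer(names(sort(table(nb), decreasing = TRUE))[1])
      lbl[lbl == s] <- tgt
      changed <- TRUE
    }
    if (!changed) break
    lbl <- matrix(match(lbl, sort(unique(as.vector(lbl)))), nrow(lbl), ncol(lbl))
  }
  lbl
}

# All 4-neighbour pixel label pairs (with multiplicity = shared boundary len).
neighbor_pairs <- function(lbl) {
  h <- nrow(lbl); w <- ncol(lbl)
  a <- c(lbl[-h, ], lbl[, -w])
  b <- c(lbl[-1, ], lbl[, -1])
  diffp <- a != b
  cbind(pmin(a[diffp], b[diffp]), pmax(a[diffp], b[diffp]))
}

# Assemble the region adjacency graph from a final label map.
superpixel_graph_from_labels <- function(lbl, lab) {
  h <- nrow(lbl); w <- ncol(lbl)
  n <- max(lbl)
  sizes <- tabulate(lbl, nbins = n)
  stopifnot(all(sizes > 0))
  px_row <- rep(seq_len(h), times = w)
  px_col <- rep(seq_len(w), each = h)
  v <- as.vector(lbl)
  mean_lab <- rowsum(lab, v) / sizes
  centroid <- cbind((rowsum(px_row, v)[, 1] / sizes - 1) / max(1, h - 1),
                    (rowsum(px_col, v)[, 1] / sizes - 1) / max(1, w - 1))
  pairs <- unique(neighbor_pairs(lbl))
  structure(
    list(
      label_map = lbl, n_nodes = n, mean_lab = mean_lab,
      centroid = centroid, sizes = sizes, adjacency = pairs,
      boundary = list(
        top = sort(unique(lbl[1, ])),
        left = sort(unique(lbl[, 1])),
        right = sort(unique(lbl[, w])),
        bottom = sort(unique(lbl[h, ]))
      )
    ),
    class = "superpixel_graph"
  )
}

#' @export
print.superpixel_graph <- function(x, ...) {
  cat("<superpixel_graph> ", x$n_nodes, " nodes over ",
      nrow(x$label_map), "x", ncol(x$label_map), " pixels, ",
      nrow(x$adjacency), " adjacent pairs\n", sep = "")
  invisible(x)
}
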