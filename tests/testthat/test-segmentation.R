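test_that("superpixel graph partitions the image and oversegments sanely", {
  img <- array(0.5, dim = c(128, 128, 3))
  g <- build_superpixel_graph(img, 100)
  expect_true(g$n_nodes >= 50 && g$n_nodes <= 150)
  # constant input: every node has the same colour
  expect_lt(max(stats::dist(g$mean_lab)), 1e-6)
  # tessellation symmetry: node centroids average to the image centre
  expect_equal(colMeans(g$centroid), c(0.5, 0.5), tolerance = 0.05)
  # partition: labels cover 1..n and every node is nonempty
  expect_setequal(unique(as.vector(g$label_map)), seq_len(g$n_nodes))
  expect_true(all(g$sizes > 0))
  expect_equal(sum(g$sizes), 128 * 128)
  # adjacency pairs are irreflexive and stored once
  expect_true(all(g$adjacency[, 1] < g$adjacency[, 2]))
  expect_true(all(unlist(g$boundary) %in% seq_len(g$n_nodes)))
  expect_error(build_superpixel_graph(img, 8), "n_segments")
  expect_error(build_superpixel_graph(img, 1e6), "exceeds")
})

test_that("first-stage affinity follows the colour kernel on the sparsity pattern", {
  lab <- rbind(c(50, 0, 0), c(50, 0, 0), c(50, 10, 0), c(80, 0, 0))
  cent <- cbind(c(0.1, 0.5, 0.9, 0.5), c(0.5, 0.5, 0.5, 0.9))
  # path graph 1-2-3, node 4 adjacent to 3 only: 1 and 4 are 3 hops apart
  g <- toy_graph(lab, cent, rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
                 boundary = list(top = 1L, left = 2L, right = 3L,
                                 bottom = 3L))
  W <- build_affinity(g, sigma_c = 10, connect_boundary = FALSE)
  expect_equal(W$weights[1, 2], 1)                       # identical colours
  expect_equal(W$weights[1, 4], 0)                       # beyond 2 hops
  expect_equal(W$weights[2, 3], exp(-1))                 # distance = sigma_c
  expect_true(isSymmetric(W$weights))
  expect_equal(diag(W$weights), rep(0, 4))
  expect_true(all(W$weights >= 0 & W$weights <= 1))
  expect_error(build_affinity(g, sigma_c = 0), "sigma_c")
})

test_that("manifold ranking solves the closed-form system", {
  # alpha = 0 returns the seeds unchanged
  w <- random_affinity(6)
  y <- stats::runif(6)
  expect_equal(manifold_rank(w, y, alpha = 0), y)

  # two-node graph, unit weight: direct 2x2 solve gives (4/3, 2/3)
  w2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(manifold_rank(w2, c(1, 0), alpha = 0.5), c(4 / 3, 2 / 3))

  # vertex-transitive ring with uniform seeds stays uniform
  ring <- matrix(0, 5, 5)
  for (i in 1:5) ring[i, i %% 5 + 1] <- ring[i %% 5 + 1, i] <- 1
  r <- manifold_rank(ring, rep(1, 5), alpha = 0.8)
  expect_lt(diff(range(r)), 1e-10)

  expect_error(manifold_rank(w, y, alpha = 1), "alpha")
  expect_error(manifold_rank(w, y[-1], 0.5), "seed length")
})

test_that("manifold ranking matches a dense brute-force solve on random graphs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    w <- random_affinity(n)
    y <- stats::runif(n)
    alpha <- stats::runif(1, 0, 0.99)
    for (nrm in c("symmetric", "random_walk")) {
      expect_equal(manifold_rank(w, y, alpha, nrm),
                   drop(brute_force_rank(w, y, alpha, nrm)),
                   tolerance = 1e-8)
    }
  }
})

test_that("increasing a seed entry never decreases that node's rank", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    w <- random_affinity(n)
    y <- stats::runif(n)
    i <- sample(n, 1)
    base <- manifold_rank(w, y, 0.9)
    y2 <- y; y2[i] <- y2[i] + 0.5
    expect_gte(manifold_rank(w, y2, 0.9)[i], base[i] - 1e-12)
  }
})

test_that("background saliency peaks on the node unlike every border", {
  # 3x3 block layout: node 5 is the centre with a distinct colour
  lab <- matrix(0, 9, 3)
  lab[5, ] <- c(60, 20, 20)
  cent <- cbind(rep(c(0, 0.5, 1), 3), rep(c(0, 0.5, 1), each = 3))
  adj <- rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6), c(7, 8), c(8, 9),
               c(1, 4), c(4, 7), c(2, 5), c(5, 8), c(3, 6), c(6, 9))
  g <- toy_graph(lab, cent, adj,
                 boundary = list(top = c(1L, 4L, 7L), left = c(1L, 2L, 3L),
                                 right = c(7L, 8L, 9L), bottom = c(3L, 6L, 9L)))
  W <- build_affinity(g, sigma_c = 10)
  i_b <- background_saliency(g, W, alpha = 0.9)
  expect_equal(which.max(i_b), 5L)
  expect_equal(max(i_b), 1)   # complement of the min-max minimum
  expect_equal(min(i_b), 0)   # complement of the min-max maximum
  expect_true(all(i_b >= 0 & i_b <= 1))

  g_empty <- g; g_empty$boundary$top <- integer()
  expect_error(background_saliency(g_empty, W), "empty border")
})

test_that("compactness saliency rewards tight, central, high-score clusters", {
  # tight bright cluster near centre (1:3) vs dispersed dim nodes (4:6)
  cent <- rbind(c(0.5, 0.5), c(0.52, 0.5), c(0.5, 0.52),
                c(0.05, 0.05), c(0.95, 0.1), c(0.1, 0.95))
  w <- matrix(0.02, 6, 6); diag(w) <- 0
  w[1:3, 1:3] <- 0.9; diag(w) <- 0
  g <- toy_graph(matrix(0, 6, 3), cent,
                 rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(5L, 6L)))
  scores <- c(1, 1, 1, 0.1, 0.1, 0.1)
  i_f <- compactness_saliency(g, w, scores)
  expect_gt(mean(i_f[1:3]), mean(i_f[4:6]))
  expect_true(all(i_f >= 0 & i_f <= 1))
  # the complement construction pins the extremes of I_v + I_d
  expect_equal(max(i_f), 1)
  expect_equal(min(i_f), 0)
  # single-node graph degenerates to the constant 1
  g1 <- toy_graph(matrix(0, 1, 3), cbind(0.5, 0.5),
                  matrix(integer(), 0, 2))
  expect_equal(compactness_saliency(g1, matrix(0, 1, 1), 1), 1)
})

test_that("coarse-to-fine refinement preserves constants and the J2 construction", {
  s <- grain_fixture()[[1]]
  g <- build_superpixel_graph(s$image, 100)
  W <- build_affinity(g, 10)
  n <- g$n_nodes

  # constant stage-one saliencies give a constant refined map
  refined <- combine_and_refine(rep(0.5, n), rep(0.5, n), g, W, alpha = 0.9)
  expect_lt(diff(range(refined$i_2)), 1e-10)

  # with J1 weights zeroed and a huge sigma_s, J2 becomes the unit-weight
  # pattern graph and the ranking matches a direct solve on it
  W0 <- W; W0$weights <- W$weights * 0
  i_1 <- minmax_norm(stats::runif(n))
  ref0 <- combine_and_refine(i_1 * 0.5, i_1 * 0.5, g, W0, alpha = 0.9,
                             sigma_s = 1e9)
  unit <- matrix(0, n, n); unit[W$pattern] <- 1
  seed1 <- minmax_norm(i_1 * 0.5 + i_1 * 0.5)
  direct <- minmax_norm(manifold_rank(unit, seed1, 0.9, "random_walk"))
  expect_equal(ref0$i_2, direct, tolerance = 1e-6)

  # J2 weights live on J1's pattern
  expect_true(all(ref0$W_j2$weights[!W$pattern] == 0))
})

test_that("saliency-to-mask thresholds per definition and maps colour", {
  s <- grain_fixture()[[1]]
  g <- build_superpixel_graph(s$image, 100)
  # binary node saliency: mask equals the 1-region exactly
  i_bin <- as.numeric(seq_len(g$n_nodes) %in% 1:5)
  res <- saliency_to_mask(i_bin, g, s$image)
  expect_identical(res$mask == 1L, res$saliency_raster >= res$threshold)
  expect_identical(as.vector(res$mask == 1L),
                   as.vector(g$label_map %in% 1:5))
  expect_equal(sum(res$mask), sum(res$saliency_raster >= res$threshold))
  # colourmapped pixels outside the mask are the constant background 0
  for (ch in 1:3) {
    expect_true(all(res$colormapped[, , ch][res$mask == 0L] == 0))
  }
  # constant saliency yields an all-background mask with a warning
  expect_warning(res0 <- saliency_to_mask(rep(0.3, g$n_nodes), g, s$image),
                 "constant")
  expect_equal(sum(res0$mask), 0)
})

test_that("end-to-end segmentation recovers the grain mask", {
  for (s in grain_fixture()[c(1, 6)]) {
    res <- segment_image(s$image)
    expect_gte(mask_iou(res$mask, s$mask), 0.80)
    expect_true(all(res$i_2 >= 0 & res$i_2 <= 1))
    expect_true(all(res$i_b >= 0 & res$i_b <= 1))
    expect_true(all(res$i_f >= 0 & res$i_f <= 1))
  }
})

test_that("directory segmentation writes masks, colormaps and a log", {
  dir_in <- withr::local_tempdir(); dir_out <- withr::local_tempdir()
  write_grain_samples(grain_fixture()[1:2], dir_in)
  log <- segment_directory(dir_in, dir_out, save_saliency = TRUE)
  expect_equal(nrow(log), 2)
  expect_named(log, c("image", "n_nodes", "threshold", "mask_area_px"))
  expect_true(all(file.exists(file.path(dir_out, sub("\\.png$", "_mask.png",
                                                     log$image)))))
  expect_true(file.exists(file.path(dir_out, "segmentation_log.csv")))
})
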