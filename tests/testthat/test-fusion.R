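test_that("Pearson correlation follows the covariance formula and conventions", {
  x <- c(1, 2, 3)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  # direct arithmetic oracle: cov = 1.5, var_x = 1, var_y = 7/3
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)),
               1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(round(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  expect_equal(pearson_correlation(rep(2, 5), 1:5), 0)
  expect_error(pearson_correlation(1:3, 1:4), "length")
})

test_that("binned maximal correlation attains the Borel-function supremum", {
  set.seed(1)
  x <- stats::runif(500, -1, 1)
  # monotone identity: supremum reached by the identity transform
  expect_gte(maximal_correlation_binned(x, x), 0.98)
  # independence: concentrates near zero (checked over seeds)
  cvs <- purrr::map_dbl(1:20, function(sd) {
    set.seed(sd)
    maximal_correlation_binned(stats::runif(500), stats::runif(500))
  })
  expect_true(all(cvs <= 0.2))
  # y = x^2 on symmetric x: Pearson is ~0 but a Borel transform aligns them
  y <- x^2
  expect_lt(abs(pearson_correlation(x, y)), 0.15)
  expect_gte(maximal_correlation_binned(x, y), 0.8)
  # dominates |Pearson| up to the estimator tolerance
  set.seed(3)
  for (rep in 1:5) {
    a <- stats::rnorm(300)
    b <- 0.6 * a + stats::rnorm(300, sd = 0.8)
    expect_gte(maximal_correlation_binned(a, b),
               abs(pearson_correlation(a, b)) - 0.02)
  }
  expect_error(maximal_correlation_binned(1:5, 1:5, n_bins = 8), "at least")
})

test_that("fusion drops exact duplicates and uncorroborated columns", {
  set.seed(2)
  n <- 500
  base <- stats::rnorm(n)
  f_a <- as_feature_tibble(cbind(a1 = base, a2 = stats::rnorm(n) + 0.5 * base),
                           labels = rep(0:1, each = n / 2))
  # view B: an exact copy of a1, a corroborated column, and pure noise
  f_b <- as_feature_tibble(cbind(b1 = base, b2 = base + stats::rnorm(n),
                                 b_noise = stats::rnorm(n)),
                           labels = rep(0:1, each = n / 2))
  res <- fuse_features(f_a, f_b, fusion_config())
  # exactly one of the duplicate pair survives (the earlier column)
  expect_true("a1" %in% res$report$kept_ids)
  expect_false("b1" %in% res$report$kept_ids)
  expect_true(any(res$report$dropped_redundant$dropped_id == "b1"))
  # the independent noise column falls to the corroboration rule
  expect_true("b_noise" %in% res$report$dropped_low$id)
  expect_lte(res$report$dropped_low$max_abs_r[
    res$report$dropped_low$id == "b_noise"], 0.05)
  # report partitions the input columns
  expect_setequal(
    c(res$report$kept_ids, res$report$dropped_redundant$dropped_id,
      res$report$dropped_low$id),
    c("a1", "a2", "b1", "b2", "b_noise"))
  expect_equal(res$report$fused_dim, ncol(res$features) - 2L)
})

test_that("fusion matches the exhaustive pairwise oracle on crafted matrices", {
  set.seed(5)
  n <- 200
  # crafted 12-column structure: duplicates, near-duplicates, noise
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
  xa <- cbind(c1 = z1, c2 = z1 + stats::rnorm(n, sd = 0.1), c3 = z2,
              c4 = stats::rnorm(n), c5 = z3, c6 = -z3)
  xb <- cbind(d1 = z1, d2 = z2 + stats::rnorm(n, sd = 0.05), d3 = z3,
              d4 = stats::rnorm(n), d5 = 0.7 * z2 + stats::rnorm(n),
              d6 = rep(1, n))
  res <- fuse_features(as_feature_tibble(xa), as_feature_tibble(xb),
                       fusion_config())
  oracle <- brute_force_fuse(cbind(xa, xb), rep(c("a", "b"), each = 6),
                             0.9, 0.05)
  expect_identical(res$report$kept_ids, oracle)

  # randomised matrices up to 20 columns
  for (rep in 1:5) {
    pa <- sample(2:10, 1); pb <- sample(2:10, 1)
    raw <- matrix(stats::rnorm(n * (pa + pb)), n)
    # inject correlation structure
    raw[, 1] <- raw[, pa + 1] + stats::rnorm(n, sd = 0.05)
    colnames(raw) <- sprintf("g_%02d", seq_len(pa + pb))
    fa <- as_feature_tibble(raw[, seq_len(pa), drop = FALSE])
    fb <- as_feature_tibble(raw[, pa + seq_len(pb), drop = FALSE])
    res_r <- fuse_features(fa, fb, fusion_config(tau_high = 0.8,
                                                 tau_low = 0.1))
    oracle_r <- brute_force_fuse(raw, rep(c("a", "b"), c(pa, pb)), 0.8, 0.1)
    expect_identical(res_r$report$kept_ids, oracle_r)
  }
})

test_that("fusion dimensionality and determinism invariants hold", {
  set.seed(9)
  n <- 100
  xa <- matrix(stats::rnorm(n * 4), n,
               dimnames = list(NULL, paste0("a", 1:4)))
  xb <- matrix(stats::rnorm(n * 4), n,
               dimnames = list(NULL, paste0("b", 1:4)))
  fa <- as_feature_tibble(xa); fb <- as_feature_tibble(xb)
  r1 <- fuse_features(fa, fb, fusion_config(tau_low = 0.01))
  r2 <- fuse_features(fa, fb, fusion_config(tau_low = 0.01))
  expect_identical(r1$report$kept_ids, r2$report$kept_ids)
  expect_lte(r1$report$fused_dim, 8)
  # equality iff no rule fires
  fired <- nrow(r1$report$dropped_redundant) + nrow(r1$report$dropped_low)
  expect_equal(r1$report$fused_dim == 8, fired == 0)
  # misaligned sample ids raise
  fb_bad <- fb; fb_bad$sample_id <- rev(fb_bad$sample_id)
  expect_error(fuse_features(fa, fb_bad, fusion_config()), "sample_id")
})
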