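test_that("fragrance follows f = c * I^a", {
  cfg <- boa_config()
  expect_equal(fragrance(cfg, 0), 0)
  expect_equal(fragrance(boa_config(sensory_c = 1, power_a = 1), 3.7), 3.7)
  expect_equal(fragrance(boa_config(sensory_c = 0.01, power_a = 0.5), 4),
               0.02)
  expect_error(fragrance(cfg, -1), "nonnegative")
  expect_error(boa_config(pop_size = 2), "pop_size")
  expect_error(boa_config(power_a = 0), "power_a")
})

test_that("global and local moves evaluate and clamp correctly", {
  # zero fragrance: no movement
  expect_equal(global_move(c(0.2, 0.7), c(0.9, 0.1), rn = 0.3, f = 0),
               c(0.2, 0.7))
  # rn^2 * b_p exactly cancels the position: step is zero
  expect_equal(global_move(0.2, 0.8, rn = 0.5, f = 1), 0.2)
  # at the optimum with rn = 1 the step vanishes for any fragrance
  expect_equal(global_move(0.6, 0.6, rn = 1, f = 0.4), 0.6)
  # results stay inside the unit box
  expect_equal(global_move(0.1, 1, rn = 1, f = 5), 1)

  # identical peers with rn = 1: difference term vanishes
  expect_equal(local_move(0.5, 0.3, 0.3, rn = 1, f = 2), 0.5)
  expect_equal(local_move(0.5, 0.6, 0.4, rn = 0.9, f = 0), 0.5)
  # direct evaluation: 0.5 + (0.6 - 0.4) * 0.5 = 0.6
  expect_equal(local_move(0.5, 0.6, 0.4, rn = 1, f = 0.5), 0.6)
})

test_that("binarisation thresholds positions and repairs empty masks", {
  expect_equal(binarize(c(1, 1, 1)), c(1L, 1L, 1L))
  expect_equal(binarize(c(0.4, 0.6, 0.5), 0.5), c(0L, 1L, 0L))
  # all-zero mask repaired at the largest position, first index on ties
  expect_equal(binarize(c(0, 0, 0)), c(1L, 0L, 0L))
  expect_equal(binarize(c(0.1, 0.3, 0.3)), c(0L, 1L, 0L))
})

test_that("wrapper fitness is CV error plus the cardinality penalty", {
  # widely separated informative block: the wrapper error is exactly zero
  sep <- gen_feature_matrix(synthetic_feature_spec(
    delta = 8, k_informative = 10, k_redundant = 0, k_noise = 10, seed = 2))
  d_sep <- 20L
  inf_sep <- as.integer(seq_len(d_sep) <= 10)
  fit_sep <- make_fitness(sep$features, lam = 0, seed = 1)
  expect_equal(fit_sep(inf_sep), 0)

  fx <- feature_fixture()
  d <- 60L
  inf_mask <- as.integer(seq_len(d) <= 10)
  all_mask <- rep(1L, d)
  fit0 <- make_fitness(fx$features, lam = 0, seed = 1)
  fit <- make_fitness(fx$features, lam = 0.01, seed = 1)
  # penalty accounting: all-features fitness = cv_error + lam
  expect_equal(fit(all_mask), fit0(all_mask) + 0.01)
  expect_lt(fit(inf_mask), fit(all_mask))
  # repeated evaluation is stable regardless of RNG state
  set.seed(123); a <- fit0(all_mask)
  set.seed(456); b <- fit0(all_mask)
  expect_identical(a, b)
  expect_error(fit(rep(0L, d)), "empty")
})

test_that("CE updates implement the smoothed Bernoulli MLE", {
  st <- ce_state(2, alpha_s = 0.5)
  st$a_k <- c(0.5, 0.5)
  elites <- rbind(c(1, 0), c(1, 1))
  up <- ce_update(elites, st)
  expect_equal(up$a_k, c(0.75, 0.5))

  # alpha_s = 1 jumps to the elite mean; alpha_s = 0 keeps the state
  st1 <- ce_state(2, alpha_s = 1); st1$a_k <- c(0.5, 0.5)
  expect_equal(ce_update(elites, st1)$a_k, c(0.99, 0.5))  # 1.0 clipped
  st0 <- ce_state(2, alpha_s = 0); st0$a_k <- c(0.5, 0.5)
  expect_equal(ce_update(elites, st0)$a_k, c(0.5, 0.5))

  expect_warning(un <- ce_update(matrix(numeric(), 0, 2), st), "empty elite")
  expect_equal(un$a_k, st$a_k)
  # probabilities stay clipped away from degeneracy
  expect_true(all(up$a_k >= 0.01 & up$a_k <= 0.99))
})

test_that("the improved BOA run keeps its bookkeeping invariants", {
  fx <- feature_fixture()
  cfg <- boa_config(n_iters = 20, seed = 4)
  sel <- run_improved_boa(fx$features, cfg)
  expect_s3_class(sel, "boa_selection")
  expect_gte(sel$n_selected, 1)
  # best-ever trace is monotonically non-increasing
  expect_true(all(diff(sel$best_fitness_trace) <= 1e-12))
  expect_length(sel$best_fitness_trace, 21)
  # determinism under identical seed/config/data
  sel2 <- run_improved_boa(fx$features, cfg)
  expect_identical(sel$mask, sel2$mask)
  expect_identical(sel$best_fitness_trace, sel2$best_fitness_trace)
  # tidy/glance accessors
  td <- tidy(sel)
  expect_equal(sum(td$selected), sel$n_selected)
  expect_equal(glance(sel)$n_features, 60)

  # n_iters = 0 returns the best of the random initial population
  sel0 <- run_improved_boa(fx$features, boa_config(n_iters = 0, seed = 4))
  expect_length(sel0$best_fitness_trace, 1)
  expect_gte(sel0$best_fitness, sel$best_fitness)
})

test_that("with CE disabled the run reduces to canonical BOA", {
  fx <- feature_fixture()
  cfg <- boa_config(n_iters = 10, seed = 2)
  st <- ce_state(60)
  sel <- run_improved_boa(fx$features, cfg, ce = st, ce_mode = "off")
  # the CE distribution is never touched
  expect_identical(sel$ce$a_k, st$a_k)
  expect_true(is.na(sel$ce$gamma))
  # and the run is still deterministic
  sel2 <- run_improved_boa(fx$features, cfg, ce = ce_state(60),
                           ce_mode = "off")
  expect_identical(sel$mask, sel2$mask)
})

test_that("canonical BOA minimises the sphere function", {
  res <- run_boa_continuous(function(x) sum(x^2), d = 2,
                            boa_config(n_iters = 100, seed = 3))
  expect_lt(res$best_fitness, 0.01)
  expect_true(all(diff(res$trace) <= 1e-12))
})
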