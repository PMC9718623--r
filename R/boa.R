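#' Butterfly-optimization configuration
#'
#' @param pop_size Population size (>= 4); default 30.
#' @param n_iters Iterations; default 200.
#' @param sensory_c Sensory modality `c` of the fragrance law; default 0.01.
#' @param power_a Power exponent `a` in `(0, 1]`; default 0.1.
#' @param switch_p Probability of the global (toward-best) move versus the
#'   local (peer-difference) move; default 0.8.
#' @param bin_thresh Threshold mapping a continuous position to a feature
#'   bit; default 0.5.
#' @param seed Integer seed; default 1.
#' @return A `boa_config` list.
#' @export
boa_config <- function(pop_size = 30L, n_iters = 200L, sensory_c = 0.01,
                       power_a = 0.1, switch_p = 0.8, bin_thresh = 0.5,
                       seed = 1L) {
  if (pop_size < 4) stop("pop_size must be >= 4")
  if (!(power_a > 0 && power_a <= 1)) stop("power_a must lie in (0, 1]")
  if (!(switch_p >= 0 && switch_p <= 1)) stop("switch_p must lie in [0, 1]")
  if (n_iters < 0) stop("n_iters must be >= 0")
  structure(list(pop_size = as.integer(pop_size), n_iters = as.integer(n_iters),
                 sensory_c = sensory_c, power_a = power_a,
                 switch_p = switch_p, bin_thresh = bin_thresh,
                 seed = as.integer(seed)),
            class = "boa_config")
}

#' Cross-entropy sampler state
#'
#' Bernoulli distribution over feature subsets maintained by the
#' cross-entropy method: elite solutions (fitness at or below the
#' rho-quantile threshold gamma) refresh the per-dimension inclusion
#' probabilities by the KL-minimising Bernoulli MLE, smoothed as
#' `a_{k+1} = alpha_s * a^+ + (1 - alpha_s) * a_k` and clipped to
#' \[0.01, 0.99\] to keep sampling non-degenerate.
#'
#' @param d Number of dimensions (features).
#' @param rho Elite fraction; default 0.1.
#' @param alpha_s Smoothing parameter in \[0, 1\]; default 0.7.
#' @param n_ce Fresh CE samples injected per iteration; default `NULL`
#'   (resolved to the population size at run time).
#' @param a0 Initial inclusion probability; default 0.5.
#' @return A `ce_state` list with `a_k`, `rho`, `alpha_s`, `n_ce`, `gamma`.
#' @export
ce_state <- function(d, rho = 0.1, alpha_s = 0.7, n_ce = NULL, a0 = 0.5) {
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]")
  if (!(alpha_s >= 0 && alpha_s <= 1)) stop("alpha_s must lie in [0, 1]")
  structure(list(a_k = rep(a0, d), rho = rho, alpha_s = alpha_s,
                 n_ce = n_ce, gamma = NA_real_),
            class = "ce_state")
}

#' Fragrance perceived for a stimulus intensity
#'
#' The butterfly fragrance law `f = c * I^a` with sensory modality `c`,
#' stimulus intensity `I` and power exponent `a`.
#'
#' @param cfg A [boa_config()].
#' @param stimulus Nonnegative stimulus intensity.
#' @return Scalar fragrance.
#' @export
fragrance <- function(cfg, stimulus) {
  if (any(stimulus < 0)) stop("stimulus must be nonnegative")
  cfg$sensory_c * stimulus^cfg$power_a
}

#' Global (toward-best) butterfly move
#'
#' `P' = P + (rn^2 * b_p - P) * f`, clamped to the unit box.
#'
#' @param position Current position vector.
#' @param best Best-known position `b_p`.
#' @param rn Uniform draw in \[0,1\].
#' @param f Fragrance of the moving butterfly.
#' @param lower,upper Box bounds; default \[0,1\].
#' @return New position vector.
#' @export
global_move <- function(position, best, rn, f, lower = 0, upper = 1) {
  stopifnot(rn >= 0, rn <= 1)
  pmin(pmax(position + (rn^2 * best - position) * f, lower), upper)
}

#' Local (peer-difference) butterfly move
#'
#' `P' = P + (rn^2 * P_k - P_l) * f` for two distinct peers, clamped.
#'
#' @param position Current position vector.
#' @param peer_k,peer_l Positions of two distinct peers.
#' @param rn Uniform draw in \[0,1\].
#' @param f Fragrance of the moving butterfly.
#' @param lower,upper Box bounds; default \[0,1\].
#' @return New position vector.
#' @export
local_move <- function(position, peer_k, peer_l, rn, f,
                       lower = 0, upper = 1) {
  stopifnot(rn >= 0, rn <= 1)
  pmin(pmax(position + (rn^2 * peer_k - peer_l) * f, lower), upper)
}

#' Binarize a continuous position into a feature mask
#'
#' Bit `i` is 1 iff `position[i] > bin_thresh`. An all-zero mask is repaired
#' by setting the single bit with the largest position (first index on
#' ties), so the wrapper fitness always sees at least one feature.
#'
#' @param position Vector in \[0,1\]^D.
#' @param bin_thresh Threshold; default 0.5.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(position, bin_thresh = 0.5) {
  mask <- as.integer(position > bin_thresh)
  if (!any(mask == 1L)) mask[which.max(position)] <- 1L
  mask
}

# Stratified fold assignment, deterministic under seed.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Wrapper fitness for a feature mask
#'
#' Builds a memoised fitness function: cross-validated 5-NN error on the
#' selected columns (stratified folds fixed once from `seed`) plus a
#' cardinality penalty `lam * n_selected / D`. Lower is better. The stimulus
#' intensity fed to the fragrance law is `1 / (fitness + 1e-6)`.
#'
#' @param features Feature tibble (`sample_id`, `label`, columns).
#' @param lam Penalty weight; default 0.01.
#' @param k Neighbours; default 5.
#' @param n_folds CV folds; default 3.
#' @param seed Fold seed; default 1.
#' @return A function `mask -> fitness`.
#' @export
make_fitness <- function(features, lam = 0.01, k = 5L, n_folds = 3L,
                         seed = 1L) {
  u <- unpack_features(features)
  x <- u$x   # columns used on their native scale
  labels <- factor(u$labels)
  d <- ncol(x)
  fold <- stratified_folds(u$labels, n_folds, seed)
  cache <- new.env(parent = emptyenv())
  function(mask) {
    stopifnot(length(mask) == d)
    if (!any(mask == 1L)) stop("empty feature mask")
    key <- paste(which(mask == 1L), collapse = ",")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    cols <- mask == 1L
    # knn breaks vote ties by a random draw; evaluate under a local seed so
    # a mask's fitness does not depend on when it is evaluated
    err <- with_seed(seed, {
      e <- 0
      for (f in seq_len(n_folds)) {
        te <- fold == f
        pred <- class::knn(x[!te, cols, drop = FALSE],
                           x[te, cols, drop = FALSE],
                           labels[!te], k = k)
        e <- e + sum(pred != labels[te])
      }
      e
    })
    fit <- err / length(labels) + lam * sum(cols) / d
    assign(key, fit, envir = cache)
    fit
  }
}

#' Cross-entropy distribution update from elite masks
#'
#' `a^+` is the per-dimension mean of the elite bits (the KL-minimising
#' Bernoulli MLE); the state is smoothed as
#' `a_{k+1} = alpha_s * a^+ + (1 - alpha_s) * a_k` and clipped to
#' \[0.01, 0.99\]. An empty elite set returns the state unchanged with a
#' warning.
#'
#' @param elite_masks Matrix of elite masks (rows = elites) or a list of
#'   0/1 vectors.
#' @param state A [ce_state()].
#' @return The updated `ce_state`.
#' @export
ce_update <- function(elite_masks, state) {
  stopifnot(inherits(state, "ce_state"))
  if (is.list(elite_masks)) elite_masks <- do.call(rbind, elite_masks)
  if (is.null(elite_masks) || nrow(elite_masks) == 0) {
    warning("empty elite set; CE state unchanged")
    return(state)
  }
  a_plus <- colMeans(elite_masks)
  a_new <- state$alpha_s * a_plus + (1 - state$alpha_s) * state$a_k
  state$a_k <- pmin(pmax(a_new, 0.01), 0.99)
  state
}

#' Improved butterfly optimization for wrapper feature selection
#'
#' Canonical butterfly moves hybridised with the cross-entropy method. Per
#' iteration: (i) every butterfly takes the global move with probability
#' `switch_p`, else the local move, with fragrance computed from its own
#' fitness; (ii) fitnesses are evaluated on the binarized positions;
#' (iii) the CE Bernoulli distribution is refreshed from the elite fraction;
#' (iv) `n_ce` fresh masks are sampled from it and replace the worst
#' butterflies' positions (`ce_mode = "inject"`), or the CE sample replaces
#' the global move itself (`"replace-global"`); (v) the best-ever mask is
#' updated. `ce_mode = "off"` reduces exactly to canonical BOA.
#'
#' @param features Feature tibble (`sample_id`, `label`, columns).
#' @param cfg A [boa_config()].
#' @param ce A [ce_state()] or `NULL` (defaults built from the feature
#'   count).
#' @param lam Cardinality penalty weight; default 0.01.
#' @param ce_mode `"inject"` (default), `"replace-global"` or `"off"`.
#' @param fitness Optional fitness function `mask -> scalar`; defaults to
#'   [make_fitness()] on `features`.
#' @return A `boa_selection`: `selected_ids`, `mask`, `best_fitness_trace`
#'   (length `n_iters + 1`, non-increasing), `n_selected`, `best_fitness`,
#'   `ce` (final state), `config`.
#' @export
run_improved_boa <- function(features, cfg = boa_config(), ce = NULL,
                             lam = 0.01, ce_mode = c("inject",
                                                     "replace-global", "off"),
                             fitness = NULL) {
  ce_mode <- match.arg(ce_mode)
  u <- unpack_features(features)
  d <- length(u$feature_ids)
  if (is.null(fitness)) fitness <- make_fitness(features, lam = lam,
                                                seed = cfg$seed)
  if (is.null(ce)) ce <- ce_state(d)
  n_ce <- if (is.null(ce$n_ce)) cfg$pop_size else ce$n_ce
  np <- cfg$pop_size

  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(np * d), np, d)
    fits <- apply(pos, 1, function(p) fitness(binarize(p, cfg$bin_thresh)))
    best_i <- which.min(fits)
    best_fit <- fits[best_i]
    best_pos <- pos[best_i, ]
    best_mask <- binarize(best_pos, cfg$bin_thresh)
    trace <- numeric(cfg$n_iters + 1)
    trace[1] <- best_fit

    for (it in seq_len(cfg$n_iters)) {
      # (i) moves, fragrance from each butterfly's own current fitness
      for (j in seq_len(np)) {
        f_j <- fragrance(cfg, 1 / (fits[j] + 1e-6))
        rn <- stats::runif(1)
        if (stats::runif(1) < cfg$switch_p) {
          if (ce_mode == "replace-global") {
            pos[j, ] <- as.numeric(stats::runif(d) < ce$a_k)
          } else {
            pos[j, ] <- global_move(pos[j, ], best_pos, rn, f_j)
          }
        } else {
          peers <- sample(setdiff(seq_len(np), j), 2)
          pos[j, ] <- local_move(pos[j, ], pos[peers[1], ], pos[peers[2], ],
                                 rn, f_j)
        }
      }
      # (ii) evaluate
      masks <- t(apply(pos, 1, binarize, bin_thresh = cfg$bin_thresh))
      fits <- apply(masks, 1, fitness)
      # (iii) CE refresh from the elite fraction
      if (ce_mode != "off") {
        gamma <- stats::quantile(fits, probs = ce$rho, type = 1)
        ce$gamma <- as.numeric(gamma)
        elite <- masks[fits <= gamma, , drop = FALSE]
        ce <- ce_update(elite, ce)
        # (iv) inject fresh CE samples over the worst butterflies
        if (ce_mode == "inject" && n_ce > 0) {
          worst <- order(fits, decreasing = TRUE)[seq_len(min(n_ce, np))]
          for (j in worst) {
            samp <- as.numeric(stats::runif(d) < ce$a_k)
            pos[j, ] <- samp
            m <- binarize(pos[j, ], cfg$bin_thresh)
            fits[j] <- fitness(m)
          }
          masks <- t(apply(pos, 1, binarize, bin_thresh = cfg$bin_thresh))
        }
      }
      # (v) best-ever bookkeeping
      i_min <- which.min(fits)
      if (fits[i_min] < best_fit) {
        best_fit <- fits[i_min]
        best_pos <- pos[i_min, ]
        best_mask <- masks[i_min, ]
      }
      trace[it + 1] <- best_fit
    }

    structure(
      list(selected_ids = u$feature_ids[best_mask == 1L],
           mask = as.integer(best_mask),
           best_fitness_trace = trace,
           n_selected = sum(best_mask),
           best_fitness = best_fit,
           ce = ce, config = cfg, feature_ids = u$feature_ids),
      class = "boa_selection"
    )
  })
}

#' Canonical butterfly optimization of a continuous objective
#'
#' The plain BOA dynamics (no cross-entropy component, no binarisation) on
#' a box-constrained continuous function; used for convergence checks
#' against standard benchmark objectives.
#'
#' @param fn Objective `function(x) -> scalar`, minimised.
#' @param d Dimension.
#' @param cfg A [boa_config()].
#' @param lower,upper Box bounds (scalars); default \[-1, 1\].
#' @return List with `best_x`, `best_fitness`, `trace` (non-increasing).
#' @export
run_boa_continuous <- function(fn, d, cfg = boa_config(),
                               lower = -1, upper = 1) {
  np <- cfg$pop_size
  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(np * d, lower, upper), np, d)
    fits <- apply(pos, 1, fn)
    best_i <- which.min(fits)
    best_fit <- fits[best_i]; best_pos <- pos[best_i, ]
    trace <- numeric(cfg$n_iters + 1)
    trace[1] <- best_fit
    for (it in seq_len(cfg$n_iters)) {
      for (j in seq_len(np)) {
        f_j <- fragrance(cfg, 1 / (fits[j] + 1e-6))
        rn <- stats::runif(1)
        pos[j, ] <- if (stats::runif(1) < cfg$switch_p) {
          global_move(pos[j, ], best_pos, rn, f_j, lower, upper)
        } else {
          peers <- sample(setdiff(seq_len(np), j), 2)
          local_move(pos[j, ], pos[peers[1], ], pos[peers[2], ], rn, f_j,
                     lower, upper)
        }
        fits[j] <- fn(pos[j, ])
      }
      i_min <- which.min(fits)
      if (fits[i_min] < best_fit) {
        best_fit <- fits[i_min]; best_pos <- pos[i_min, ]
      }
      trace[it + 1] <- best_fit
    }
    list(best_x = best_pos, best_fitness = best_fit, trace = trace)
  })
}

#' @export
print.boa_selection <- function(x, ...) {
  cat("<boa_selection> ", x$n_selected, " of ", length(x$mask),
      " features selected; best fitness ", signif(x$best_fitness, 4),
      " after ", length(x$best_fitness_trace) - 1, " iterations\n", sep = "")
  invisible(x)
}
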