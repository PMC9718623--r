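# Minimal fully connected ReLU/softmax network with full-batch Adam.
# Used for the neural-network panel members (single to three hidden layers,
# ReLU units) and for the trainable feature extractor. Deterministic given
# the init seed; inputs are standardised with training-set statistics.

mlp_init <- function(n_in, hidden, n_out, seed = 1L) {
  sizes <- c(n_in, hidden, n_out)
  with_seed(seed, {
    w <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[l]
      w[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                       fan_in, sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    list(w = w, b = b, sizes = sizes)
  })
}

mlp_forward <- function(net, x, tap = FALSE) {
  a <- x
  n_layers <- length(net$w)
  hidden_last <- NULL
  for (l in seq_len(n_layers)) {
    z <- sweep(a %*% net$w[[l]], 2, net$b[[l]], "+")
    if (l < n_layers) {
      a <- pmax(z, 0)
      hidden_last <- a
    } else {
      z <- z - apply(z, 1, max)
      e <- exp(z)
      a <- e / rowSums(e)
    }
  }
  if (tap) list(prob = a, hidden = hidden_last) else a
}

# One-hot cross-entropy training with full-batch Adam.
# train_layers = "all" updates every layer, "head" only the final one.
mlp_train <- function(net, x, y_onehot, epochs = 300L, lr = 0.01,
                      train_layers = "all", tol = 1e-5) {
  if (epochs == 0) return(net)
  n_layers <- length(net$w)
  first <- if (train_layers == "head") n_layers else 1L
  m <- lapply(net$w, function(w) w * 0); v <- m
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  prev_loss <- Inf
  for (t in seq_len(epochs)) {
    # forward with cached activations
    acts <- list(x)
    for (l in seq_len(n_layers)) {
      z <- sweep(acts[[l]] %*% net$w[[l]], 2, net$b[[l]], "+")
      acts[[l + 1]] <- if (l < n_layers) pmax(z, 0) else {
        z <- z - apply(z, 1, max); e <- exp(z); e / rowSums(e)
      }
    }
    p <- acts[[n_layers + 1]]
    loss <- -mean(log(pmax(rowSums(p * y_onehot), 1e-12)))
    if (abs(prev_loss - loss) < tol && loss < 0.01) break
    prev_loss <- loss
    delta <- (p - y_onehot) / n
    for (l in n_layers:first) {
      gw <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > first) {
        delta <- (delta %*% t(net$w[[l]])) * (acts[[l]] > 0)
      }
      m[[l]] <- beta1 * m[[l]] + (1 - beta1) * gw
      v[[l]] <- beta2 * v[[l]] + (1 - beta2) * gw^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mh <- m[[l]] / (1 - beta1^t); vh <- v[[l]] / (1 - beta2^t)
      mbh <- mb[[l]] / (1 - beta1^t); vbh <- vb[[l]] / (1 - beta2^t)
      net$w[[l]] <- net$w[[l]] - lr * mh / (sqrt(vh) + eps)
      net$b[[l]] <- net$b[[l]] - lr * mbh / (sqrt(vbh) + eps)
    }
  }
  net
}

mlp_onehot <- function(labels, n_classes) {
  oh <- matrix(0, length(labels), n_classes)
  oh[cbind(seq_along(labels), labels + 1L)] <- 1
  oh
}
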