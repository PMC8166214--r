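# Minimal feed-forward network engine used by both the cell-level and the
# pixel-level type classifiers: dense layers without bias, batch
# normalization, tanh activations, softmax output, cross-entropy loss,
# Xavier initialization, Adam updates, and an L1 or L2 weight penalty.
# All randomness (init, shuffling) comes from the caller's RNG stream so a
# single set.seed() makes training bitwise-reproducible.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

mlp_init <- function(n_in, hidden, n_out,
                     penalty = c("l1", "l2"), lambda = 0,
                     penalize_output = FALSE) {
  penalty <- match.arg(penalty)
  dims <- c(n_in, hidden)
  layers <- vector("list", length(hidden))
  for (l in seq_along(hidden)) {
    layers[[l]] <- list(
      W = xavier(dims[l], dims[l + 1]),
      gamma = rep(1, hidden[l]),
      beta = rep(0, hidden[l]),
      run_mean = rep(0, hidden[l]),
      run_var = rep(1, hidden[l])
    )
  }
  net <- list(
    layers = layers,
    W_out = xavier(hidden[length(hidden)], n_out),
    b_out = rep(0, n_out),
    n_in = n_in, n_out = n_out, hidden = hidden,
    penalty = penalty, lambda = lambda,
    penalize_output = penalize_output,
    adam = NULL, adam_t = 0L
  )
  class(net) <- "jsta_mlp"
  net
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# forward pass; training = TRUE uses batch statistics and returns a cache
mlp_forward <- function(net, X, training = FALSE) {
  cache <- if (training) list(A0 = X) else NULL
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W
    if (training) {
      mb <- colMeans(Z)
      vb <- colMeans(Z^2) - mb^2
      net$layers[[l]]$run_mean <- BN_MOMENTUM * ly$run_mean + (1 - BN_MOMENTUM) * mb
      net$layers[[l]]$run_var <- BN_MOMENTUM * ly$run_var + (1 - BN_MOMENTUM) * vb
    } else {
      mb <- ly$run_mean
      vb <- ly$run_var
    }
    inv_sd <- 1 / sqrt(vb + BN_EPS)
    Zh <- sweep(sweep(Z, 2, mb, "-"), 2, inv_sd, "*")
    S <- sweep(sweep(Zh, 2, ly$gamma, "*"), 2, ly$beta, "+")
    A_next <- tanh(S)
    if (training) {
      cache[[paste0("Zh", l)]] <- Zh
      cache[[paste0("inv_sd", l)]] <- inv_sd
      cache[[paste0("A", l)]] <- A_next
    }
    A <- A_next
  }
  logits <- sweep(A %*% net$W_out, 2, net$b_out, "+")
  P <- softmax_rows(logits)
  list(P = P, cache = cache, net = net)
}

penalty_grad <- function(net, W) {
  if (net$lambda == 0) return(0)
  if (net$penalty == "l1") net$lambda * sign(W) else 2 * net$lambda * W
}

adam_step <- function(net, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(net$adam)) {
    net$adam <- lapply(grads, function(g) list(m = g * 0, v = g * 0))
  }
  net$adam_t <- net$adam_t + 1L
  t <- net$adam_t
  upd <- vector("list", length(grads))
  for (i in seq_along(grads)) {
    st <- net$adam[[i]]
    st$m <- b1 * st$m + (1 - b1) * grads[[i]]
    st$v <- b2 * st$v + (1 - b2) * grads[[i]]^2
    net$adam[[i]] <- st
    mh <- st$m / (1 - b1^t)
    vh <- st$v / (1 - b2^t)
    upd[[i]] <- lr * mh / (sqrt(vh) + eps)
  }
  names(upd) <- names(grads)
  net$.upd <- upd
  net
}

# one minibatch update; y is an integer vector of 1-based class labels
mlp_step <- function(net, X, y, lr) {
  n <- nrow(X)
  fw <- mlp_forward(net, X, training = TRUE)
  net <- fw$net
  P <- fw$P
  cache <- fw$cache
  Y <- matrix(0, n, net$n_out)
  Y[cbind(seq_len(n), y)] <- 1

  grads <- list()
  dlogits <- (P - Y) / n
  A_last <- cache[[paste0("A", length(net$layers))]]
  grads$W_out <- crossprod(A_last, dlogits)
  if (net$penalize_output) grads$W_out <- grads$W_out + penalty_grad(net, net$W_out)
  grads$b_out <- colSums(dlogits)
  dA <- tcrossprod(dlogits, net$W_out)

  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    A <- cache[[paste0("A", l)]]
    Zh <- cache[[paste0("Zh", l)]]
    inv_sd <- cache[[paste0("inv_sd", l)]]
    dS <- dA * (1 - A^2)
    grads[[paste0("gamma", l)]] <- colSums(dS * Zh)
    grads[[paste0("beta", l)]] <- colSums(dS)
    dZh <- sweep(dS, 2, ly$gamma, "*")
    # batch-norm backward (population statistics)
    sum_dZh <- colSums(dZh)
    sum_dZhZh <- colSums(dZh * Zh)
    dZ <- sweep(dZh, 2, sum_dZh / n, "-") -
      sweep(Zh, 2, sum_dZhZh / n, "*")
    dZ <- sweep(dZ, 2, inv_sd, "*")
    A_prev <- if (l == 1) cache$A0 else cache[[paste0("A", l - 1)]]
    grads[[paste0("W", l)]] <- crossprod(A_prev, dZ) + penalty_grad(net, ly$W)
    if (l > 1) dA <- tcrossprod(dZ, ly$W)
  }

  net <- adam_step(net, grads, lr)
  upd <- net$.upd
  net$.upd <- NULL
  net$W_out <- net$W_out - upd$W_out
  net$b_out <- net$b_out - upd$b_out
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- net$layers[[l]]$W - upd[[paste0("W", l)]]
    net$layers[[l]]$gamma <- net$layers[[l]]$gamma - upd[[paste0("gamma", l)]]
    net$layers[[l]]$beta <- net$layers[[l]]$beta - upd[[paste0("beta", l)]]
  }
  net
}

cross_entropy <- function(P, y) {
  p <- P[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-12)))
}

# train for `epochs` at learning rate `lr`; returns net plus per-epoch
# train/validation loss and accuracy
mlp_train_phase <- function(net, X, y, epochs, lr, batch_size = 64,
                            X_val = NULL, y_val = NULL) {
  n <- nrow(X)
  trace <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      if (length(idx) < 2) next # batch norm needs >= 2 rows
      net <- mlp_step(net, X[idx, , drop = FALSE], y[idx], lr)
    }
    P_tr <- mlp_forward(net, X)$P
    row <- data.frame(
      epoch = ep, lr = lr,
      train_loss = cross_entropy(P_tr, y),
      train_acc = mean(max.col(P_tr, ties.method = "first") == y)
    )
    if (!is.null(X_val)) {
      P_v <- mlp_forward(net, X_val)$P
      row$val_loss <- cross_entropy(P_v, y_val)
      row$val_acc <- mean(max.col(P_v, ties.method = "first") == y_val)
    }
    trace <- rbind(trace, row)
  }
  list(net = net, trace = trace)
}

#' @export
predict.jsta_mlp <- function(object, newdata, ...) {
  mlp_forward(object, as.matrix(newdata))$P
}
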