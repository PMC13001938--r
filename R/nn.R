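# Internal minibatch feedforward engine: dense and batch-normalization layers,
# ReLU / sigmoid / linear / Gaussian activations, Adam, MSE loss, best-R2
# checkpointing at a fixed epoch cadence. All networks in the package (both
# categorical codecs, the ADNN, the VAE halves and the oil predictor) run on
# this engine, so its gradients are verified against finite differences in the
# test suite.

nn_act <- function(z, act) {
  switch(act,
    relu     = pmax(z, 0),
    sigmoid  = 1 / (1 + exp(-z)),
    linear   = z,
    gaussian = exp(-z^2),
    stop("unknown activation: ", act)
  )
}

# derivative w.r.t. pre-activation, given pre-activation z and activation a
nn_act_grad <- function(z, a, act) {
  switch(act,
    relu     = (z > 0) * 1,
    sigmoid  = a * (1 - a),
    linear   = array(1, dim(z)),
    gaussian = -2 * z * a,
    stop("unknown activation: ", act)
  )
}

# He-style init for ReLU-family layers, Xavier for sigmoid/linear outputs.
nn_init_dense <- function(n_in, n_out, act) {
  sd <- if (act %in% c("relu", "gaussian")) sqrt(2 / n_in) else sqrt(1 / n_in)
  # small positive ReLU bias keeps narrow bottlenecks from initializing dead
  b0 <- if (act == "relu") 0.1 else 0
  list(
    type = "dense", act = act,
    W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
    b = rep(b0, n_out)
  )
}

nn_init_bn <- function(n, momentum = 0.1, eps = 1e-5) {
  list(
    type = "bn", gamma = rep(1, n), beta = rep(0, n),
    run_mean = rep(0, n), run_var = rep(1, n),
    momentum = momentum, eps = eps
  )
}

#' @noRd
# spec: list of list(type = "dense", n_in, n_out, act) / list(type = "bn", n)
nn_new <- function(spec, seed = NULL) {
  build <- function() {
    layers <- lapply(spec, function(s) {
      if (s$type == "dense") nn_init_dense(s$n_in, s$n_out, s$act)
      else if (s$type == "bn") nn_init_bn(s$n)
      else stop("unknown layer type: ", s$type)
    })
    structure(list(layers = layers), class = "microstress_nn")
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

nn_n_params <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (l$type == "dense") length(l$W) + length(l$b) else length(l$gamma) + length(l$beta)
  }, numeric(1)))
}

# Forward pass. training = TRUE uses batch statistics in BN layers (and
# updates running stats in place via the returned net); FALSE uses running
# statistics so inference is batch-size independent.
nn_forward <- function(net, X, training = FALSE, keep_cache = FALSE) {
  X <- as.matrix(X)
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  A <- X
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "dense") {
      Z <- A %*% l$W
      Z <- Z + matrix(l$b, nrow(Z), ncol(Z), byrow = TRUE)
      A_out <- nn_act(Z, l$act)
      if (keep_cache) cache[[i]] <- list(X = A, Z = Z, A = A_out)
      A <- A_out
    } else { # bn
      if (training) {
        mu <- colMeans(A)
        xc <- A - matrix(mu, nrow(A), ncol(A), byrow = TRUE)
        v <- colMeans(xc^2)
        invstd <- 1 / sqrt(v + l$eps)
        xhat <- xc * matrix(invstd, nrow(A), ncol(A), byrow = TRUE)
        net$layers[[i]]$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
        net$layers[[i]]$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
      } else {
        invstd <- 1 / sqrt(l$run_var + l$eps)
        xhat <- (A - matrix(l$run_mean, nrow(A), ncol(A), byrow = TRUE)) *
          matrix(invstd, nrow(A), ncol(A), byrow = TRUE)
      }
      A_out <- xhat * matrix(l$gamma, nrow(A), ncol(A), byrow = TRUE) +
        matrix(l$beta, nrow(A), ncol(A), byrow = TRUE)
      if (keep_cache) cache[[i]] <- list(xhat = xhat, invstd = invstd)
      A <- A_out
    }
  }
  list(out = A, cache = cache, net = net)
}

# Backward pass from dOut (gradient of loss w.r.t. network output).
# Returns per-layer parameter gradients plus dX (gradient w.r.t. input).
nn_backward <- function(net, cache, dOut) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- cache[[i]]
    if (l$type == "dense") {
      dZ <- dA * nn_act_grad(cc$Z, cc$A, l$act)
      grads[[i]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
      dA <- dZ %*% t(l$W)
    } else {
      n <- nrow(cc$xhat)
      dgamma <- colSums(dA * cc$xhat)
      dbeta <- colSums(dA)
      dxhat <- dA * matrix(l$gamma, n, ncol(dA), byrow = TRUE)
      # standard batch-norm input gradient
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cc$xhat)
      dA <- (dxhat - matrix(s1 / n, n, ncol(dA), byrow = TRUE) -
        cc$xhat * matrix(s2 / n, n, ncol(dA), byrow = TRUE)) *
        matrix(cc$invstd, n, ncol(dA), byrow = TRUE)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    }
  }
  list(grads = grads, dX = dA)
}

nn_adam_init <- function(net) {
  list(
    t = 0,
    m = lapply(net$layers, function(l) {
      if (l$type == "dense") list(W = l$W * 0, b = l$b * 0)
      else list(gamma = l$gamma * 0, beta = l$beta * 0)
    }),
    v = lapply(net$layers, function(l) {
      if (l$type == "dense") list(W = l$W * 0, b = l$b * 0)
      else list(gamma = l$gamma * 0, beta = l$beta * 0)
    })
  )
}

nn_adam_step <- function(net, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    for (p in names(grads[[i]])) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[p]] / bc1
      vhat <- state$v[[i]][[p]] / bc2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

# Pooled multi-output R^2: 1 - SSE/SST summed over columns, zero-variance
# columns excluded from both sums. If every column is constant the metric
# degenerates: 1 when predictions reproduce the constants, NA otherwise.
r2_pooled <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  cm <- colMeans(Y)
  tot_col <- colSums((Y - matrix(cm, nrow(Y), ncol(Y), byrow = TRUE))^2)
  keep <- tot_col > 1e-12
  if (!any(keep)) {
    sse <- sum((Y - Yhat)^2)
    return(if (sse <= 1e-12) 1 else NA_real_)
  }
  sse <- sum((Y[, keep, drop = FALSE] - Yhat[, keep, drop = FALSE])^2)
  1 - sse / sum(tot_col[keep])
}

# Minibatch MSE training with per-`monitor_every` epoch R2 logging and
# best-checkpoint retention (highest pooled training R2). Delegates the hot
# loop to the compiled core; `col_weights` (squared original-scale sds of
# the target columns) let the monitored pooled R2 refer to the original
# scale when training happens on standardized targets.
nn_train <- function(net, X, Y, epochs, batch = 32, lr = 1e-3, seed = 0,
                     monitor_every = 100, early_stop_mse = NULL,
                     col_weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), epochs >= 1)
  if (is.null(col_weights)) col_weights <- rep(1, ncol(Y))
  res <- withr::with_seed(as.integer(seed), {
    cpp_train_mlp(
      nn_to_list(net), X, Y,
      as.integer(epochs), as.integer(batch), lr,
      as.integer(monitor_every),
      if (is.null(early_stop_mse)) 0 else early_stop_mse,
      as.numeric(col_weights)
    )
  })
  if (isTRUE(res$diverged)) {
    rlang::abort("training diverged: non-finite loss", class = "microstress_divergence_error")
  }
  list(
    net = nn_from_list(res$layers),
    final_net = nn_from_list(res$final_layers),
    log = tibble::tibble(
      epoch = as.integer(res$epoch), mse = res$mse, r_squared = res$r2
    ),
    r_squared = res$best_r2
  )
}

# Pure-R reference trainer (same math, same RNG usage pattern); kept for
# gradient-checking the update rule against the compiled core.
nn_train_r <- function(net, X, Y, epochs, batch = 32, lr = 1e-3, seed = 0,
                       monitor_every = 100, early_stop_mse = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(n == nrow(Y), epochs >= 1)
  batch <- min(batch, n)
  withr::with_seed(as.integer(seed), {
    state <- nn_adam_init(net)
    best <- list(r2 = -Inf, net = net)
    log_epoch <- integer(0); log_mse <- numeric(0); log_r2 <- numeric(0)
    monitor_every <- max(1L, min(as.integer(monitor_every), epochs))
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        rows <- idx[start:min(start + batch - 1, n)]
        Xb <- X[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        fw <- nn_forward(net, Xb, training = TRUE, keep_cache = TRUE)
        net <- fw$net # BN running-stat updates
        dOut <- 2 * (fw$out - Yb) / length(Yb)
        bw <- nn_backward(net, fw$cache, dOut)
        upd <- nn_adam_step(net, bw$grads, state, lr = lr)
        net <- upd$net; state <- upd$state
      }
      if (ep %% monitor_every == 0 || ep == epochs) {
        pred <- nn_forward(net, X, training = FALSE)$out
        mse <- mean((pred - Y)^2)
        if (!is.finite(mse)) {
          rlang::abort("training diverged: non-finite loss", class = "microstress_divergence_error")
        }
        r2 <- r2_pooled(Y, pred)
        log_epoch <- c(log_epoch, ep); log_mse <- c(log_mse, mse); log_r2 <- c(log_r2, r2)
        if (is.finite(r2) && r2 > best$r2) best <- list(r2 = r2, net = net)
        if (!is.null(early_stop_mse) && mse < early_stop_mse) break
      }
    }
    if (!is.finite(best$r2)) best <- list(r2 = log_r2[length(log_r2)], net = net)
    list(
      net = best$net, final_net = net,
      log = tibble::tibble(epoch = log_epoch, mse = log_mse, r_squared = log_r2),
      r_squared = best$r2
    )
  })
}

# --- feature standardization helpers (z-score; constant columns get sd 1) ---

zscaler_fit <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

zscaler_apply <- function(scaler, X) {
  X <- as.matrix(X)
  (X - matrix(scaler$mean, nrow(X), ncol(X), byrow = TRUE)) /
    matrix(scaler$sd, nrow(X), ncol(X), byrow = TRUE)
}

zscaler_invert <- function(scaler, Z) {
  Z <- as.matrix(Z)
  Z * matrix(scaler$sd, nrow(Z), ncol(Z), byrow = TRUE) +
    matrix(scaler$mean, nrow(Z), ncol(Z), byrow = TRUE)
}

# --- JSON (de)serialization for checkpoints: plain lists of numbers only ---

nn_to_list <- function(net) {
  lapply(net$layers, function(l) {
    if (l$type == "dense") {
      list(type = "dense", act = l$act, dim = dim(l$W), W = l$W, b = l$b)
    } else {
      list(
        type = "bn", gamma = l$gamma, beta = l$beta,
        run_mean = l$run_mean, run_var = l$run_var,
        momentum = l$momentum, eps = l$eps
      )
    }
  })
}

nn_from_list <- function(layers) {
  layers <- lapply(layers, function(l) {
    if (l$type == "dense") {
      W <- if (is.matrix(l$W)) l$W else matrix(unlist(l$W), unlist(l$dim)[1], unlist(l$dim)[2])
      storage.mode(W) <- "double"
      list(type = "dense", act = l$act, W = W, b = as.numeric(unlist(l$b)))
    } else {
      list(
        type = "bn", gamma = unlist(l$gamma), beta = unlist(l$beta),
        run_mean = unlist(l$run_mean), run_var = unlist(l$run_var),
        momentum = l$momentum, eps = l$eps
      )
    }
  })
  structure(list(layers = layers), class = "microstress_nn")
}
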