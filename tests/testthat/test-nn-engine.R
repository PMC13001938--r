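# The analytic gradients of the network engine against finite differences,
# and agreement between the compiled trainer and the R reference step.

grad_check_net <- function() {
  spec <- list(
    list(type = "dense", n_in = 3, n_out = 5, act = "relu"),
    list(type = "bn", n = 5),
    list(type = "dense", n_in = 5, n_out = 4, act = "gaussian"),
    list(type = "dense", n_in = 4, n_out = 2, act = "sigmoid")
  )
  microstress:::nn_new(spec, seed = 11)
}

test_that("backpropagated gradients match finite differences through all layer types", {
  net <- grad_check_net()
  withr::with_seed(42, {
    X <- matrix(rnorm(8 * 3), 8, 3)
    Y <- matrix(runif(8 * 2), 8, 2)
  })
  loss_of <- function(net) {
    out <- microstress:::nn_forward(net, X, training = TRUE)$out
    mean((out - Y)^2)
  }
  fw <- microstress:::nn_forward(net, X, training = TRUE, keep_cache = TRUE)
  dOut <- 2 * (fw$out - Y) / length(Y)
  bw <- microstress:::nn_backward(net, fw$cache, dOut)

  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    params <- if (net$layers[[li]]$type == "dense") c("W", "b") else c("gamma", "beta")
    for (p in params) {
      vals <- net$layers[[li]][[p]]
      probe <- seq_len(min(4, length(vals)))
      for (idx in probe) {
        net_hi <- net; net_hi$layers[[li]][[p]][idx] <- vals[idx] + eps
        net_lo <- net; net_lo$layers[[li]][[p]][idx] <- vals[idx] - eps
        num <- (loss_of(net_hi) - loss_of(net_lo)) / (2 * eps)
        ana <- bw$grads[[li]][[p]][idx]
        expect_equal(ana, num, tolerance = 1e-4)
      }
    }
  }
})

test_that("the compiled trainer reproduces the R reference Adam step on a full batch", {
  net <- grad_check_net()
  withr::with_seed(7, {
    X <- matrix(rnorm(10 * 3), 10, 3)
    Y <- matrix(runif(10 * 2), 10, 2)
  })
  lr <- 1e-2
  # one full-batch epoch: row order cannot affect the summed gradients
  cpp <- withr::with_seed(1, {
    microstress:::cpp_train_mlp(
      microstress:::nn_to_list(net), X, Y, 1L, nrow(X), lr, 1L, 0, rep(1, 2)
    )
  })
  fw <- microstress:::nn_forward(net, X, training = TRUE, keep_cache = TRUE)
  net_r <- fw$net
  dOut <- 2 * (fw$out - Y) / length(Y)
  bw <- microstress:::nn_backward(net_r, fw$cache, dOut)
  upd <- microstress:::nn_adam_step(net_r, bw$grads, microstress:::nn_adam_init(net_r), lr = lr)
  ref <- upd$net
  got <- microstress:::nn_from_list(cpp$final_layers)
  expect_equal(net_weights(got), net_weights(ref), tolerance = 1e-10)
})

test_that("training is deterministic per seed and flags divergence", {
  withr::with_seed(5, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    Y <- matrix(rnorm(40 * 2), 40, 2)
  })
  spec <- list(
    list(type = "dense", n_in = 3, n_out = 8, act = "relu"),
    list(type = "dense", n_in = 8, n_out = 2, act = "linear")
  )
  net <- microstress:::nn_new(spec, seed = 1)
  f1 <- microstress:::nn_train(net, X, Y, epochs = 30, batch = 8, seed = 9)
  f2 <- microstress:::nn_train(net, X, Y, epochs = 30, batch = 8, seed = 9)
  expect_identical(net_weights(f1$net), net_weights(f2$net))
  f3 <- microstress:::nn_train(net, X, Y, epochs = 30, batch = 8, seed = 10)
  expect_false(identical(net_weights(f3$net), net_weights(f1$net)))

  Xbad <- X; Xbad[1, 1] <- Inf # non-finite forward pass must be flagged
  expect_error(
    microstress:::nn_train(net, Xbad, Y, epochs = 5, batch = 8, seed = 1),
    class = "microstress_divergence_error"
  )
})

test_that("pooled R^2 excludes zero-variance columns and handles the all-constant case", {
  Y <- cbind(c(1, 2, 3), c(5, 5, 5))
  Yhat_perfect <- Y
  expect_equal(microstress:::r2_pooled(Y, Yhat_perfect), 1)
  Yhat <- cbind(c(1, 2, 4), c(9, 9, 9)) # constant column must not contribute
  expect_equal(microstress:::r2_pooled(Y, Yhat), 1 - 1 / 2)
  const <- cbind(c(2, 2, 2))
  expect_equal(microstress:::r2_pooled(const, const), 1)
  expect_true(is.na(microstress:::r2_pooled(const, const + 1)))
})
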