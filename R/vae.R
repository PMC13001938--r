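# Variational autoencoder over the augmented (5 + N)-feature rows. The
# encoder trunk (256-128-64, ReLU) feeds linear mu and log-variance heads
# over a 3-D latent space; z = mu + sigma * eps is decoded by the mirrored
# decoder (64-128-256, ReLU, linear output). Loss is per-sample
# reconstruction SSE plus the analytic KL divergence to N(0, I), optimized
# with Adam. Trained on z-scored features; outputs are de-standardized.

#' Closed-form KL divergence of a diagonal Gaussian from N(0, I)
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) = 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param mu Mean vector.
#' @param sigma Standard-deviation vector (elementwise positive).
#' @return The KL divergence (scalar).
#' @export
kl_gaussian <- function(mu, sigma) {
  if (any(sigma <= 0)) {
    rlang::abort("sigma must be positive", class = "microstress_domain_error")
  }
  0.5 * sum(mu^2 + sigma^2 - 1 - log(sigma^2))
}

vae_encoder_spec <- function(d) {
  list(
    list(type = "dense", n_in = d, n_out = 256, act = "relu"),
    list(type = "dense", n_in = 256, n_out = 128, act = "relu"),
    list(type = "dense", n_in = 128, n_out = 64, act = "relu")
  )
}

vae_decoder_spec <- function(d, latent = 3) {
  list(
    list(type = "dense", n_in = latent, n_out = 64, act = "relu"),
    list(type = "dense", n_in = 64, n_out = 128, act = "relu"),
    list(type = "dense", n_in = 128, n_out = 256, act = "relu"),
    list(type = "dense", n_in = 256, n_out = d, act = "linear")
  )
}

head_spec <- function(latent = 3) {
  list(list(type = "dense", n_in = 64, n_out = latent, act = "linear"))
}

augmented_matrix <- function(augmented) {
  cols <- setdiff(names(augmented), "provenance")
  as.matrix(augmented[, cols, drop = FALSE])
}

#' Train the variational autoencoder on an augmented set
#'
#' @param augmented An `augmented_set` (or any tibble of `(5 + N)` numeric
#'   feature columns, with an optional `provenance` column that is dropped).
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param seed Integer seed (initialization, shuffling and reparameterization
#'   draws).
#' @param lr Adam learning rate.
#' @param beta Weight of the KL term relative to the per-sample
#'   reconstruction SSE. The default `NULL` uses `1 / n_features`, i.e. the
#'   loss is the per-feature mean reconstruction MSE plus a
#'   dimension-normalized KL — the reduction convention under which the
#'   reconstruction term is plain MSE. Pass `1` for the
#'   summed-reconstruction reading.
#' @param monitor_every Epoch cadence of the reconstruction-R-squared log;
#'   monitoring reconstructs deterministically at `z = mu`, and the
#'   best-R-squared checkpoint is kept.
#' @return A `vae_model` with encoder/heads/decoder, the feature scaler,
#'   `r_squared` (pooled reconstruction R-squared on the original scale) and
#'   the epoch log. Posterior collapse (negative reconstruction R-squared)
#'   triggers a warning, not a failure.
#' @export
train_vae <- function(augmented, epochs = 3000, batch = 32, seed = 0,
                      lr = 1e-3, beta = NULL, monitor_every = 100) {
  X <- augmented_matrix(augmented)
  n <- nrow(X); d <- ncol(X)
  if (is.null(beta)) beta <- 1 / d
  if (n < batch) batch <- max(1, n)
  scaler <- zscaler_fit(X)
  Xs <- zscaler_apply(scaler, X)
  latent <- 3L

  res <- withr::with_seed(as.integer(seed), {
    trunk <- nn_new(vae_encoder_spec(d))
    mu_head <- nn_new(head_spec(latent))
    lv_head <- nn_new(head_spec(latent))
    dec <- nn_new(vae_decoder_spec(d, latent))
    cpp_train_vae(
      nn_to_list(trunk), nn_to_list(mu_head), nn_to_list(lv_head), nn_to_list(dec),
      Xs, as.integer(epochs), as.integer(batch), lr, beta,
      as.integer(monitor_every),
      scaler$sd^2 # monitor pooled reconstruction R^2 on the original scale
    )
  })
  if (isTRUE(res$diverged)) {
    rlang::abort("VAE training diverged: non-finite reconstruction",
      class = "microstress_divergence_error"
    )
  }
  if (res$best_r2 < 0) {
    rlang::warn("possible posterior collapse: reconstruction R^2 < 0",
      class = "microstress_collapse_warning"
    )
  }
  structure(
    list(
      trunk = nn_from_list(res$trunk), mu_head = nn_from_list(res$mu_head),
      lv_head = nn_from_list(res$lv_head), decoder = nn_from_list(res$decoder),
      scaler = scaler, feature_names = colnames(X), latent_dim = latent,
      r_squared = res$best_r2, beta = beta,
      log = tibble::tibble(
        epoch = as.integer(res$epoch), loss = res$loss, r_squared = res$r2
      )
    ),
    class = "vae_model"
  )
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf(
    "<vae_model> %d features, %d-D latent, reconstruction R^2 = %s\n",
    length(x$feature_names), x$latent_dim, format(x$r_squared, digits = 4)
  ))
  invisible(x)
}

#' Encode rows to the latent posterior parameters
#'
#' @param model A trained `vae_model`.
#' @param x Feature rows on the original scale (matrix or augmented-set
#'   tibble).
#' @param eps Optional fixed reparameterization noise matrix; `0` (the
#'   default) gives the deterministic `z = mu`.
#' @return List with `mu`, `sigma` and the sampled `z`.
#' @export
vae_encode <- function(model, x, eps = 0) {
  stopifnot(inherits(model, "vae_model"))
  if (is.data.frame(x)) x <- augmented_matrix(x)
  xs <- zscaler_apply(model$scaler, x)
  H <- nn_forward(model$trunk, xs)$out
  mu <- nn_forward(model$mu_head, H)$out
  logvar <- pmin(pmax(nn_forward(model$lv_head, H)$out, -10), 10)
  sigma <- exp(0.5 * logvar)
  if (is.null(dim(eps))) eps <- matrix(eps, nrow(mu), ncol(mu))
  list(mu = mu, sigma = sigma, z = mu + sigma * eps)
}

#' Decode latent vectors to feature rows on the original scale
#'
#' @param model A trained `vae_model`.
#' @param z `n x 3` latent matrix.
#' @return Tibble of decoded feature rows.
#' @export
vae_decode <- function(model, z) {
  stopifnot(inherits(model, "vae_model"))
  z <- matrix(z, ncol = model$latent_dim)
  out <- zscaler_invert(model$scaler, nn_forward(model$decoder, z)$out)
  colnames(out) <- model$feature_names
  tibble::as_tibble(as.data.frame(out))
}

#' Sample an in-distribution stress-test set from the VAE latent space
#'
#' Draws `n` latent vectors from N(0, I3) and decodes them, yielding
#' synthetic `(5 + N)`-feature rows that stay within the learned data
#' manifold. These probe predictor robustness; they are not independent
#' validation data.
#'
#' @param model A trained `vae_model`.
#' @param n Number of stress samples (the study uses 2,020).
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return A `stress_set` tibble with the model's feature columns.
#' @export
sample_stress_set <- function(model, n = 2020, seed = 0) {
  stopifnot(inherits(model, "vae_model"))
  if (!is.numeric(n) || n <= 0 || n != floor(n)) {
    rlang::abort("n must be a positive integer", class = "microstress_domain_error")
  }
  z <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(n * model$latent_dim), n, model$latent_dim)
  })
  out <- vae_decode(model, z)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("stress_set", class(out))
  out
}
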