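# Augmented-data neural network (ADNN): learns the map from the five
# environmental features to the selected taxa abundances, then manufactures
# synthetic training rows by injecting 0.01-sigma Gaussian noise into the
# environmental block and predicting the matching taxa values.

#' Noise specification for environmental-feature injection
#'
#' Records the per-feature standard deviations (sigma_1..sigma_5) of the
#' environmental block together with the noise scale (default 0.01, i.e.
#' perturbations of sd 0.01 * sigma_i) and the number of injection rounds
#' (default 4, so 404 real rows yield 1,616 synthetic rows).
#'
#' @param env Matrix or data frame of the five environmental features the
#'   sigmas are computed from, or a sample table.
#' @param c Noise scale factor applied to each sigma_i.
#' @param rounds Number of independent injection rounds.
#' @param seed Integer seed used when the noise is drawn.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(env, c = 0.01, rounds = 4, seed = 0) {
  env <- env_matrix(env)
  if (c < 0 || rounds < 0 || rounds != floor(rounds)) {
    rlang::abort("need c >= 0 and integer rounds >= 0", class = "microstress_config_error")
  }
  sigma <- apply(env, 2, stats::sd)
  sigma[!is.finite(sigma)] <- 0
  structure(
    list(sigma = sigma, c = c, rounds = as.integer(rounds), seed = as.integer(seed)),
    class = "noise_spec"
  )
}

env_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(env_feature_cols() %in% names(x))) x <- x[, env_feature_cols()]
  }
  as.matrix(x)
}

#' Inject Gaussian noise into an environmental feature matrix
#'
#' Each round adds an independent `n x 5` Gaussian matrix (mean zero,
#' per-column sd `c * sigma_i`) to the full original matrix; rounds are
#' concatenated, so `n` rows become `n * rounds` synthetic rows.
#'
#' @param env `n x 5` environmental matrix (or sample table).
#' @param spec A [noise_spec()] computed from the same matrix.
#' @return Matrix with `n * rounds` rows.
#' @export
inject_noise <- function(env, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  env <- env_matrix(env)
  if (ncol(env) != length(spec$sigma)) {
    rlang::abort("environmental matrix width does not match noise spec",
      class = "microstress_shape_error"
    )
  }
  n <- nrow(env)
  if (spec$rounds == 0 || n == 0) {
    return(env[integer(0), , drop = FALSE])
  }
  withr::with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(spec$rounds), function(r) {
      noise <- matrix(
        stats::rnorm(n * ncol(env), 0, rep(spec$c * spec$sigma, each = n)),
        n, ncol(env)
      )
      env + noise
    }))
  })
}

#' Train the augmented-data neural network
#'
#' Fits the 5 -> 32 -> 64 -> 128 (Gaussian) -> 64 -> 32 -> N feedforward
#' network (ReLU except for the Gaussian `exp(-x^2)` third hidden layer,
#' linear output) from the environmental block to the selected taxa counts,
#' with Adam, MSE loss and batch size 32. All samples are used. Features and
#' targets are z-scored internally (fit on the training data) and the pooled
#' training R-squared — tracked every 100 epochs, best checkpoint kept — is
#' reported on the original count scale. A training R-squared below 0.75
#' marks the model unreliable; downstream stages warn when they consume it.
#'
#' @param table A sample table.
#' @param selected_taxa Integer vector of taxon indices (from
#'   [select_top_k()]).
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param seed Integer seed.
#' @param lr Adam learning rate.
#' @param monitor_every Epoch cadence for the R-squared log.
#' @return An `adnn_model` with the best-R-squared checkpoint, scalers, the
#'   epoch log and `r_squared`.
#' @export
train_adnn <- function(table, selected_taxa, epochs = 3000, batch = 32,
                       seed = 0, lr = 1e-3, monitor_every = 100) {
  if (length(selected_taxa) < 1) {
    rlang::abort("need at least one selected taxon", class = "microstress_domain_error")
  }
  tc <- paste0("Bac_", selected_taxa)
  missing <- setdiff(tc, names(table))
  if (length(missing) > 0) {
    rlang::abort(paste0("selected taxa not in table: ", paste(missing, collapse = ", ")),
      class = "microstress_schema_error"
    )
  }
  X <- env_matrix(table)
  Y <- as.matrix(table[, tc, drop = FALSE])
  x_scaler <- zscaler_fit(X)
  y_scaler <- zscaler_fit(Y)
  Xs <- zscaler_apply(x_scaler, X)
  Ys <- zscaler_apply(y_scaler, Y)
  N <- length(selected_taxa)
  spec <- list(
    list(type = "dense", n_in = 5, n_out = 32, act = "relu"),
    list(type = "dense", n_in = 32, n_out = 64, act = "relu"),
    list(type = "dense", n_in = 64, n_out = 128, act = "gaussian"),
    list(type = "dense", n_in = 128, n_out = 64, act = "relu"),
    list(type = "dense", n_in = 64, n_out = 32, act = "relu"),
    list(type = "dense", n_in = 32, n_out = N, act = "linear")
  )
  net <- nn_new(spec, seed = seed)
  fit <- nn_train(net, Xs, Ys,
    epochs = epochs, batch = batch, lr = lr, seed = as.integer(seed) + 1L,
    monitor_every = monitor_every,
    col_weights = y_scaler$sd^2 # monitor pooled R^2 on the count scale
  )
  pred <- zscaler_invert(y_scaler, nn_forward(fit$net, Xs)$out)
  r2 <- r2_pooled(Y, pred)
  structure(
    list(
      net = fit$net, x_scaler = x_scaler, y_scaler = y_scaler,
      selected_taxa = selected_taxa, r_squared = r2, log = fit$log,
      reliable = is.finite(r2) && r2 >= 0.75
    ),
    class = "adnn_model"
  )
}

#' @export
print.adnn_model <- function(x, ...) {
  cat(sprintf(
    "<adnn_model> 5 -> %d taxa, training R^2 = %s%s\n",
    length(x$selected_taxa), format(x$r_squared, digits = 4),
    if (x$reliable) "" else " (below 0.75 reliability gate)"
  ))
  invisible(x)
}

#' Predict selected taxa abundances from environmental features
#'
#' @param model A trained `adnn_model`.
#' @param env `n x 5` environmental matrix (or sample table).
#' @param clip Clip negative predictions at zero (abundances are
#'   non-negative).
#' @return Matrix of predicted taxa values, columns named `Bac_*`.
#' @export
adnn_predict <- function(model, env, clip = TRUE) {
  stopifnot(inherits(model, "adnn_model"))
  env <- env_matrix(env)
  if (ncol(env) != 5) {
    rlang::abort("environmental matrix must have 5 columns", class = "microstress_shape_error")
  }
  out <- zscaler_invert(model$y_scaler, nn_forward(model$net, zscaler_apply(model$x_scaler, env))$out)
  if (clip) out[out < 0] <- 0
  colnames(out) <- paste0("Bac_", model$selected_taxa)
  out
}

#' Build the augmented training set (real + noise-injected synthetic rows)
#'
#' Real rows are the untouched projection of the sample table onto the
#' environmental block plus the selected taxa; synthetic rows pair each
#' noise-injected environmental row with the ADNN's taxa predictions for it.
#' With the defaults (404 real samples, 4 rounds) the result is the
#' 404 + 1,616 = 2,020-row augmented set.
#'
#' @param table The real sample table.
#' @param model A trained `adnn_model`.
#' @param spec A [noise_spec()] computed from the same table.
#' @param selected_taxa Taxon indices; must match the model's.
#' @return An `augmented_set` tibble with a `provenance` column
#'   (`"real"`/`"synthetic"`), the five environmental columns and the
#'   selected `Bac_*` columns.
#' @export
build_augmented_set <- function(table, model, spec, selected_taxa = model$selected_taxa) {
  stopifnot(inherits(model, "adnn_model"), inherits(spec, "noise_spec"))
  if (!identical(as.integer(selected_taxa), as.integer(model$selected_taxa))) {
    rlang::abort("selected taxa do not match the trained ADNN",
      class = "microstress_schema_error"
    )
  }
  if (!model$reliable) {
    rlang::warn(paste0(
      "ADNN training R^2 ",
      format(model$r_squared, digits = 3),
      " is below the 0.75 reliability gate; synthetic rows may be unreliable"
    ), class = "microstress_reliability_warning")
  }
  tc <- paste0("Bac_", selected_taxa)
  env_real <- env_matrix(table)
  real <- tibble::as_tibble(as.data.frame(cbind(env_real, as.matrix(table[, tc, drop = FALSE]))))
  names(real) <- c(env_feature_cols(), tc)
  real <- dplyr::mutate(real, provenance = "real", .before = 1)

  env_syn <- inject_noise(env_real, spec)
  if (nrow(env_syn) > 0) {
    taxa_syn <- adnn_predict(model, env_syn)
    syn <- tibble::as_tibble(as.data.frame(cbind(env_syn, taxa_syn)))
    names(syn) <- c(env_feature_cols(), tc)
    syn <- dplyr::mutate(syn, provenance = "synthetic", .before = 1)
  } else {
    syn <- real[integer(0), ]
  }
  out <- dplyr::bind_rows(real, syn)
  attr(out, "selected_taxa") <- as.integer(selected_taxa)
  attr(out, "n_real") <- nrow(real)
  attr(out, "rounds") <- spec$rounds
  class(out) <- c("augmented_set", class(out))
  out
}
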