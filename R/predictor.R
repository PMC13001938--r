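# Oil-contamination prediction network: (4 + N) inputs (location, time,
# temperature, month and the N selected taxa; the oil encoding is the
# regression target, never an input), hidden layers 32-64-128-64-32 (ReLU),
# one linear output neuron. Batch normalization, when enabled, sits on the
# fifth hidden layer (dense -> BN -> ReLU); inference uses running statistics
# so predictions are batch-size independent.

predictor_layers <- function(n_in, use_bn = TRUE, bn_all = FALSE) {
  widths <- c(32, 64, 128, 64, 32)
  spec <- list()
  prev <- n_in
  for (i in seq_along(widths)) {
    w <- widths[i]
    bn_here <- use_bn && (i == 5 || bn_all)
    # "ReLU combined with BN": normalization of the activated layer output
    spec <- c(spec, list(list(type = "dense", n_in = prev, n_out = w, act = "relu")))
    if (bn_here) spec <- c(spec, list(list(type = "bn", n = w)))
    prev <- w
  }
  c(spec, list(list(type = "dense", n_in = prev, n_out = 1, act = "linear")))
}

predictor_input_cols <- function(selected_taxa) {
  c(predictor_env_cols(), paste0("Bac_", selected_taxa))
}

#' Train the oil-contamination prediction network
#'
#' Trains the (4 + N) -> 32 -> 64 -> 128 -> 64 -> 32 -> 1 regression network
#' on an augmented set with Adam, MSE loss and batch size 16, predicting the
#' encoded oil type from the other four environmental features plus the N
#' selected taxa. With `use_bn = TRUE` batch normalization is applied on the
#' fifth hidden layer ("ReLU combined with BN"); `bn_all = TRUE` extends it
#' to every hidden layer for the high-dimensional comparison. Inputs (and
#' the target) are z-scored on the training data; the training R-squared is
#' tracked every `monitor_every` epochs and the best checkpoint is kept.
#'
#' @param augmented An `augmented_set` (or sample table carrying `oil_enc`
#'   and the selected `Bac_*` columns).
#' @param use_bn Enable batch normalization.
#' @param epochs Training epochs.
#' @param batch Minibatch size.
#' @param seed Integer seed.
#' @param lr Adam learning rate.
#' @param bn_all Apply BN to all hidden layers instead of only the fifth.
#' @param monitor_every Epoch cadence of the R-squared log.
#' @return A `predictor_model` with the best checkpoint, scalers, flags,
#'   `r_squared` and the epoch log.
#' @export
train_predictor <- function(augmented, use_bn = TRUE, epochs = 1500, batch = 16,
                            seed = 0, lr = 1e-3, bn_all = FALSE,
                            monitor_every = 100) {
  selected_taxa <- attr(augmented, "selected_taxa")
  if (is.null(selected_taxa)) {
    selected_taxa <- as.integer(sub("^Bac_", "", taxa_cols(augmented)))
  }
  cols <- predictor_input_cols(selected_taxa)
  missing <- setdiff(c(cols, "oil_enc"), names(augmented))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
      class = "microstress_schema_error"
    )
  }
  X <- as.matrix(augmented[, cols, drop = FALSE])
  y <- matrix(augmented$oil_enc, ncol = 1)
  x_scaler <- zscaler_fit(X)
  y_scaler <- zscaler_fit(y)
  Xs <- zscaler_apply(x_scaler, X)
  ys <- zscaler_apply(y_scaler, y)
  net <- nn_new(predictor_layers(ncol(X), use_bn = use_bn, bn_all = bn_all), seed = seed)
  fit <- nn_train(net, Xs, ys,
    epochs = epochs, batch = batch, lr = lr, seed = as.integer(seed) + 1L,
    monitor_every = monitor_every
  )
  pred <- zscaler_invert(y_scaler, nn_forward(fit$net, Xs)$out)
  structure(
    list(
      net = fit$net, x_scaler = x_scaler, y_scaler = y_scaler,
      selected_taxa = as.integer(selected_taxa), use_bn = use_bn, bn_all = bn_all,
      input_cols = cols, r_squared = r_squared(as.vector(y), as.vector(pred)),
      log = fit$log
    ),
    class = "predictor_model"
  )
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf(
    "<predictor_model> %d inputs (4 env + %d taxa), BN %s, training R^2 = %s\n",
    length(x$input_cols), length(x$selected_taxa),
    if (x$use_bn) if (x$bn_all) "all layers" else "5th layer" else "off",
    format(x$r_squared, digits = 4)
  ))
  invisible(x)
}

#' Predict encoded oil-type values
#'
#' Deterministic forward pass in inference mode (BN layers use running
#' statistics, so the result does not depend on how rows are batched).
#'
#' @param model A trained `predictor_model`.
#' @param samples Sample table, augmented set, stress set or numeric matrix
#'   with the model's `(4 + N)` input columns.
#' @return Numeric vector of predicted encoded oil values, one per row.
#' @export
predict_oil <- function(model, samples) {
  stopifnot(inherits(model, "predictor_model"))
  if (is.data.frame(samples)) {
    missing <- setdiff(model$input_cols, names(samples))
    if (length(missing) > 0) {
      rlang::abort(paste0("missing input column(s): ", paste(missing, collapse = ", ")),
        class = "microstress_shape_error"
      )
    }
    X <- as.matrix(samples[, model$input_cols, drop = FALSE])
  } else {
    X <- as.matrix(samples)
    if (ncol(X) != length(model$input_cols)) {
      rlang::abort(sprintf(
        "expected %d input columns, got %d",
        length(model$input_cols), ncol(X)
      ), class = "microstress_shape_error")
    }
  }
  pred <- nn_forward(model$net, zscaler_apply(model$x_scaler, X))$out
  as.vector(zscaler_invert(model$y_scaler, pred))
}

#' Decode predicted oil scalars to textual labels
#'
#' Each predicted encoded value is passed through the oil codec's decoder and
#' the raw output pair is mapped to the nearest legal oil-type label, so the
#' function is total even for predictions outside the training range.
#'
#' @param values Numeric vector of predicted encoded oil values.
#' @param oil_bundle A trained oil `codec_bundle`.
#' @return Character vector of labels in `{no_oil, crude, diesel}`.
#' @export
decode_predictions <- function(values, oil_bundle) {
  stopifnot(inherits(oil_bundle, "codec_bundle"))
  code_to_oil_label(decode(oil_bundle, values))
}
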