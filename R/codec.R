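# Categorical autoencoders: compress the two-digit oil-type code and the
# latitude/longitude pair each into a single decodable scalar through a
# one-neuron bottleneck.

#' The legal oil-type binary codes
#'
#' @return 3 x 2 matrix of `(b1, b2)` codes with labels as row names.
#' @export
oil_codes <- function() {
  matrix(c(0, 0, 0, 1, 1, 0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("no_oil", "crude", "diesel"), c("b1", "b2"))
  )
}

#' Map oil-type labels to their two-digit binary codes
#'
#' The closed label set maps as no_oil -> (0,0), crude -> (0,1),
#' diesel -> (1,0); (1,1) is not a legal code.
#'
#' @param label Character vector of labels in `{no_oil, crude, diesel}`.
#' @return Numeric matrix with one `(b1, b2)` row per label.
#' @export
oil_label_to_code <- function(label) {
  codes <- oil_codes()
  bad <- setdiff(label, rownames(codes))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown oil label(s): ", paste(bad, collapse = ", ")),
      class = "microstress_domain_error"
    )
  }
  codes[label, , drop = FALSE]
}

#' Map raw decoder output back to an oil-type label
#'
#' Each coordinate of the raw pair (decoder sigmoid output in `[0,1]`) is
#' rounded at 0.5. A legal rounded code maps directly to its label; the
#' illegal code (1,1) falls back to the label whose code is nearest to the
#' *raw* pair in Euclidean distance, ties broken in the order no_oil, crude,
#' diesel. The function is total on `[0,1]^2`.
#'
#' @param raw Numeric vector of length 2 or matrix with 2 columns.
#' @return Character vector of labels.
#' @export
code_to_oil_label <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, ncol = 2, byrow = TRUE)
  if (ncol(raw) != 2) {
    rlang::abort("raw codes must have two columns", class = "microstress_shape_error")
  }
  codes <- oil_codes()
  apply(raw, 1, function(p) {
    r <- as.numeric(p >= 0.5)
    hit <- which(codes[, 1] == r[1] & codes[, 2] == r[2])
    if (length(hit) == 1) {
      return(rownames(codes)[hit])
    }
    d <- sqrt(colSums((t(codes) - p)^2))
    rownames(codes)[which.min(d)] # which.min keeps the first of tied labels
  })
}

# architecture builders --------------------------------------------------

oil_ae_spec <- function() {
  list(
    list(type = "dense", n_in = 2, n_out = 8, act = "relu"),
    list(type = "dense", n_in = 8, n_out = 4, act = "relu"),
    list(type = "dense", n_in = 4, n_out = 1, act = "relu"), # bottleneck
    list(type = "dense", n_in = 1, n_out = 4, act = "relu"),
    list(type = "dense", n_in = 4, n_out = 8, act = "relu"),
    list(type = "dense", n_in = 8, n_out = 2, act = "sigmoid")
  )
}

location_ae_spec <- function() {
  list(
    list(type = "dense", n_in = 2, n_out = 16, act = "relu"),
    list(type = "dense", n_in = 16, n_out = 8, act = "relu"),
    list(type = "dense", n_in = 8, n_out = 4, act = "relu"),
    list(type = "dense", n_in = 4, n_out = 1, act = "sigmoid"), # bottleneck
    list(type = "dense", n_in = 1, n_out = 4, act = "relu"),
    list(type = "dense", n_in = 4, n_out = 8, act = "relu"),
    list(type = "dense", n_in = 8, n_out = 16, act = "relu"),
    list(type = "dense", n_in = 16, n_out = 2, act = "linear")
  )
}

new_codec_bundle <- function(net, arch, n_encoder_layers, r_squared, log,
                             scaler = NULL, degenerate = NULL) {
  structure(
    list(
      net = net, arch = arch, n_encoder_layers = n_encoder_layers,
      r_squared = r_squared, log = log, scaler = scaler, degenerate = degenerate
    ),
    class = "codec_bundle"
  )
}

#' @export
print.codec_bundle <- function(x, ...) {
  cat(sprintf(
    "<codec_bundle: %s> 1-neuron bottleneck, training R^2 = %s\n",
    x$arch, format(x$r_squared, digits = 4)
  ))
  invisible(x)
}

#' Train the oil-type autoencoder
#'
#' Trains the 2-8-4-1-4-8-2 autoencoder (ReLU throughout, ReLU one-neuron
#' bottleneck, sigmoid output pair) on the binary oil-type codes with Adam,
#' MSE loss and batch size 16. By default the three legal codes are
#' replicated to a per-sample-sized training set (so minibatching is
#' meaningful); set `unique_codes = TRUE` to train on the three unique rows
#' only. A converged codec reconstructs all three codes, giving training
#' R-squared of 1 to reported precision. Because a ReLU bottleneck can
#' collapse for unlucky initializations, training restarts from a derived
#' seed when reconstruction stays poor (up to `restarts` times).
#'
#' @param codes Optional matrix of training codes; defaults to the three
#'   legal codes.
#' @param epochs Maximum training epochs.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param replicate_to Number of rows codes are cycled up to when
#'   `unique_codes` is FALSE.
#' @param unique_codes Train on unique code rows only.
#' @param restarts Maximum extra initializations if reconstruction R-squared
#'   stays below 0.999.
#' @param lr Adam learning rate.
#' @return A `codec_bundle` with the trained network, training R-squared and
#'   the 100-epoch monitoring log.
#' @export
train_oil_autoencoder <- function(codes = NULL, epochs = 2000, seed = 0,
                                  replicate_to = 404, unique_codes = FALSE,
                                  restarts = 3, lr = 5e-3) {
  if (is.null(codes)) codes <- oil_codes()
  codes <- as.matrix(codes)
  if (ncol(codes) != 2) {
    rlang::abort("oil codes must have two columns", class = "microstress_shape_error")
  }
  X <- if (unique_codes) codes else codes[rep_len(seq_len(nrow(codes)), replicate_to), , drop = FALSE]
  best <- NULL
  for (attempt in 0:restarts) {
    s <- as.integer(seed) + attempt * 1000L
    net <- nn_new(oil_ae_spec(), seed = s)
    fit <- nn_train(net, X, X,
      epochs = epochs, batch = 16, lr = lr, seed = s + 1L,
      monitor_every = 100, early_stop_mse = 1e-7
    )
    if (is.null(best) || fit$r_squared > best$r_squared) best <- fit
    if (best$r_squared >= 0.999) break
  }
  new_codec_bundle(best$net, "oil",
    n_encoder_layers = 3,
    r_squared = best$r_squared, log = best$log
  )
}

#' Train the location autoencoder
#'
#' Trains the 2-16-8-4-1-4-8-16-2 autoencoder (ReLU hidden layers, sigmoid
#' one-neuron bottleneck, linear output pair) on latitude/longitude pairs
#' with Adam, MSE loss and batch size 16. Coordinates are min-max scaled to
#' `[0,1]` before training and inverse-scaled at the decoder output; raw
#' degrees with a linear head train poorly otherwise.
#'
#' @param coords Matrix or data frame with two columns (latitude, longitude).
#' @param epochs Maximum training epochs.
#' @param seed Integer seed.
#' @param restarts Maximum extra initializations if R-squared stays below 0.98.
#' @param lr Adam learning rate.
#' @return A `codec_bundle`; for a single distinct coordinate the bundle is a
#'   degenerate one-point codec (with a warning) whose R-squared is undefined.
#' @export
train_location_autoencoder <- function(coords, epochs = 2000, seed = 0,
                                       restarts = 3, lr = 2e-3) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) {
    rlang::abort("coords must have two columns", class = "microstress_shape_error")
  }
  if (nrow(unique(coords)) < 2) {
    rlang::warn("single distinct coordinate: returning degenerate one-point codec")
    return(new_codec_bundle(NULL, "location",
      n_encoder_layers = 4,
      r_squared = NA_real_, log = tibble::tibble(),
      degenerate = coords[1, ]
    ))
  }
  mn <- apply(coords, 2, min)
  rg <- apply(coords, 2, max) - mn
  rg[rg < 1e-12] <- 1
  scaler <- list(min = mn, range = rg)
  Xs <- sweep(sweep(coords, 2, mn), 2, rg, "/")
  best <- NULL
  for (attempt in 0:restarts) {
    s <- as.integer(seed) + attempt * 1000L
    net <- nn_new(location_ae_spec(), seed = s)
    fit <- nn_train(net, Xs, Xs,
      epochs = epochs, batch = 16, lr = lr, seed = s + 1L,
      monitor_every = 100, early_stop_mse = 1e-9,
      col_weights = scaler$range^2 # monitor R^2 on the degree scale
    )
    if (is.null(best) || fit$r_squared > best$r_squared) best <- fit
    if (best$r_squared >= 0.98) break
  }
  # R^2 reported on the original degree scale
  recon <- zscale_minmax_invert(scaler, nn_forward(best$net, Xs)$out)
  r2 <- r2_pooled(coords, recon)
  new_codec_bundle(best$net, "location",
    n_encoder_layers = 4,
    r_squared = r2, log = best$log, scaler = scaler
  )
}

zscale_minmax_apply <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2, scaler$min), 2, scaler$range, "/")
}

zscale_minmax_invert <- function(scaler, X) {
  sweep(sweep(as.matrix(X), 2, scaler$range, "*"), 2, scaler$min, "+")
}

#' Encode inputs to the one-neuron bottleneck scalar
#'
#' @param bundle A trained `codec_bundle`.
#' @param x Input row(s): a length-2 vector or an `n x 2` matrix (oil codes
#'   or latitude/longitude pairs, matching the bundle's architecture).
#' @return Numeric vector of bottleneck scalars (one per row).
#' @export
encode <- function(bundle, x) {
  stopifnot(inherits(bundle, "codec_bundle"))
  if (is.null(dim(x))) x <- matrix(x, ncol = length(x))
  if (!is.null(bundle$degenerate)) {
    return(rep(0.5, nrow(x)))
  }
  if (ncol(x) != 2) {
    rlang::abort("codec inputs must have two columns", class = "microstress_shape_error")
  }
  if (bundle$arch == "location") x <- zscale_minmax_apply(bundle$scaler, x)
  enc <- structure(list(layers = bundle$net$layers[seq_len(bundle$n_encoder_layers)]),
    class = "microstress_nn"
  )
  as.vector(nn_forward(enc, x)$out)
}

#' Decode bottleneck scalars back to the input space
#'
#' @param bundle A trained `codec_bundle`.
#' @param s Numeric vector of bottleneck scalars.
#' @return An `n x 2` matrix: raw sigmoid code pairs for the oil codec,
#'   latitude/longitude degrees for the location codec.
#' @export
decode <- function(bundle, s) {
  stopifnot(inherits(bundle, "codec_bundle"))
  s <- as.numeric(s)
  if (!is.null(bundle$degenerate)) {
    return(matrix(bundle$degenerate, length(s), 2, byrow = TRUE))
  }
  dec <- structure(
    list(layers = bundle$net$layers[-seq_len(bundle$n_encoder_layers)]),
    class = "microstress_nn"
  )
  out <- nn_forward(dec, matrix(s, ncol = 1))$out
  if (bundle$arch == "location") out <- zscale_minmax_invert(bundle$scaler, out)
  out
}

#' Save or load a codec bundle as JSON
#'
#' @param bundle A `codec_bundle`.
#' @param path File path.
#' @return `codec_save` returns `path` invisibly; `codec_load` the bundle.
#' @export
codec_save <- function(bundle, path) {
  jsonlite::write_json(
    list(
      arch = bundle$arch, n_encoder_layers = bundle$n_encoder_layers,
      r_squared = bundle$r_squared, scaler = bundle$scaler,
      degenerate = bundle$degenerate,
      layers = if (is.null(bundle$net)) NULL else nn_to_list(bundle$net),
      log = bundle$log
    ),
    path,
    digits = NA, auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname codec_save
#' @export
codec_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  new_codec_bundle(
    net = if (is.null(obj$layers) || length(obj$layers) == 0) NULL else nn_from_list(obj$layers),
    arch = obj$arch, n_encoder_layers = obj$n_encoder_layers,
    r_squared = obj$r_squared,
    log = if (length(obj$log)) {
      dplyr::bind_rows(lapply(obj$log, tibble::as_tibble))
    } else {
      tibble::tibble()
    },
    scaler = if (is.null(obj$scaler)) NULL else list(
      min = unlist(obj$scaler$min), range = unlist(obj$scaler$range)
    ),
    degenerate = if (is.null(obj$degenerate)) NULL else unlist(obj$degenerate)
  )
}
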