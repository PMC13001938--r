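# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature ranking
#'
#' @param x A `feature_ranking`.
#' @param ... Unused.
#' @return Tibble with `rank`, `taxon_index`, `taxon`, `importance`.
#' @export
tidy.feature_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rank", "taxon_index", "taxon", "importance")])
}

#' @rdname tidy.feature_ranking
#' @export
glance.feature_ranking <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x),
    r_squared = attr(x, "r_squared"),
    num_trees = attr(x, "num_trees"),
    max_depth = attr(x, "max_depth")
  )
}

#' Tidy the training log of a fitted network
#'
#' The tidy method returns the per-checkpoint epoch log (epoch, loss/MSE,
#' pooled training R-squared); glance returns a one-row model summary.
#'
#' @param x An `adnn_model`, `vae_model`, `predictor_model` or
#'   `codec_bundle`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.adnn_model <- function(x, ...) x$log

#' @rdname tidy.adnn_model
#' @export
glance.adnn_model <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$selected_taxa), r_squared = x$r_squared,
    reliable = x$reliable, n_params = nn_n_params(x$net)
  )
}

#' @rdname tidy.adnn_model
#' @export
tidy.vae_model <- function(x, ...) x$log

#' @rdname tidy.adnn_model
#' @export
glance.vae_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names), latent_dim = x$latent_dim,
    r_squared = x$r_squared, beta = x$beta
  )
}

#' @rdname tidy.adnn_model
#' @export
tidy.predictor_model <- function(x, ...) x$log

#' @rdname tidy.adnn_model
#' @export
glance.predictor_model <- function(x, ...) {
  tibble::tibble(
    n_inputs = length(x$input_cols), n_taxa = length(x$selected_taxa),
    use_bn = x$use_bn, bn_all = x$bn_all,
    r_squared = x$r_squared, n_params = nn_n_params(x$net)
  )
}

#' @rdname tidy.adnn_model
#' @export
tidy.codec_bundle <- function(x, ...) x$log

#' @rdname tidy.adnn_model
#' @export
glance.codec_bundle <- function(x, ...) {
  tibble::tibble(
    arch = x$arch, r_squared = x$r_squared,
    n_params = if (is.null(x$net)) 0L else nn_n_params(x$net)
  )
}

#' Tidy a hold-out result
#'
#' @param x A `holdout_result`.
#' @param ... Unused.
#' @return Per-split tibble (tidy) or one-row summary (glance).
#' @export
tidy.holdout_result <- function(x, ...) {
  dplyr::select(x$splits, -dplyr::any_of(c("test_bottles", "train_bottles")))
}

#' @rdname tidy.holdout_result
#' @export
glance.holdout_result <- function(x, ...) {
  tibble::tibble(
    n_splits = x$n_splits, test_frac = x$test_frac, k = x$k,
    mean_test_r2 = x$summary$mean, sd_test_r2 = x$summary$sd,
    min_test_r2 = x$summary$min, max_test_r2 = x$summary$max
  )
}
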