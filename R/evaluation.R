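# Metrics, the VAE stress-test comparison, the feature-count sweep and the
# leakage-guarded bottle-level repeated hold-out protocol.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Negative values are
#' possible (and meaningful) on held-out data.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return The R-squared (scalar).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2) {
    rlang::abort("y and yhat must have equal length >= 2",
      class = "microstress_metric_error"
    )
  }
  tot <- sum((y - mean(y))^2)
  if (tot <= 0) {
    rlang::abort("R^2 undefined: y has zero variance", class = "microstress_metric_error")
  }
  1 - sum((y - yhat)^2) / tot
}

# Snap generated oil_enc values to the nearest legal encoded oil-type value.
# `code_values` are the (three) distinct encodings present in the training
# table; when an oil codec is supplied they are its encode() outputs, i.e.
# snapping is decode-to-label / re-encode.
snap_oil_enc <- function(values, code_values) {
  code_values <- sort(unique(code_values))
  idx <- vapply(values, function(v) which.min(abs(code_values - v)), integer(1))
  code_values[idx]
}

#' Stress-test a predictor on VAE-generated samples
#'
#' Scores the predictor on a stress set. Because generated rows carry a
#' continuous `oil_enc` value, the target for each row is its value snapped
#' to the nearest legal encoded oil type (equivalently: decoded to a label
#' through the oil codec and re-encoded).
#'
#' @param model A trained `predictor_model`.
#' @param stress A `stress_set`.
#' @param code_values The distinct encoded oil-type values of the training
#'   table, or an oil `codec_bundle` from which they are derived.
#' @return The stress-test R-squared (scalar).
#' @export
stress_test <- function(model, stress, code_values) {
  if (inherits(code_values, "codec_bundle")) {
    code_values <- encode(code_values, oil_codes())
  }
  targets <- snap_oil_enc(stress$oil_enc, code_values)
  r_squared(targets, predict_oil(model, stress))
}

#' Bottle-level repeated grouped hold-out evaluation
#'
#' Repeatedly partitions *bottles* (independent physical microcosms), never
#' samples, into train/test sets; per split the feature ranking, the ADNN,
#' the noise injection and the predictor are fitted on the training-split
#' samples only, and the test R-squared is computed on the untouched
#' held-out real samples. With 172 bottles at a 0.2 test fraction the
#' held-out bottle count alternates between 34 and 35 across splits.
#'
#' @param table A sample table with `bottle_id`.
#' @param k Number of top-ranked taxa used per split.
#' @param n_splits Number of repeated random splits.
#' @param test_frac Fraction of bottles held out per split.
#' @param seed Master seed; split seeds are derived as `seed + split - 1`.
#' @param use_bn Batch normalization in the predictor.
#' @param num_trees,max_depth Forest parameters for the per-split ranking.
#' @param epochs_adnn,epochs_predictor Per-split training epochs.
#' @param noise_c,rounds Noise-injection scale and rounds.
#' @param max_resample Maximum redraws of a degenerate split (empty test or
#'   zero target variance); redraws are logged in the result.
#' @return A `holdout_result` with per-split metrics (`splits`), summary
#'   statistics of test R-squared (`summary`) and the call parameters.
#' @export
bottle_holdout <- function(table, k = 5, n_splits = 22, test_frac = 0.2,
                           seed = 0, use_bn = TRUE,
                           num_trees = 2500, max_depth = 25,
                           epochs_adnn = 3000, epochs_predictor = 1500,
                           noise_c = 0.01, rounds = 4, max_resample = 10) {
  table <- validate_sample_table(table)
  bottles <- unique(table$bottle_id)
  n_b <- length(bottles)
  if (n_b < 5) {
    rlang::abort("need at least 5 bottles", class = "microstress_validation_error")
  }
  if (test_frac <= 0 || test_frac >= 1) {
    rlang::abort("test_frac must be in (0, 1)", class = "microstress_config_error")
  }
  raw <- test_frac * n_b
  n_lo <- max(1L, as.integer(floor(raw)))
  n_hi <- max(1L, as.integer(ceiling(raw)))

  splits <- vector("list", n_splits)
  notes <- character(0)
  for (s in seq_len(n_splits)) {
    split_seed <- as.integer(seed) + s - 1L
    # alternate floor/ceiling so a fractional bottle count averages out
    n_test <- if (n_lo == n_hi) n_lo else if (s %% 2 == 1) n_hi else n_lo
    res <- NULL
    for (attempt in 0:max_resample) {
      test_bottles <- withr::with_seed(split_seed + 7919L * attempt, {
        sample(bottles, n_test)
      })
      train_tbl <- dplyr::filter(table, !.data$bottle_id %in% test_bottles)
      test_tbl <- dplyr::filter(table, .data$bottle_id %in% test_bottles)
      if (nrow(test_tbl) == 0 || stats::var(test_tbl$oil_enc) <= 0 ||
        stats::var(train_tbl$oil_enc) <= 0) {
        notes <- c(notes, sprintf("split %d: degenerate draw resampled (attempt %d)", s, attempt + 1))
        next
      }
      stopifnot(length(intersect(unique(train_tbl$bottle_id), unique(test_tbl$bottle_id))) == 0)
      ranking <- rank_features_rfr(train_tbl,
        num_trees = num_trees, max_depth = max_depth, seed = split_seed
      )
      sel <- select_top_k(ranking, k)
      adnn <- train_adnn(train_tbl, sel,
        epochs = epochs_adnn, seed = split_seed
      )
      spec <- noise_spec(train_tbl, c = noise_c, rounds = rounds, seed = split_seed)
      aug <- withCallingHandlers(
        build_augmented_set(train_tbl, adnn, spec),
        microstress_reliability_warning = function(w) invokeRestart("muffleWarning")
      )
      pred_model <- train_predictor(aug,
        use_bn = use_bn, epochs = epochs_predictor, seed = split_seed
      )
      res <- tibble::tibble(
        split = s, seed = split_seed,
        n_test_bottles = n_test, n_test_samples = nrow(test_tbl),
        train_r2 = r_squared(aug$oil_enc, predict_oil(pred_model, aug)),
        test_r2 = r_squared(test_tbl$oil_enc, predict_oil(pred_model, test_tbl)),
        test_bottles = list(sort(test_bottles)),
        train_bottles = list(sort(unique(train_tbl$bottle_id)))
      )
      break
    }
    if (is.null(res)) {
      rlang::abort(sprintf("split %d: could not draw a non-degenerate test split", s),
        class = "microstress_validation_error"
      )
    }
    splits[[s]] <- res
  }
  splits <- dplyr::bind_rows(splits)
  structure(
    list(
      splits = splits,
      summary = list(
        mean = mean(splits$test_r2), sd = stats::sd(splits$test_r2),
        min = min(splits$test_r2), max = max(splits$test_r2)
      ),
      n_splits = n_splits, test_frac = test_frac, k = k, seed = seed,
      notes = notes
    ),
    class = "holdout_result"
  )
}

#' @export
print.holdout_result <- function(x, ...) {
  cat(sprintf(
    "<holdout_result> %d bottle-level splits (test fraction %.2f, k = %d)\n  test R^2: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
    x$n_splits, x$test_frac, x$k,
    x$summary$mean, x$summary$sd, x$summary$min, x$summary$max
  ))
  invisible(x)
}

#' Feature-count sweep over the full generative pipeline
#'
#' For each k: rank-and-select the top k taxa, train the ADNN, build the
#' noise-augmented set, train the VAE, draw a stress set, train the oil
#' predictor, and record the four R-squared values (ADNN training, VAE
#' reconstruction, predictor training, predictor stress test).
#'
#' @param table A sample table.
#' @param k_list Strictly increasing feature counts.
#' @param seed Master seed.
#' @param use_bn Batch normalization in the predictor.
#' @param epochs_adnn,epochs_vae,epochs_predictor Per-stage epochs.
#' @param n_stress Stress-set size (defaults to the augmented-set size).
#' @param num_trees,max_depth Forest parameters for the ranking.
#' @param noise_c,rounds Noise-injection parameters.
#' @return A `sweep_result` tibble with one row per k.
#' @export
feature_sweep <- function(table, k_list, seed = 0, use_bn = TRUE,
                          epochs_adnn = 3000, epochs_vae = 3000,
                          epochs_predictor = 1500, n_stress = NULL,
                          num_trees = 2500, max_depth = 25,
                          noise_c = 0.01, rounds = 4) {
  k_list <- as.integer(k_list)
  if (length(k_list) == 0 || any(diff(k_list) <= 0)) {
    rlang::abort("k_list must be strictly increasing", class = "microstress_config_error")
  }
  table <- validate_sample_table(table)
  if (any(k_list < 1) || any(k_list > length(taxa_cols(table)))) {
    rlang::abort("k out of range", class = "microstress_config_error")
  }
  ranking <- rank_features_rfr(table, seed = seed, num_trees = num_trees, max_depth = max_depth)
  code_values <- sort(unique(table$oil_enc))
  rows <- lapply(seq_along(k_list), function(i) {
    k <- k_list[i]
    stage_seed <- as.integer(seed) + 100L * i
    sel <- select_top_k(ranking, k)
    adnn <- train_adnn(table, sel, epochs = epochs_adnn, seed = stage_seed)
    spec <- noise_spec(table, c = noise_c, rounds = rounds, seed = stage_seed)
    aug <- withCallingHandlers(
      build_augmented_set(table, adnn, spec),
      microstress_reliability_warning = function(w) invokeRestart("muffleWarning")
    )
    vae <- train_vae(aug, epochs = epochs_vae, seed = stage_seed + 1L)
    stress <- sample_stress_set(vae, n = if (is.null(n_stress)) nrow(aug) else n_stress,
      seed = stage_seed + 2L
    )
    pred <- train_predictor(aug, use_bn = use_bn, epochs = epochs_predictor, seed = stage_seed + 3L)
    tibble::tibble(
      k = k,
      adnn_train_r2 = adnn$r_squared,
      vae_train_r2 = vae$r_squared,
      predictor_train_r2 = pred$r_squared,
      predictor_stress_r2 = stress_test(pred, stress, code_values)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "use_bn") <- use_bn
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", class(out))
  out
}
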