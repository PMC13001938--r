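# Config-driven end-to-end orchestration: simulate (or load) a cohort,
# train codecs on the raw metadata, re-encode the table, rank taxa, train
# the ADNN, inject noise, train the VAE, draw the stress set, train the
# predictor and write every artifact (tagged with the config hash and master
# seed) into a run directory.

#' Pipeline configuration
#'
#' All stage defaults follow the study pipeline: k = 5 selected taxa, noise
#' scale 0.01 with 4 rounds, 3000/3000/1500 epochs and 32/32/16 batch sizes
#' for ADNN/VAE/predictor, batch normalization on.
#'
#' @param cohort A [cohort_config()] used when the run is synthetic.
#' @param k Number of selected taxa features.
#' @param noise_c,rounds Noise-injection scale and rounds.
#' @param epochs_codec,epochs_adnn,epochs_vae,epochs_predictor Stage epochs.
#' @param batch_adnn,batch_vae,batch_predictor Stage batch sizes.
#' @param use_bn Batch normalization in the predictor.
#' @param num_trees,max_depth Random-forest ranking parameters.
#' @param n_stress Stress-set size (`NULL` = augmented-set size).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), k = 5,
                            noise_c = 0.01, rounds = 4,
                            epochs_codec = 2000, epochs_adnn = 3000,
                            epochs_vae = 3000, epochs_predictor = 1500,
                            batch_adnn = 32, batch_vae = 32, batch_predictor = 16,
                            use_bn = TRUE, num_trees = 2500, max_depth = 25,
                            n_stress = NULL, seed = 1) {
  cfg <- list(
    cohort = cohort, k = as.integer(k), noise_c = noise_c, rounds = as.integer(rounds),
    epochs_codec = epochs_codec, epochs_adnn = epochs_adnn,
    epochs_vae = epochs_vae, epochs_predictor = epochs_predictor,
    batch_adnn = batch_adnn, batch_vae = batch_vae, batch_predictor = batch_predictor,
    use_bn = isTRUE(use_bn), num_trees = num_trees, max_depth = max_depth,
    n_stress = n_stress, seed = as.integer(seed)
  )
  if (cfg$k < 1 || cfg$rounds < 0 || cfg$noise_c < 0 ||
    any(unlist(cfg[grep("^epochs", names(cfg))]) < 1)) {
    rlang::abort("invalid pipeline configuration", class = "microstress_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$cohort <- unclass(out$cohort)
  out$cohort$effect_log2fc <- if (is.null(out$cohort$effect_log2fc)) {
    NULL
  } else {
    as.data.frame(out$cohort$effect_log2fc)
  }
  out
}

#' Write or read a pipeline configuration as YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `pipeline_config_write` returns `path` invisibly;
#'   `pipeline_config_read` the configuration.
#' @export
pipeline_config_write <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config_write
#' @export
pipeline_config_read <- function(path) {
  raw <- yaml::read_yaml(path)
  co <- raw$cohort
  eff <- if (is.null(co$effect_log2fc)) NULL else as.matrix(as.data.frame(co$effect_log2fc))
  cohort <- cohort_config(
    n_bottles = co$n_bottles, samples_per_bottle_mean = co$samples_per_bottle_mean,
    n_taxa = co$n_taxa, n_sites = co$n_sites, n_responsive = co$n_responsive,
    effect_log2fc = eff, sparsity = co$sparsity, dispersion = co$dispersion,
    zi_mean_scale = co$zi_mean_scale,
    baseline_meanlog = co$baseline_meanlog, baseline_sdlog = co$baseline_sdlog,
    bottle_effect_sd = co$bottle_effect_sd, ramp_week = co$ramp_week,
    ramp_offset = co$ramp_offset, seed = co$seed
  )
  pipeline_config(
    cohort = cohort, k = raw$k, noise_c = raw$noise_c, rounds = raw$rounds,
    epochs_codec = raw$epochs_codec, epochs_adnn = raw$epochs_adnn,
    epochs_vae = raw$epochs_vae, epochs_predictor = raw$epochs_predictor,
    batch_adnn = raw$batch_adnn, batch_vae = raw$batch_vae,
    batch_predictor = raw$batch_predictor, use_bn = raw$use_bn,
    num_trees = raw$num_trees, max_depth = raw$max_depth,
    n_stress = raw$n_stress, seed = raw$seed
  )
}

config_hash <- function(cfg) {
  s <- paste(deparse(config_to_list(cfg)), collapse = "")
  # tiny FNV-style rolling hash; stable across sessions, no extra deps
  h <- 2166136261 %% 2^31
  for (ch in utf8ToInt(s)) {
    h <- (bitwXor(as.integer(h), ch) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Re-encode a sample table through trained codecs
#'
#' Replaces the generator's placeholder `oil_enc` and `location_enc` columns
#' with the bottleneck scalars of trained oil/location autoencoders, as the
#' study pipeline does.
#'
#' @param table A sample table.
#' @param metadata Per-sample raw metadata with `oil_label`, `latitude`,
#'   `longitude` (as returned by [generate_cohort()]).
#' @param oil_bundle,location_bundle Trained `codec_bundle`s.
#' @return The re-encoded sample table.
#' @export
encode_metadata <- function(table, metadata, oil_bundle, location_bundle) {
  stopifnot(identical(table$sample_id, metadata$sample_id))
  table$oil_enc <- encode(oil_bundle, oil_label_to_code(metadata$oil_label))
  table$location_enc <- encode(
    location_bundle,
    cbind(metadata$latitude, metadata$longitude)
  )
  validate_sample_table(table)
}

#' Run the full pipeline on a synthetic or supplied cohort
#'
#' Executes codec training, ranking, selection, ADNN training, noise
#' injection, VAE training, stress sampling, predictor training and
#' evaluation; optionally writes every artifact into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param table Optional real sample table; when `NULL` a synthetic cohort
#'   is generated from `config$cohort`.
#' @param metadata Per-sample raw metadata (required with `table`; generated
#'   alongside a synthetic cohort).
#' @param out_dir Optional run directory; created if needed.
#' @return A list with the trained models, tables and a `metrics` list
#'   (per-stage R-squared values, stress R-squared and, for synthetic runs,
#'   decoded-label accuracy against the planted bottle labels).
#' @export
run_pipeline <- function(config = pipeline_config(), table = NULL, metadata = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  truth <- NULL
  if (is.null(table)) {
    cohort <- generate_cohort(config$cohort)
    table <- cohort$samples
    metadata <- cohort$metadata
    truth <- cohort$truth
  } else {
    if (is.null(metadata)) {
      rlang::abort("metadata is required with a supplied table",
        class = "microstress_config_error"
      )
    }
    table <- validate_sample_table(table)
    cohort <- NULL
  }

  oil_bundle <- train_oil_autoencoder(epochs = config$epochs_codec, seed = seed + 10L)
  location_bundle <- train_location_autoencoder(
    unique(cbind(metadata$latitude, metadata$longitude)),
    epochs = config$epochs_codec, seed = seed + 20L
  )
  table <- encode_metadata(table, metadata, oil_bundle, location_bundle)

  ranking <- rank_features_rfr(table,
    seed = seed + 30L,
    num_trees = config$num_trees, max_depth = config$max_depth
  )
  sel <- select_top_k(ranking, config$k)
  adnn <- train_adnn(table, sel,
    epochs = config$epochs_adnn, batch = config$batch_adnn, seed = seed + 40L
  )
  spec <- noise_spec(table, c = config$noise_c, rounds = config$rounds, seed = seed + 50L)
  aug <- build_augmented_set(table, adnn, spec)
  vae <- train_vae(aug,
    epochs = config$epochs_vae, batch = config$batch_vae, seed = seed + 60L
  )
  stress <- sample_stress_set(vae,
    n = if (is.null(config$n_stress)) nrow(aug) else config$n_stress,
    seed = seed + 70L
  )
  pred <- train_predictor(aug,
    use_bn = config$use_bn, epochs = config$epochs_predictor,
    batch = config$batch_predictor, seed = seed + 80L
  )

  metrics <- list(
    oil_codec_r2 = oil_bundle$r_squared,
    location_codec_r2 = location_bundle$r_squared,
    rfr_train_r2 = attr(ranking, "r_squared"),
    adnn_train_r2 = adnn$r_squared,
    vae_train_r2 = vae$r_squared,
    predictor_train_r2 = pred$r_squared,
    predictor_stress_r2 = stress_test(pred, stress, oil_bundle),
    n_real = attr(aug, "n_real"),
    n_synthetic = nrow(aug) - attr(aug, "n_real"),
    n_augmented = nrow(aug),
    seed = seed
  )
  if (!is.null(truth)) {
    labels <- decode_predictions(predict_oil(pred, table), oil_bundle)
    true_labels <- metadata$oil_label
    metrics$label_accuracy <- mean(labels == true_labels)
  }

  result <- list(
    config = config, table = table, metadata = metadata, truth = truth,
    oil_bundle = oil_bundle, location_bundle = location_bundle,
    ranking = ranking, selected_taxa = sel, adnn = adnn, noise = spec,
    augmented = aug, vae = vae, stress = stress, predictor = pred,
    metrics = metrics
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- paste0(config_hash(config), "_seed", seed)
    pipeline_config_write(config, file.path(out_dir, paste0("config_", tag, ".yaml")))
    write_sample_table(table, file.path(out_dir, paste0("samples_", tag, ".csv")))
    if (!is.null(truth)) {
      write_ground_truth(cohort, file.path(out_dir, paste0("ground_truth_", tag, ".json")))
    }
    codec_save(oil_bundle, file.path(out_dir, paste0("oil_codec_", tag, ".json")))
    codec_save(location_bundle, file.path(out_dir, paste0("location_codec_", tag, ".json")))
    readr::write_tsv(
      tibble::tibble(
        rank = ranking$rank, taxon = ranking$taxon,
        importance = ranking$importance
      ),
      file.path(out_dir, paste0("ranking_", tag, ".tsv")), progress = FALSE
    )
    readr::write_csv(aug, file.path(out_dir, paste0("augmented_", tag, ".csv")), progress = FALSE)
    readr::write_csv(stress, file.path(out_dir, paste0("stress_", tag, ".csv")), progress = FALSE)
    readr::write_csv(adnn$log, file.path(out_dir, paste0("adnn_log_", tag, ".csv")), progress = FALSE)
    readr::write_csv(vae$log, file.path(out_dir, paste0("vae_log_", tag, ".csv")), progress = FALSE)
    readr::write_csv(pred$log, file.path(out_dir, paste0("predictor_log_", tag, ".csv")), progress = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, paste0("metrics_", tag, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  result
}
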