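test_that("r_squared matches hand-computed values and rejects degenerate inputs", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_lt(r_squared(y, c(3, 2, 1)), 0) # worse than the mean
  expect_error(r_squared(y, c(1, 2)), class = "microstress_metric_error")
  expect_error(r_squared(c(2, 2, 2), y), class = "microstress_metric_error")
})

test_that("generated oil encodings snap to the nearest legal code value", {
  cv <- c(0, 1, 2)
  expect_equal(microstress:::snap_oil_enc(c(-3, 0.4, 0.6, 1.9, 7), cv), c(0, 0, 1, 2, 2))
})

test_that("bottle-level splits are leakage-free with the documented held-out counts", {
  co <- generate_cohort(cohort_config(
    n_bottles = 172, n_taxa = 30, n_responsive = 6, seed = 51
  ))
  hr <- bottle_holdout(co$samples,
    k = 3, n_splits = 4, test_frac = 0.2, seed = 1,
    num_trees = 200, epochs_adnn = 60, epochs_predictor = 60
  )
  # 0.2 * 172 = 34.4 -> alternating 35/34 held-out bottles
  expect_setequal(unique(hr$splits$n_test_bottles), c(34, 35))
  for (i in seq_len(nrow(hr$splits))) {
    expect_length(
      intersect(hr$splits$test_bottles[[i]], hr$splits$train_bottles[[i]]), 0
    )
    expect_equal(
      length(hr$splits$test_bottles[[i]]) + length(hr$splits$train_bottles[[i]]), 172
    )
  }
  expect_gt(min(hr$splits$n_test_samples), 0)

  # summary statistics recompute exactly from the per-split values
  expect_equal(hr$summary$mean, mean(hr$splits$test_r2), tolerance = 1e-12)
  expect_equal(hr$summary$sd, sd(hr$splits$test_r2), tolerance = 1e-12)
  expect_equal(hr$summary$min, min(hr$splits$test_r2), tolerance = 1e-12)
  expect_equal(hr$summary$max, max(hr$splits$test_r2), tolerance = 1e-12)

  expect_error(bottle_holdout(co$samples, test_frac = 0), class = "microstress_config_error")
  expect_error(
    bottle_holdout(co$samples[co$samples$bottle_id %in% unique(co$samples$bottle_id)[1:3], ]),
    class = "microstress_validation_error"
  )
})

test_that("grouping matters: bottle-level hold-out is harder than sample-level", {
  # strong per-bottle random effects make within-bottle samples informative
  # about each other; splitting by sample leaks that, splitting by bottle not
  co <- generate_cohort(cohort_config(
    n_bottles = 60, samples_per_bottle_mean = 4, n_taxa = 30, n_responsive = 6,
    bottle_effect_sd = 1.5, seed = 52
  ))
  args <- list(
    k = 3, n_splits = 3, seed = 2,
    num_trees = 200, epochs_adnn = 80, epochs_predictor = 80
  )
  by_bottle <- do.call(bottle_holdout, c(list(co$samples), args))
  by_sample_tbl <- dplyr::mutate(co$samples, bottle_id = sample_id)
  by_sample <- do.call(bottle_holdout, c(list(by_sample_tbl), args))
  expect_lt(by_bottle$summary$mean, by_sample$summary$mean)
})

test_that("the feature sweep emits one finite four-metric row per k", {
  co <- tiny_cohort(seed = 53)
  sw <- feature_sweep(co$samples, c(2, 4),
    seed = 1, num_trees = 200,
    epochs_adnn = 100, epochs_vae = 100, epochs_predictor = 100
  )
  expect_equal(sw$k, c(2L, 4L))
  vals <- as.matrix(dplyr::select(tibble::as_tibble(sw), -k))
  expect_true(all(is.finite(vals)))
  expect_error(feature_sweep(co$samples, c(4, 2)), class = "microstress_config_error")
  expect_error(feature_sweep(co$samples, 999), class = "microstress_config_error")
})

test_that("stress_test equals training R^2 on the training set itself and dies on shuffled targets", {
  co <- tiny_cohort(seed = 54)
  sel <- select_top_k(rank_features_rfr(co$samples, num_trees = 200, seed = 1), 3)
  adnn <- train_adnn(co$samples, sel, epochs = 300, seed = 1)
  aug <- build_augmented_set(co$samples, adnn, noise_spec(co$samples, seed = 1))
  model <- train_predictor(aug, epochs = 300, seed = 1)
  cv <- sort(unique(co$samples$oil_enc))

  # degenerate identity: scoring the training rows reproduces training R^2
  # (up to the snap of the synthetic rows' noise-perturbed oil encodings)
  fake_stress <- aug[, setdiff(names(aug), "provenance")]
  class(fake_stress) <- c("stress_set", class(fake_stress))
  expect_equal(stress_test(model, fake_stress, cv), model$r_squared, tolerance = 1e-3)

  # shuffled targets destroy the score
  shuffled <- dplyr::mutate(fake_stress,
    oil_enc = withr::with_seed(9, sample(oil_enc))
  )
  expect_lt(stress_test(model, shuffled, cv), 0.1)
})
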