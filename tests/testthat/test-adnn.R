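test_that("noise injection reproduces the study bookkeeping: 404 rows -> 1,616 -> 2,020", {
  withr::with_seed(1, env <- matrix(rnorm(404 * 5), 404, 5))
  colnames(env) <- env_feature_cols()
  spec <- noise_spec(env, c = 0.01, rounds = 4, seed = 1)
  syn <- inject_noise(env, spec)
  expect_equal(nrow(syn), 1616)
  expect_equal(ncol(syn), 5)
})

test_that("zero noise scale reproduces exact copies and per-column noise matches 0.01 sigma", {
  withr::with_seed(2, env <- matrix(rnorm(300 * 5, sd = rep(c(1, 5, 10, 2, 7), each = 300)), 300, 5))
  spec0 <- noise_spec(env, c = 0, rounds = 4, seed = 3)
  expect_equal(inject_noise(env, spec0), do.call(rbind, replicate(4, env, simplify = FALSE)))

  spec <- noise_spec(env, c = 0.01, rounds = 4, seed = 3)
  syn <- inject_noise(env, spec)
  resid <- syn - do.call(rbind, replicate(4, env, simplify = FALSE))
  sds <- apply(resid, 2, sd)
  expect_true(all(abs(sds - 0.01 * spec$sigma) / (0.01 * spec$sigma) < 0.10))

  # each round draws independent noise
  expect_false(identical(syn[1:300, ], syn[301:600, ]))
})

test_that("ADNN training is deterministic, fits the planted cohort, and logs checkpoints", {
  co <- tiny_cohort(seed = 21)
  sel <- co$truth$responsive_taxa[1:5]
  m1 <- train_adnn(co$samples, sel, epochs = 500, seed = 2)
  m2 <- train_adnn(co$samples, sel, epochs = 500, seed = 2)
  expect_identical(net_weights(m1$net), net_weights(m2$net))
  expect_gte(m1$r_squared, 0.8)
  expect_equal(max(tidy(m1)$r_squared), m1$r_squared, tolerance = 1e-8)
  expect_true(all(tidy(m1)$epoch %% 100 == 0 | tidy(m1)$epoch == 500))

  expect_error(train_adnn(co$samples, integer(0)), class = "microstress_domain_error")
  expect_error(train_adnn(co$samples, 999), class = "microstress_schema_error")
})

test_that("predicted abundances are non-negative and the augmented set partitions correctly", {
  co <- tiny_cohort(seed = 22)
  sel <- select_top_k(rank_features_rfr(co$samples, num_trees = 300, seed = 1), 4)
  model <- train_adnn(co$samples, sel, epochs = 400, seed = 1)
  spec <- noise_spec(co$samples, rounds = 4, seed = 5)
  aug <- build_augmented_set(co$samples, model, spec)

  n <- nrow(co$samples)
  expect_equal(nrow(aug), n * 5)
  expect_equal(sum(aug$provenance == "real"), n)
  expect_equal(sum(aug$provenance == "synthetic"), n * 4)
  expect_true(all(as.matrix(aug[, paste0("Bac_", sel)]) >= 0))

  # real rows are the untouched projection of the source table
  real <- dplyr::filter(aug, provenance == "real")
  expect_equal(
    as.matrix(real[, env_feature_cols()]),
    as.matrix(co$samples[, env_feature_cols()]),
    ignore_attr = TRUE
  )
  expect_equal(
    as.matrix(real[, paste0("Bac_", sel)]),
    as.matrix(co$samples[, paste0("Bac_", sel)]),
    ignore_attr = TRUE
  )

  spec0 <- noise_spec(co$samples, rounds = 0, seed = 5)
  aug0 <- build_augmented_set(co$samples, model, spec0)
  expect_equal(nrow(aug0), n)
  expect_true(all(aug0$provenance == "real"))
})

test_that("an unreliable ADNN (training R^2 < 0.75) triggers the downstream quality gate", {
  co <- tiny_cohort(seed = 23)
  sel <- co$truth$responsive_taxa[1:3]
  weak <- train_adnn(co$samples, sel, epochs = 1, seed = 1)
  expect_lt(weak$r_squared, 0.75)
  expect_false(weak$reliable)
  expect_warning(
    build_augmented_set(co$samples, weak, noise_spec(co$samples, seed = 1)),
    class = "microstress_reliability_warning"
  )
})
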