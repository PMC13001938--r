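test_that("identical configurations generate byte-identical cohorts", {
  a <- generate_cohort(cohort_config(seed = 5, n_bottles = 40, n_taxa = 60))
  b <- generate_cohort(cohort_config(seed = 5, n_bottles = 40, n_taxa = 60))
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$responsive_taxa, b$truth$responsive_taxa)
  c <- generate_cohort(cohort_config(seed = 6, n_bottles = 40, n_taxa = 60))
  expect_false(identical(a$samples, c$samples))
})

test_that("default-shaped cohorts land near the study size with the expected sparsity", {
  for (seed in 1:6) {
    co <- generate_cohort(cohort_config(seed = seed))
    n <- nrow(co$samples)
    expect_gte(n, 404 * 0.9)
    expect_lte(n, 404 * 1.1)
    expect_equal(length(unique(co$samples$bottle_id)), 172)
    counts <- as.matrix(co$samples[, paste0("Bac_", 1:503)])
    # structural zeros alone guarantee >= sparsity * (1 - eps) zero cells
    expect_gte(mean(counts == 0), 0.4 * 0.95)
  }
})

test_that("bottles keep one oil label, one site and distinct sample weeks", {
  co <- tiny_cohort(seed = 9)
  per_bottle <- dplyr::summarise(
    dplyr::group_by(co$metadata, bottle_id),
    n_oil = dplyr::n_distinct(oil_label),
    n_site = dplyr::n_distinct(site),
    weeks_distinct = !anyDuplicated(week),
    .groups = "drop"
  )
  expect_true(all(per_bottle$n_oil == 1))
  expect_true(all(per_bottle$n_site == 1))
  expect_true(all(per_bottle$weeks_distinct))
  expect_true(all(co$metadata$week %in% 0:7))
  expect_true(all(co$samples$time_enc == 10 * co$metadata$week))
})

test_that("marginal counts match the zero-inflated negative-binomial target moments", {
  # flat baseline, no random effects, no planted signal -> iid ZINB cells
  cfg <- cohort_config(
    n_bottles = 60, samples_per_bottle_mean = 2.5, n_taxa = 50,
    n_responsive = 0, sparsity = 0.3, dispersion = 0.5,
    baseline_meanlog = log(8), baseline_sdlog = 0, bottle_effect_sd = 0, seed = 11
  )
  co <- generate_cohort(cfg)
  cells <- as.vector(as.matrix(co$samples[, paste0("Bac_", 1:50)]))
  expect_gte(length(cells), 5000)
  mu <- 8; phi <- 0.5
  p <- 0.3 * exp(-mu / 10) # abundance-damped structural-zero probability
  m_expect <- (1 - p) * mu
  v_expect <- (1 - p) * (mu + phi * mu^2) + p * (1 - p) * mu^2
  expect_lt(abs(mean(cells) - m_expect) / m_expect, 0.15)
  expect_lt(abs(var(cells) - v_expect) / v_expect, 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_responsive = 10, n_taxa = 5), class = "microstress_config_error")
  expect_error(cohort_config(sparsity = 1.2), class = "microstress_config_error")
  expect_error(cohort_config(dispersion = 0), class = "microstress_config_error")
  expect_error(
    cohort_config(n_responsive = 3, effect_log2fc = matrix(1, 2, 2)),
    class = "microstress_config_error"
  )
  expect_error(generate_cohort(list()), class = "microstress_config_error")
})

test_that("the ground-truth sidecar is valid JSON naming the planted taxa", {
  co <- tiny_cohort(seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(co, path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sort(gt$responsive_taxa), co$truth$responsive_taxa)
  expect_length(gt$bottle_oil$bottle_id, 24)
  expect_setequal(unique(gt$bottle_oil$oil_label), c("no_oil", "crude", "diesel"))
})
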