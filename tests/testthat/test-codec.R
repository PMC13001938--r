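test_that("oil labels map to the fixed binary codes and back", {
  expect_equal(unname(oil_label_to_code("crude")[1, ]), c(0, 1))
  expect_equal(unname(oil_label_to_code("diesel")[1, ]), c(1, 0))
  expect_equal(unname(oil_label_to_code("no_oil")[1, ]), c(0, 0))
  expect_error(oil_label_to_code("petrol"), class = "microstress_domain_error")
})

test_that("raw decoder pairs resolve to labels by rounding, nearest-code fallback and tie order", {
  expect_equal(code_to_oil_label(c(0.02, 0.97)), "crude")
  # rounds to the illegal (1,1); crude's code is nearest to the raw pair
  expect_equal(code_to_oil_label(c(0.98, 0.99)), "crude")
  # equidistant from all three codes -> first label in tie order
  expect_equal(code_to_oil_label(c(0.5, 0.5)), "no_oil")
  expect_equal(
    code_to_oil_label(rbind(c(0, 0), c(0.6, 0.1), c(0.1, 0.8))),
    c("no_oil", "diesel", "crude")
  )
})

test_that("the oil codec reconstructs all three codes through its one-neuron bottleneck", {
  bundle <- train_oil_autoencoder(seed = 0)
  expect_gte(bundle$r_squared, 0.999)

  s <- encode(bundle, oil_codes())
  expect_true(all(s >= 0)) # ReLU bottleneck
  expect_gt(min(dist(s)), 1e-6) # distinct codes -> distinct scalars
  expect_equal(code_to_oil_label(decode(bundle, s)), rownames(oil_codes()))

  # the full label -> code -> scalar -> raw pair -> label loop is identity
  for (lab in rownames(oil_codes())) {
    z <- encode(bundle, oil_label_to_code(lab))
    expect_equal(code_to_oil_label(decode(bundle, z)), lab)
  }
})

test_that("codec training is deterministic per seed", {
  b1 <- train_oil_autoencoder(seed = 3, epochs = 300)
  b2 <- train_oil_autoencoder(seed = 3, epochs = 300)
  expect_identical(net_weights(b1$net), net_weights(b2$net))
})

test_that("the location codec compresses distinct site coordinates with high fidelity", {
  coords <- cbind(
    latitude = c(47.62, 44.80, 47.12, 45.81),
    longitude = c(-87.50, -86.90, -88.55, -84.73)
  )
  bundle <- train_location_autoencoder(coords, seed = 0)
  expect_gte(bundle$r_squared, 0.98)

  s <- encode(bundle, coords)
  expect_true(all(s > 0 & s < 1)) # sigmoid bottleneck
  expect_gt(min(dist(s)), 1e-6)
  recon <- decode(bundle, s)
  expect_lt(max(abs(recon - coords)), 0.5) # within half a degree

  # duplicated coordinates decode to the same reconstruction
  s2 <- encode(bundle, coords[c(1, 1), ])
  expect_equal(s2[1], s2[2])
})

test_that("a single distinct coordinate yields a degenerate one-point codec with a warning", {
  coords <- matrix(rep(c(47.0, -88.0), 3), ncol = 2, byrow = TRUE)
  expect_warning(bundle <- train_location_autoencoder(coords, seed = 1), "degenerate")
  expect_true(is.na(bundle$r_squared))
  expect_equal(unname(decode(bundle, 0.5)[1, ]), c(47.0, -88.0))
})

test_that("codec bundles survive JSON serialization", {
  bundle <- train_oil_autoencoder(seed = 2, epochs = 400)
  path <- withr::local_tempfile(fileext = ".json")
  codec_save(bundle, path)
  back <- codec_load(path)
  expect_equal(back$r_squared, bundle$r_squared)
  expect_equal(encode(back, oil_codes()), encode(bundle, oil_codes()), tolerance = 1e-12)
  expect_equal(decode(back, 0.7), decode(bundle, 0.7), tolerance = 1e-12)
})
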