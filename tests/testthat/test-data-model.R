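test_that("temporal encoding multiplies week and month by ten and inverts exactly", {
  expect_equal(scale_temporal(0, 8), tibble::tibble(time_enc = 0, month_enc = 80))
  expect_equal(scale_temporal(7, 5), tibble::tibble(time_enc = 70, month_enc = 50))
  expect_equal(scale_temporal(0, 1), tibble::tibble(time_enc = 0, month_enc = 10))

  grid <- expand.grid(week = 0:7, month = 1:12)
  enc <- scale_temporal(grid$week, grid$month)
  expect_false(any(duplicated(enc))) # injective on the study domain
  back <- unscale_temporal(enc$time_enc, enc$month_enc)
  expect_equal(back$week, grid$week)
  expect_equal(back$month, grid$month)
})

test_that("temporal encoding rejects out-of-domain months and weeks", {
  expect_error(scale_temporal(0, 0), class = "microstress_domain_error")
  expect_error(scale_temporal(0, 13), class = "microstress_domain_error")
  expect_error(scale_temporal(-1, 6), class = "microstress_domain_error")
})

test_that("sample tables round-trip through CSV and TSV with value equality", {
  co <- tiny_cohort(seed = 7)
  for (delim in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_sample_table(co$samples, path, delim = delim)
    back <- read_sample_table(path, delim = delim)
    expect_equal(as.data.frame(back), as.data.frame(co$samples), tolerance = 1e-12)
  }
})

test_that("a table with non-ASCII bottle ids survives the round trip verbatim", {
  tbl <- tiny_cohort(seed = 3)$samples
  tbl$bottle_id[1] <- "flasche_ü1"
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(tbl, path)
  expect_identical(read_sample_table(path)$bottle_id[1], "flasche_ü1")
})

test_that("a taxa-free table (T = 0) is valid and round-trips", {
  tbl <- tiny_cohort(seed = 1)$samples[, c("sample_id", "bottle_id", env_feature_cols())]
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(tbl, path)
  expect_equal(nrow(read_sample_table(path)), nrow(tbl))
})

test_that("schema and validation violations are rejected with classed errors", {
  tbl <- tiny_cohort(seed = 1)$samples
  expect_error(validate_sample_table(dplyr::select(tbl, -bottle_id)),
    class = "microstress_schema_error"
  )
  expect_error(validate_sample_table(tbl, n_taxa = 99),
    class = "microstress_schema_error"
  )

  bad <- tbl; bad$Bac_1[2] <- -2
  expect_error(validate_sample_table(bad), class = "microstress_validation_error")
  bad <- tbl; bad$Bac_1[2] <- 1.5
  expect_error(validate_sample_table(bad), class = "microstress_validation_error")
  bad <- tbl; bad$temperature[1] <- NA
  expect_error(validate_sample_table(bad), class = "microstress_validation_error")
  bad <- tbl; bad$sample_id[2] <- bad$sample_id[1]
  expect_error(validate_sample_table(bad), class = "microstress_validation_error")
  bad <- tbl; bad$month_enc[1] <- 85 # not 10 x calendar month
  expect_error(validate_sample_table(bad), class = "microstress_validation_error")

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(tbl, Bac_1 = Bac_1 - 10), path)
  expect_error(read_sample_table(path), class = "microstress_validation_error")
  expect_error(read_sample_table("no/such/file.csv"), class = "microstress_io_error")
})
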