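#' Environmental feature columns of a sample table
#'
#' Column order of the five-feature environmental block used throughout the
#' pipeline: encoded location, encoded incubation time (10 x weeks), encoded
#' oil type, incubation temperature (degrees C) and encoded calendar month
#' (10 x month).
#'
#' @return Character vector of column names.
#' @export
env_feature_cols <- function() {
  c("location_enc", "time_enc", "oil_enc", "temperature", "month_enc")
}

# environmental block minus the prediction target
predictor_env_cols <- function() setdiff(env_feature_cols(), "oil_enc")

taxa_cols <- function(tbl) grep("^Bac_\\d+$", names(tbl), value = TRUE)

#' Encode incubation week and calendar month on the fixed-point scale
#'
#' Incubation time and collection month enter the model tables multiplied by
#' ten: week 0..7 becomes 0..70 and month 1..12 becomes 10..120 (so 80 is an
#' August collection).
#'
#' @param week Non-negative integer incubation week(s).
#' @param month Calendar month(s), 1-12.
#' @return A tibble with columns `time_enc` and `month_enc`.
#' @examples
#' scale_temporal(0, 8) # time_enc 0, month_enc 80
#' @export
scale_temporal <- function(week, month) {
  if (length(week) != length(month) && length(week) != 1 && length(month) != 1) {
    rlang::abort("week and month lengths are incompatible", class = "microstress_domain_error")
  }
  if (any(!is.finite(week)) || any(week < 0) || any(week != floor(week))) {
    rlang::abort("week must be a non-negative integer", class = "microstress_domain_error")
  }
  if (any(!is.finite(month)) || any(month < 1) || any(month > 12) || any(month != floor(month))) {
    rlang::abort("month must be an integer in 1..12", class = "microstress_domain_error")
  }
  tibble::tibble(time_enc = 10 * week, month_enc = 10 * month)
}

#' Invert the fixed-point temporal encoding
#'
#' @param time_enc,month_enc Encoded values as produced by [scale_temporal()].
#' @return A tibble with columns `week` and `month`.
#' @export
unscale_temporal <- function(time_enc, month_enc) {
  tibble::tibble(week = time_enc / 10, month = month_enc / 10)
}

#' Validate a sample table
#'
#' Checks the invariants of the flat sample table: required identifier and
#' environmental columns, `Bac_*` taxa count columns holding non-negative
#' integers, no missing values, unique sample ids and a month encoding that
#' divides back to a calendar month.
#'
#' @param tbl A data frame.
#' @param n_taxa Optional expected number of taxa columns.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_sample_table <- function(tbl, n_taxa = NULL) {
  required <- c("sample_id", "bottle_id", env_feature_cols())
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "microstress_schema_error"
    )
  }
  tc <- taxa_cols(tbl)
  if (!is.null(n_taxa) && length(tc) != n_taxa) {
    rlang::abort(
      sprintf("expected %d taxa columns, found %d", n_taxa, length(tc)),
      class = "microstress_schema_error"
    )
  }
  tbl <- tibble::as_tibble(tbl)
  if (anyNA(tbl[, c(required, tc)])) {
    rlang::abort("missing values are not allowed in a sample table",
      class = "microstress_validation_error"
    )
  }
  if (anyDuplicated(tbl$sample_id) > 0) {
    rlang::abort("sample_id values must be unique", class = "microstress_validation_error")
  }
  if (length(tc) > 0) {
    counts <- as.matrix(tbl[, tc])
    if (!is.numeric(counts) || any(counts < 0) || any(counts != floor(counts))) {
      rlang::abort("taxa counts must be non-negative integers",
        class = "microstress_validation_error"
      )
    }
  }
  if (nrow(tbl) > 0) {
    m <- tbl$month_enc / 10
    if (any(m < 1 | m > 12 | m != floor(m))) {
      rlang::abort("month_enc must be 10 x a calendar month in 1..12",
        class = "microstress_validation_error"
      )
    }
  }
  tbl
}

#' Read a sample table from delimited text
#'
#' Expects a header row with columns
#' `sample_id,bottle_id,location_enc,time_enc,oil_enc,temperature,month_enc,Bac_1..Bac_T`.
#'
#' @param path File path.
#' @param n_taxa Optional expected taxa count (validated against the header).
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A validated sample-table tibble.
#' @export
read_sample_table <- function(path, n_taxa = NULL, delim = ",") {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "microstress_io_error")
  }
  header <- names(readr::read_delim(path,
    delim = delim, n_max = 0,
    show_col_types = FALSE, progress = FALSE
  ))
  missing <- setdiff(c("sample_id", "bottle_id", env_feature_cols()), header)
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "microstress_schema_error"
    )
  }
  tbl <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      bottle_id = readr::col_character(),
      .default = readr::col_double()
    )
  )
  validate_sample_table(tbl, n_taxa = n_taxa)
}

#' Write a sample table to delimited text
#'
#' @param tbl A valid sample table.
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tbl, path, delim = ",") {
  tbl <- validate_sample_table(tbl)
  ok <- tryCatch(
    {
      readr::write_delim(tbl, path, delim = delim, progress = FALSE)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    rlang::abort(paste0("cannot write sample table: ", conditionMessage(ok)),
      class = "microstress_io_error"
    )
  }
  invisible(path)
}
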