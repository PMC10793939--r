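#' Read an abridged life-table CSV
#'
#' Reads the canonical abridged-mortality CSV dialect: UTF-8, comma-separated,
#' header `country,code,sex,period,age_start,age_span,qx`, one row per
#' country/sex/period/age group, open age span encoded as `-1`, and `period`
#' either a lower-endpoint year (`1990`) or a range label (`"1990-1995"`),
#' which is mapped to its lower endpoint.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping the canonical column
#'   names to the names used in `path` (for raw WPP-style exports), e.g.
#'   `c(country = "Location", qx = "qx5")`.
#' @return A validated [mortality_panel] tibble, rows sorted by
#'   country, sex, period and age.
#' @export
read_abridged_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("mortclubs_io_error", "error")))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df)) {
        names(df)[names(df) == col_map[[canon]]] <- canon
      }
    }
  }
  need <- c("country", "code", "sex", "period", "age_start", "age_span", "qx")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(errorCondition(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      class = c("mortclubs_format_error", "error")))
  }
  df <- df |>
    dplyr::mutate(
      period_start = parse_period(.data$period),
      sex = tolower(as.character(.data$sex)),
      country = as.character(.data$country),
      code = as.character(.data$code),
      age_start = as.numeric(.data$age_start),
      age_span = as.numeric(.data$age_span),
      qx = as.numeric(.data$qx)
    ) |>
    dplyr::select(dplyr::all_of(panel_cols)) |>
    dplyr::arrange(.data$country, .data$sex, .data$period_start, .data$age_start)
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop(errorCondition(
      sprintf("unknown sex value(s): %s", paste(bad_sex, collapse = ", ")),
      class = c("mortclubs_validation_error", "error")))
  }
  validate_panel(df)
}

parse_period <- function(period) {
  p <- as.character(period)
  lower <- sub("^\\s*(\\d{4}).*$", "\\1", p)
  out <- suppressWarnings(as.integer(lower))
  if (anyNA(out)) {
    stop(errorCondition(
      sprintf("unparseable period label: %s", p[which(is.na(out))[1]]),
      class = c("mortclubs_format_error", "error")))
  }
  out
}

#' Write a mortality panel to the canonical CSV dialect
#'
#' Emits the same dialect [read_abridged_csv()] accepts, with deterministic
#' row order (country, sex, period, age) and the period written as a
#' `"1990-1995"`-style label for 5-year periods.
#'
#' @param panel A validated mortality panel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abridged_csv <- function(panel, path) {
  if (nrow(panel) == 0) {
    stop(errorCondition("empty panel", class = c("mortclubs_validation_error", "error")))
  }
  panel <- validate_panel(panel)
  out <- panel |>
    dplyr::arrange(.data$country, .data$sex, .data$period_start, .data$age_start) |>
    dplyr::mutate(period = sprintf("%d-%d", .data$period_start, .data$period_start + 5L)) |>
    dplyr::select("country", "code", "sex", "period", "age_start", "age_span", "qx")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
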