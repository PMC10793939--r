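#' Mortality panels
#'
#' A mortality panel is a long tibble of abridged death probabilities with one
#' row per country, sex, 5-year period and age group, and columns
#' `country`, `code`, `sex`, `period_start`, `age_start`, `age_span`, `qx`.
#' Periods are labelled by their lower endpoint (the 1990-1995 period is
#' stored as `period_start = 1990`). `sex` is `"male"` or `"female"`; there is
#' no combined-sexes category because the analysis treats the sexes as
#' separate populations throughout.
#'
#' @name mortality_panel
NULL

panel_cols <- c("country", "code", "sex", "period_start", "age_start",
                "age_span", "qx")

new_mortality_panel <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- unique(c("mortality_panel", class(df)))
  df
}

#' Validate a mortality panel
#'
#' Checks column presence, the death-probability range, duplicate keys, and
#' that every (country, sex, period) schedule sits on a valid common abridged
#' age grid. Missing `qx` is allowed only in the terminal open group (see
#' [fill_terminal_group()]); a missing value in any closed group is an error.
#'
#' @param panel A data frame in the mortality-panel layout.
#' @param allow_missing_terminal Permit `NA` qx in the open age group.
#' @return The panel (as a `mortality_panel` tibble), invisibly.
#' @export
validate_panel <- function(panel, allow_missing_terminal = TRUE) {
  missing_cols <- setdiff(panel_cols, names(panel))
  if (length(missing_cols) > 0) {
    stop(errorCondition(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      class = c("mortclubs_format_error", "error")))
  }
  panel <- new_mortality_panel(panel[, panel_cols])

  open <- panel$age_span < 0
  bad_na <- which(is.na(panel$qx) & !open)
  if (length(bad_na) > 0) {
    stop(errorCondition(
      sprintf("missing qx outside the terminal group at row %d (only the open group may be imputed)",
              bad_na[1]),
      class = c("mortclubs_validation_error", "error")))
  }
  if (!allow_missing_terminal && anyNA(panel$qx)) {
    stop(errorCondition("missing qx in terminal group",
                        class = c("mortclubs_validation_error", "error")))
  }
  bad_q <- which(!is.na(panel$qx) & (panel$qx < 0 | panel$qx > 1 | !is.finite(panel$qx)))
  if (length(bad_q) > 0) {
    stop(errorCondition(
      sprintf("qx outside [0, 1] at row %d (value %g)", bad_q[1], panel$qx[bad_q[1]]),
      class = c("mortclubs_validation_error", "error")))
  }

  keys <- panel[c("country", "sex", "period_start", "age_start")]
  if (anyDuplicated(keys)) {
    stop(errorCondition("duplicate (country, sex, period, age) rows",
                        class = c("mortclubs_validation_error", "error")))
  }

  ref <- NULL
  split_idx <- split(seq_len(nrow(panel)),
                     interaction(panel$country, panel$sex, panel$period_start,
                                 drop = TRUE))
  for (idx in split_idx) {
    idx <- idx[order(panel$age_start[idx])]
    g <- tibble::tibble(age_start = panel$age_start[idx],
                        age_span = panel$age_span[idx])
    validate_age_grid(g)
    if (is.null(ref)) {
      ref <- g
    } else if (!isTRUE(all.equal(ref, g, check.attributes = FALSE))) {
      stop(errorCondition("schedules do not share a common age grid",
                          class = c("mortclubs_grid_error", "error")))
    }
  }
  invisible(panel)
}

#' Extract the age grid of a panel
#'
#' @param panel A validated mortality panel.
#' @return An `age_grid` tibble.
#' @export
panel_grid <- function(panel) {
  one <- dplyr::filter(panel,
                       .data$country == panel$country[1],
                       .data$sex == panel$sex[1],
                       .data$period_start == panel$period_start[1])
  one <- dplyr::arrange(one, .data$age_start)
  age_grid(one$age_start, one$age_span)
}

#' Impute a missing terminal-group death probability
#'
#' A few populations in WPP-style extracts carry no information for the open
#' 100+ group; for those, the value of the previous (95-99) group is copied
#' in. Missing values in any closed group are not covered by this rule and
#' raise a validation error.
#'
#' @param panel A mortality panel, possibly with `NA` qx in open groups.
#' @param quiet Suppress the message reporting how many cells were filled.
#' @return The panel with every open-group `qx` populated.
#' @export
fill_terminal_group <- function(panel, quiet = FALSE) {
  panel <- validate_panel(panel, allow_missing_terminal = TRUE)
  out <- panel |>
    dplyr::group_by(.data$country, .data$sex, .data$period_start) |>
    dplyr::arrange(.data$age_start, .by_group = TRUE) |>
    dplyr::mutate(qx = ifelse(is.na(.data$qx) & .data$age_span < 0,
                              dplyr::lag(.data$qx), .data$qx)) |>
    dplyr::ungroup()
  n_filled <- sum(is.na(panel$qx)) - sum(is.na(out$qx))
  if (!quiet && n_filled > 0) {
    message(sprintf("fill_terminal_group: imputed %d open-group cell(s) from the previous group", n_filled))
  }
  new_mortality_panel(out)
}
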