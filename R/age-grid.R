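#' Abridged age grid
#'
#' An abridged mortality age grid: age-group lower bounds and interval widths.
#' The terminal group is open-ended and encoded with span `-1`. The default
#' grid is the WPP-style abridged layout: under 1, 1-4, then 5-year groups
#' up to 95-99, closed out by the open group 100+ (22 groups in all).
#'
#' @param starts Integer-ish vector of age-group lower bounds (years),
#'   strictly increasing.
#' @param spans Interval widths in years; the last element must be `-1`
#'   (open group), and each closed interval must abut the next
#'   (`starts[i] + spans[i] == starts[i + 1]`).
#' @return A tibble with columns `age_start` and `age_span`, of class
#'   `age_grid`.
#' @examples
#' g <- age_grid()
#' nrow(g) # 22
#' @export
age_grid <- function(starts = c(0L, 1L, seq(5L, 100L, by = 5L)),
                     spans = c(1L, 4L, rep(5L, 19L), -1L)) {
  if (length(starts) != length(spans)) {
    stop("`starts` and `spans` must have the same length", call. = FALSE)
  }
  g <- tibble::tibble(age_start = as.numeric(starts), age_span = as.numeric(spans))
  class(g) <- c("age_grid", class(g))
  validate_age_grid(g)
  g
}

#' Validate an abridged age grid
#'
#' Checks the structural invariants of an abridged age grid: strictly
#' increasing starts, exactly one open-ended group in the last position, and
#' contiguity of the closed intervals.
#'
#' @param grid A data frame with columns `age_start`, `age_span`.
#' @return The grid, invisibly, if valid; otherwise an error of class
#'   `mortclubs_grid_error`.
#' @export
validate_age_grid <- function(grid) {
  starts <- grid$age_start
  spans <- grid$age_span
  n <- length(starts)
  fail <- function(msg, index = NA_integer_) {
    stop(errorCondition(msg, index = index,
                        class = c("mortclubs_grid_error", "error")))
  }
  if (n < 2) fail("age grid needs at least two groups")
  if (any(diff(starts) <= 0)) {
    fail("age starts must be strictly increasing",
         index = which(diff(starts) <= 0)[1] + 1L)
  }
  open <- which(spans < 0)
  if (length(open) != 1L || open != n) {
    fail("exactly one open-ended span (coded -1) is required, in last position")
  }
  closed <- seq_len(n - 1L)
  bad <- which(abs(starts[closed] + spans[closed] - starts[closed + 1L]) > 1e-9)
  if (length(bad) > 0) {
    fail(sprintf("age grid gap/overlap at index %d: %g + %g != %g",
                 bad[1] + 1L, starts[bad[1]], spans[bad[1]], starts[bad[1] + 1L]),
         index = bad[1] + 1L)
  }
  invisible(grid)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' @importFrom rlang .data %||%
NULL
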