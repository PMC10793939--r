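#' Average years lived by decedents (a-values)
#'
#' Standard abridged-table constants for the average number of years lived
#' within an age group by those dying in it: 0.3 yr for the infant group,
#' 1.5 yr for ages 1-4, half the span for other closed groups, and 2.5 yr for
#' the open terminal group.
#'
#' @param a0 Infant-group value (years).
#' @param a1_4 Value for the 1-4 group (years).
#' @param a_open Terminal open-group value (years); fixes the person-years of
#'   the open group as `L = a_open * l`.
#' @return A list of class `a_rules`.
#' @export
a_rules <- function(a0 = 0.3, a1_4 = 1.5, a_open = 2.5) {
  structure(list(a0 = a0, a1_4 = a1_4, a_open = a_open), class = "a_rules")
}

a_values <- function(grid, rules = a_rules()) {
  spans <- grid$age_span
  a <- spans / 2
  a[spans < 0] <- rules$a_open
  if (grid$age_start[1] == 0 && spans[1] == 1) a[1] <- rules$a0
  i14 <- which(grid$age_start == 1 & spans == 4)
  if (length(i14) == 1) a[i14] <- rules$a1_4
  a
}

#' Build an abridged life table from death probabilities
#'
#' Constructs the full life-table column set (l, d, a, L, T, e) from per-group
#' death probabilities following standard demographic procedures. The open
#' group's death probability is forced to 1 (everyone alive at its start
#' eventually dies in it); its person-years are `a_open * l`.
#'
#' An interior `qx == 1` is permitted: survivorship hits zero there, later
#' rows are zero-filled, and `ex` is reported as 0 with `defined = FALSE`
#' where `lx == 0`.
#'
#' @param schedule A data frame with columns `age_start`, `age_span`, `qx`
#'   for a single population (one country, sex and period), or a full
#'   mortality panel filtered down to one schedule.
#' @param radix Number of survivors at age 0 (default 100000). All
#'   downstream indicators are invariant to this choice.
#' @param rules An [a_rules()] object.
#' @return A tibble with columns `age_start`, `age_span`, `qx`, `ax`, `lx`,
#'   `dx`, `Lx`, `Tx`, `ex`, `defined`, of class `life_table`.
#' @examples
#' g <- age_grid()
#' lt <- life_table(tibble::tibble(age_start = g$age_start,
#'                                 age_span = g$age_span,
#'                                 qx = c(rep(0, 21), 1)))
#' lt$ex[1] # 102.5: nobody dies before 100, then 2.5 years on average
#' @export
life_table <- function(schedule, radix = 1e5, rules = a_rules()) {
  schedule <- dplyr::arrange(tibble::as_tibble(schedule), .data$age_start)
  grid <- age_grid(schedule$age_start, schedule$age_span)
  q <- schedule$qx
  n <- nrow(grid)
  if (anyNA(q) || any(q < 0 | q > 1)) {
    stop(errorCondition("qx must be in [0, 1] and non-missing",
                        class = c("mortclubs_validation_error", "error")))
  }
  q[n] <- 1 # open group closeout
  a <- a_values(grid, rules)

  l <- numeric(n)
  l[1] <- radix
  for (i in seq_len(n - 1)) l[i + 1] <- l[i] * (1 - q[i])
  d <- l * q
  span <- grid$age_span
  L <- numeric(n)
  closed <- seq_len(n - 1)
  L[closed] <- span[closed] * l[closed + 1] + a[closed] * d[closed]
  L[n] <- a[n] * l[n]
  Tx <- rev(cumsum(rev(L)))
  defined <- l > 0
  e <- ifelse(defined, Tx / pmax(l, .Machine$double.xmin), 0)
  if (any(!defined)) {
    warning("survivorship reaches zero before the terminal group; ex reported as 0 there",
            call. = FALSE)
  }
  out <- tibble::tibble(
    age_start = grid$age_start, age_span = span, qx = q, ax = a,
    lx = l, dx = d, Lx = L, Tx = Tx, ex = e, defined = defined
  )
  class(out) <- c("life_table", class(out))
  out
}

#' Conditional distribution of age at death
#'
#' Collapses a life table into the discrete distribution of exact age at
#' death conditional on surviving to `from_age`: one point mass per age
#' group, located at the group's representative death age
#' (`age_start + ax`), weighted by the group's share of deaths among those
#' alive at `from_age`. This distribution is the shared substrate for the
#' modal age, Gini, conditional-SD and moment computations.
#'
#' @param table A [life_table()].
#' @param from_age A grid start with positive survivorship.
#' @return A tibble with columns `age` (representative death age, years) and
#'   `weight` (summing to 1).
#' @export
death_ages <- function(table, from_age = 0) {
  i0 <- match(from_age, table$age_start)
  if (is.na(i0)) {
    stop(errorCondition(sprintf("from_age %g is not an age-group start", from_age),
                        class = c("mortclubs_domain_error", "error")))
  }
  l0 <- table$lx[i0]
  if (l0 <= 0) {
    stop(errorCondition(sprintf("no survivors at age %g", from_age),
                        class = c("mortclubs_undefined_indicator", "error")))
  }
  idx <- seq(i0, nrow(table))
  tibble::tibble(
    age = table$age_start[idx] + table$ax[idx],
    weight = table$dx[idx] / l0
  )
}
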