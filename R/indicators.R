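#' Nine longevity indicators
#'
#' The indicator set used to characterise a population's mortality regime:
#'
#' * `e0`, `e65` — remaining life expectancy at birth and at age 65 (years);
#' * `M` — modal age at death: midpoint of the age group with the most
#'   life-table deaths (years, absolute age);
#' * `G0`, `G65` — Gini index of lifespans conditional on surviving to 0 /
#'   65 (dimensionless, in `[0, 1)`); 0 means everyone dies at the same age;
#' * `s0`, `s65` — conditional standard deviation of age at death among
#'   survivors to 0 / 65 (years);
#' * `y50_0` — median age at death from birth (years);
#' * `y75_65` — age by which 75% of those alive at 65 have died (years).
#'
#' @name indicators
NULL

indicator_names <- c("e0", "e65", "M", "G0", "G65", "s0", "s65", "y50_0", "y75_65")

#' Remaining life expectancy at a grid age
#'
#' @param table A [life_table()].
#' @param age An age-group start (years).
#' @return Remaining expectancy `ex = Tx / lx` at that age (years).
#' @export
life_expectancy <- function(table, age = 0) {
  i <- match(age, table$age_start)
  if (is.na(i)) {
    stop(errorCondition(sprintf("age %g is not an age-group start", age),
                        class = c("mortclubs_domain_error", "error")))
  }
  if (!table$defined[i]) {
    stop(errorCondition(sprintf("life expectancy undefined: no survivors at age %g", age),
                        class = c("mortclubs_undefined_indicator", "error")))
  }
  table$ex[i]
}

#' Modal age at death
#'
#' The mean age of the interval with the highest number of life-table
#' deaths: `start + span/2` for a closed group, `start + ax` for the open
#' group. Ties are broken toward the youngest group, deterministically.
#'
#' @param table A [life_table()].
#' @return Modal age at death (years, absolute age).
#' @export
modal_age <- function(table) {
  i <- which.max(table$dx) # which.max takes the first (= youngest) maximum
  if (table$age_span[i] < 0) {
    table$age_start[i] + table$ax[i]
  } else {
    table$age_start[i] + table$age_span[i] / 2
  }
}

#' Gini index from a discrete death-age distribution
#'
#' Pairwise-difference (double-sum) Gini of a discrete distribution of ages
#' at death: `G = sum_ij w_i w_j |z_i - z_j| / (2 mu)` with `mu = sum w_i z_i`.
#'
#' @param age Ages at death (years).
#' @param weight Probability masses (will be normalised to sum to 1).
#' @return Dimensionless Gini in `[0, 1)`.
#' @export
gini_from_death_ages <- function(age, weight) {
  w <- weight / sum(weight)
  mu <- sum(w * age)
  if (mu <= 0) return(0)
  sum(outer(w, w) * abs(outer(age, age, "-"))) / (2 * mu)
}

#' Gini index of lifespans
#'
#' Lifespan inequality among survivors to `age`, computed on absolute ages at
#' death (not remaining years) from the conditional [death_ages()]
#' distribution. Zero when everyone dies at the same age; approaches 1 when
#' all but a vanishing fraction die at the earliest age.
#'
#' @param table A [life_table()].
#' @param age Conditioning age (a grid start, usually 0 or 65).
#' @param absolute Compute on absolute ages (default). With `FALSE`, ages are
#'   first shifted to remaining years past `age`, which changes the
#'   denominator mean and hence the index for `age > 0`.
#' @return Dimensionless Gini index.
#' @export
gini_index <- function(table, age = 0, absolute = TRUE) {
  dd <- death_ages(table, age)
  z <- if (absolute) dd$age else dd$age - age
  gini_from_death_ages(z, dd$weight)
}

#' Conditional standard deviation of age at death
#'
#' Standard deviation of the age at death among survivors to `age`
#' (location-invariant, so identical for absolute ages and remaining years).
#'
#' @inheritParams gini_index
#' @return Standard deviation in years.
#' @export
conditional_sd <- function(table, age = 0) {
  dd <- death_ages(table, age)
  mu <- sum(dd$weight * dd$age)
  sqrt(sum(dd$weight * (dd$age - mu)^2))
}

#' Survival percentile (life preparancy)
#'
#' The age by which a fraction `p` of those alive at `age` have died, read
#' off the conditional survival curve `l_y / l_age` with linear interpolation
#' of `lx` within the bracketing group (deaths uniform within the group).
#' When the crossing would fall inside the open terminal group the
#' representative age `start + ax` of the open group is returned and flagged
#' as censored via attribute `censored`.
#'
#' @param table A [life_table()].
#' @param p Fraction in (0, 1); `p = 0.5` from birth is the median age at
#'   death.
#' @param age Conditioning age (a grid start).
#' @return Age in years (absolute), with attribute `censored`.
#' @export
survival_percentile <- function(table, p, age = 0) {
  stopifnot(p > 0, p < 1)
  i0 <- match(age, table$age_start)
  if (is.na(i0)) {
    stop(errorCondition(sprintf("age %g is not an age-group start", age),
                        class = c("mortclubs_domain_error", "error")))
  }
  l0 <- table$lx[i0]
  if (l0 <= 0) {
    stop(errorCondition(sprintf("no survivors at age %g", age),
                        class = c("mortclubs_undefined_indicator", "error")))
  }
  target <- (1 - p) * l0
  n <- nrow(table)
  idx <- seq(i0, n)
  l <- table$lx[idx]
  starts <- table$age_start[idx]
  spans <- table$age_span[idx]
  # first grid point (after the conditioning age) at or below the target
  below <- which(l <= target + 1e-12 * l0)
  below <- below[below > 1]
  if (length(below) == 0) {
    # crossing inside the open group
    out <- starts[length(starts)] + table$ax[n]
    attr(out, "censored") <- TRUE
    return(out)
  }
  j <- below[1]
  l_hi <- l[j - 1]
  l_lo <- l[j]
  frac <- if (l_hi - l_lo > 0) (l_hi - target) / (l_hi - l_lo) else 0
  out <- starts[j - 1] + spans[j - 1] * frac
  attr(out, "censored") <- FALSE
  out
}

#' All nine indicators for one life table
#'
#' @param table A [life_table()].
#' @return A one-row tibble with columns
#'   `e0, e65, M, G0, G65, s0, s65, y50_0, y75_65`.
#' @export
indicator_vector <- function(table) {
  tibble::tibble(
    e0 = life_expectancy(table, 0),
    e65 = life_expectancy(table, 65),
    M = modal_age(table),
    G0 = gini_index(table, 0),
    G65 = gini_index(table, 65),
    s0 = conditional_sd(table, 0),
    s65 = conditional_sd(table, 65),
    y50_0 = as.numeric(survival_percentile(table, 0.5, 0)),
    y75_65 = as.numeric(survival_percentile(table, 0.75, 65))
  )
}

#' Country-by-indicator panel for one period and sex
#'
#' Builds life tables for every country present in the mortality panel at
#' the requested period and sex and assembles the country x indicator matrix
#' used by the clustering and convergence stages.
#'
#' @param panel A validated mortality panel.
#' @param period_start Period lower endpoint (year).
#' @param sex `"male"` or `"female"`.
#' @param radix,rules Passed to [life_table()].
#' @return A tibble with columns `country`, `code`, `sex`, `period_start`
#'   and the nine indicator columns, in input country order; class
#'   `indicator_panel`.
#' @export
indicator_panel <- function(panel, period_start, sex, radix = 1e5,
                            rules = a_rules()) {
  sub <- panel[panel$period_start == period_start & panel$sex == sex, ]
  if (nrow(sub) == 0) {
    stop(errorCondition(
      sprintf("no schedules for period %s, sex %s", period_start, sex),
      class = c("mortclubs_domain_error", "error")))
  }
  countries <- unique(panel$country)
  have <- unique(sub$country)
  missing <- setdiff(countries, have)
  if (length(missing) > 0) {
    stop(errorCondition(
      sprintf("missing schedules for (%s, %s): %s", period_start, sex,
              paste(missing, collapse = ", ")),
      class = c("mortclubs_domain_error", "error")))
  }
  out <- sub |>
    dplyr::group_by(.data$country, .data$code, .data$sex, .data$period_start) |>
    dplyr::group_modify(function(df, key) {
      indicator_vector(life_table(df, radix = radix, rules = rules))
    }) |>
    dplyr::ungroup()
  out <- out[match(countries, out$country), ]
  class(out) <- c("indicator_panel", class(out))
  out
}

#' Indicator panels for several periods and sexes
#'
#' @param panel A mortality panel.
#' @param periods Period lower endpoints; default all in `panel`.
#' @param sexes Sexes; default all in `panel`.
#' @inheritParams indicator_panel
#' @return One tibble stacking an [indicator_panel()] per (period, sex).
#' @export
indicator_panels <- function(panel, periods = NULL, sexes = NULL, radix = 1e5,
                             rules = a_rules()) {
  periods <- periods %||% sort(unique(panel$period_start))
  sexes <- sexes %||% sort(unique(panel$sex))
  combos <- tidyr::expand_grid(period_start = periods, sex = sexes)
  out <- purrr::pmap(combos, function(period_start, sex) {
    indicator_panel(panel, period_start, sex, radix = radix, rules = rules)
  }) |> purrr::list_rbind()
  class(out) <- c("indicator_panel", class(out))
  out
}

#' Correlation between the nine indicators
#'
#' Pearson correlations pooled over all rows (countries, sexes, periods) of
#' the supplied indicator panel(s). A constant column yields `NA`
#' correlations with the other columns.
#'
#' @param panels An indicator panel (or several, row-bound).
#' @return A 9 x 9 symmetric correlation matrix with unit diagonal.
#' @export
indicator_correlation <- function(panels) {
  x <- as.matrix(panels[, indicator_names])
  if (nrow(x) < 2) {
    stop(errorCondition("need at least two rows to correlate",
                        class = c("mortclubs_domain_error", "error")))
  }
  constant <- apply(x, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  r
}
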