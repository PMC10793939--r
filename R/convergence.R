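#' Beta-convergence regression for one indicator
#'
#' Classical cross-country beta-convergence: ordinary least squares of the
#' log growth of an indicator between two periods on its initial log level,
#' `log(y_t2 / y_t1) = a + beta * log(y_t1) + eps`, over the countries
#' present in both panels. A significantly negative slope means laggard
#' countries catch up (convergence); a significantly positive one means
#' divergence.
#'
#' @param panel_t1,panel_t2 [indicator_panel()] tibbles for the initial and
#'   final period (same sex).
#' @param indicator One of the nine indicator column names.
#' @param min_countries Minimum usable shared countries (default 10).
#' @return A one-row tibble of class `convergence_result`: indicator, sex,
#'   periods, `beta`, `se`, `statistic` (t), `p.value`, `n`, and verdicts at
#'   the .01/.05/.10 levels (`"convergence"`, `"divergence"` or
#'   `"inconclusive"`).
#' @export
beta_convergence <- function(panel_t1, panel_t2, indicator,
                             min_countries = 10L) {
  shared <- intersect(panel_t1$country, panel_t2$country)
  y1 <- panel_t1[[indicator]][match(shared, panel_t1$country)]
  y2 <- panel_t2[[indicator]][match(shared, panel_t2$country)]
  ok <- is.finite(y1) & is.finite(y2) & y1 > 0 & y2 > 0
  if (any(!ok)) {
    warning(sprintf("dropping %d country(ies) with non-positive %s",
                    sum(!ok), indicator), call. = FALSE)
  }
  y1 <- y1[ok]; y2 <- y2[ok]
  n <- length(y1)
  if (n < min_countries) {
    stop(errorCondition(
      sprintf("beta-convergence needs >= %d usable shared countries, got %d",
              min_countries, n),
      class = c("mortclubs_domain_error", "error")))
  }
  x <- log(y1)
  g <- log(y2) - log(y1)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (g - mean(g))) / sxx
  resid <- g - mean(g) - beta * (x - mean(x))
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  if (se < 1e-300) {
    # perfectly collinear growth: zero slope is uninformative, non-zero exact
    tstat <- if (abs(beta) < 1e-12) 0 else sign(beta) * Inf
    p <- if (abs(beta) < 1e-12) 1 else 0
  } else {
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  verdict <- function(level) {
    if (p < level) {
      if (beta < 0) "convergence" else "divergence"
    } else "inconclusive"
  }
  out <- tibble::tibble(
    indicator = indicator,
    sex = panel_t1$sex[1],
    period_t1 = panel_t1$period_start[1],
    period_t2 = panel_t2$period_start[1],
    beta = beta, se = se, statistic = tstat, p.value = p, n = n,
    verdict_01 = verdict(0.01), verdict_05 = verdict(0.05),
    verdict_10 = verdict(0.10)
  )
  class(out) <- c("convergence_result", class(out))
  out
}

#' Sigma-convergence: coefficient of variation across countries
#'
#' The cross-country coefficient of variation (population standard
#' deviation divided by the mean) of each indicator, per period and sex.
#' A declining CV over time is sigma-convergence. A `cv_ratio` column
#' (male / female) is attached per indicator and period where both sexes are
#' present, since male longevity dispersion is systematically compared with
#' female dispersion.
#'
#' @param panels A stacked [indicator_panels()] tibble.
#' @return A tibble with columns `indicator`, `sex`, `period_start`, `cv`,
#'   and (where computable) `cv_male_over_female`.
#' @export
sigma_dispersion <- function(panels) {
  long <- panels |>
    tidyr::pivot_longer(dplyr::all_of(indicator_names),
                        names_to = "indicator", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$indicator, .data$sex, .data$period_start) |>
    dplyr::summarise(
      cv = stats::sd(.data$value) * sqrt((dplyr::n() - 1) / dplyr::n()) /
        mean(.data$value),
      .groups = "drop"
    )
  if (all(c("male", "female") %in% unique(out$sex))) {
    ratio <- out |>
      tidyr::pivot_wider(names_from = "sex", values_from = "cv") |>
      dplyr::mutate(cv_male_over_female = .data$male / .data$female) |>
      dplyr::select("indicator", "period_start", "cv_male_over_female")
    out <- dplyr::left_join(out, ratio, by = c("indicator", "period_start"))
  } else {
    out$cv_male_over_female <- NA_real_
  }
  dplyr::arrange(out, .data$indicator, .data$sex, .data$period_start)
}

#' Full beta-convergence grid
#'
#' Runs [beta_convergence()] for every indicator, sex, and requested period
#' pair, with significance stars at the .01/.05/.10 levels and a
#' Holm-adjusted p-value column across the whole grid for transparency (the
#' per-cell verdicts are not adjusted).
#'
#' @param panels A stacked [indicator_panels()] tibble.
#' @param pairs A list of `c(t1, t2)` period pairs.
#' @param indicators Indicator columns to test (default all nine).
#' @return A tibble with one row per indicator x sex x pair.
#' @export
convergence_report <- function(panels, pairs,
                               indicators = indicator_names) {
  sexes <- sort(unique(panels$sex))
  grid <- tidyr::expand_grid(
    pair = pairs, sex = sexes, indicator = indicators
  )
  out <- purrr::pmap(grid, function(pair, sex, indicator) {
    p1 <- panels[panels$period_start == pair[1] & panels$sex == sex, ]
    p2 <- panels[panels$period_start == pair[2] & panels$sex == sex, ]
    beta_convergence(p1, p2, indicator)
  }) |> purrr::list_rbind()
  out |>
    dplyr::mutate(
      stars = dplyr::case_when(
        .data$p.value < 0.01 ~ "***",
        .data$p.value < 0.05 ~ "**",
        .data$p.value < 0.10 ~ "*",
        TRUE ~ ""
      ),
      p.holm = stats::p.adjust(.data$p.value, method = "holm")
    )
}
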