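#' Fit the logit-link Lee-Carter model for one population
#'
#' Models the logit of the abridged death probabilities as
#' `logit q_{x,t} = alpha_x + beta_x * kappa_t`, with the identifiability
#' constraints `sum(beta) = 1` and `sum(kappa) = 0`. `alpha_x` is the per-age
#' mean of the logit over the fitted periods; `(beta, kappa)` is the
#' least-squares rank-1 factorisation of the centered logit matrix (first
#' singular component), i.e. Gaussian maximum likelihood on the logit scale.
#' The open terminal group is never modelled (its probability is 1 by
#' construction) and is excluded from fitting.
#'
#' Death probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logit;
#' the number of clamped cells is recorded in the fit.
#'
#' @param panel A validated mortality panel.
#' @param country,sex Population selector.
#' @return An object of class `lc_fit`: list with `alpha`, `beta`, `kappa`,
#'   `fitted_periods`, `grid`, `country`, `code`, `sex`, `rss` (residual sum
#'   of squares on the logit scale), `sv_share` (share of centered variation
#'   captured by the rank-1 term), `n_clamped`.
#' @export
lc_fit <- function(panel, country, sex) {
  sub <- panel[panel$country == country & panel$sex == sex, ]
  if (nrow(sub) == 0) {
    stop(errorCondition(sprintf("no schedules for %s/%s", country, sex),
                        class = c("mortclubs_domain_error", "error")))
  }
  periods <- sort(unique(sub$period_start))
  if (length(periods) < 3) {
    stop(errorCondition("Lee-Carter fit needs at least 3 periods",
                        class = c("mortclubs_fit_error", "error")))
  }
  grid <- panel_grid(sub)
  closed <- grid$age_span > 0
  wide <- sub |>
    dplyr::arrange(.data$period_start, .data$age_start) |>
    dplyr::select("period_start", "age_start", "qx") |>
    tidyr::pivot_wider(names_from = "period_start", values_from = "qx") |>
    dplyr::arrange(.data$age_start)
  q <- as.matrix(wide[closed, as.character(periods)])
  n_clamped <- sum(q < 1e-7 | q > 1 - 1e-7)
  q <- pmin(pmax(q, 1e-7), 1 - 1e-7)
  Z <- logit(q) # ages x periods

  alpha <- rowMeans(Z)
  C <- Z - alpha
  s <- svd(C, nu = 1, nv = 1)
  if (s$d[1] < 1e-12) {
    beta <- rep(1 / nrow(C), nrow(C))
    kappa <- rep(0, ncol(C))
    warning("degenerate (constant) logit surface: beta set uniform, kappa zero",
            call. = FALSE)
  } else {
    u <- s$u[, 1]
    v <- s$v[, 1]
    bsum <- sum(u)
    if (abs(bsum) < 1e-12) {
      stop(errorCondition("beta not normalisable: age loadings sum to zero",
                          class = c("mortclubs_fit_error", "error")))
    }
    beta <- u / bsum
    kappa <- s$d[1] * v * bsum
    # columns of C have zero row-sums, so v is orthogonal to 1: sum(kappa) ~ 0
  }
  fitted <- alpha + outer(beta, kappa)
  structure(list(
    alpha = alpha, beta = beta, kappa = kappa,
    fitted_periods = periods, grid = grid,
    country = country, code = sub$code[1], sex = sex,
    rss = sum((Z - fitted)^2),
    sv_share = if (s$d[1] < 1e-12) 1 else s$d[1]^2 / sum(s$d^2),
    n_clamped = n_clamped
  ), class = "lc_fit")
}

#' Extrapolate the Lee-Carter period index
#'
#' Selects a time-series model for `kappa_t` over a small ARIMA grid by
#' (small-sample corrected) AIC and returns the central forecast. The grid
#' spans p in 0..2, d in 0..1, q in 0..1 restricted to `p + q <= 1`, each
#' with and without a drift/trend term. Series with fewer than 8
#' observations cannot support order selection, so the model is then forced
#' to a random walk with drift — the classical Lee-Carter extrapolation.
#'
#' @param fit An [lc_fit()] object (or a numeric kappa series).
#' @param horizon Number of periods ahead (>= 1).
#' @return An object of class `kappa_forecast`: list with `order` (p, d, q),
#'   `drift` (logical), `coef`, `aicc`, `forecast` (central forecast, length
#'   `horizon`), `candidates` (per-candidate AICc table), `kappa`.
#' @export
lc_forecast_kappa <- function(fit, horizon) {
  stopifnot(horizon >= 1)
  kappa <- if (inherits(fit, "lc_fit")) fit$kappa else as.numeric(fit)
  if (any(!is.finite(kappa))) {
    stop(errorCondition("non-finite kappa", class = c("mortclubs_fit_error", "error")))
  }
  n <- length(kappa)
  if (n < 8) {
    cand <- tibble::tibble(p = 0L, d = 1L, q = 0L, drift = TRUE)
  } else {
    cand <- tidyr::expand_grid(p = 0:2, d = 0:1, q = 0:1,
                               drift = c(TRUE, FALSE))
    cand <- cand[cand$p + cand$q <= 1, ]
  }
  results <- purrr::pmap(cand, function(p, d, q, drift) {
    fit_kappa_arima(kappa, c(p, d, q), drift, horizon)
  })
  ok <- !purrr::map_lgl(results, is.null)
  if (!any(ok)) {
    stop(errorCondition("no kappa time-series candidate converged",
                        class = c("mortclubs_fit_error", "error")))
  }
  aiccs <- purrr::map_dbl(results, \(r) if (is.null(r)) Inf else r$aicc)
  best <- results[[which.min(aiccs)]]
  best$candidates <- dplyr::mutate(cand, aicc = aiccs)
  best$kappa <- kappa
  class(best) <- "kappa_forecast"
  best
}

# One ARIMA candidate fitted by conditional/state-space ML. "Drift" is a
# linear time regressor: with d = 1 its coefficient is the per-period drift.
fit_kappa_arima <- function(kappa, order, drift, horizon) {
  n <- length(kappa)
  d <- order[2]
  if (order[1] == 0 && d == 1 && order[3] == 0) {
    # random walk with (optional) drift: closed form, always available
    mu <- if (drift) mean(diff(kappa)) else 0
    res <- diff(kappa) - mu
    sigma2 <- mean(res^2)
    k <- 1 + as.integer(drift)
    m <- n - 1
    ll <- -0.5 * m * (log(2 * pi * max(sigma2, 1e-300)) + 1)
    aic <- -2 * ll + 2 * k
    aicc <- aic + if (m - k - 1 > 0) 2 * k * (k + 1) / (m - k - 1) else Inf
    if (n < 8) aicc <- aic # forced model, no competition
    return(list(order = c(0L, 1L, 0L), drift = drift,
                coef = c(drift = mu), sigma2 = sigma2, aicc = aicc,
                forecast = kappa[n] + mu * seq_len(horizon),
                resid = res))
  }
  xreg <- if (drift) matrix(seq_len(n), dimnames = list(NULL, "drift")) else NULL
  fit <- tryCatch(
    stats::arima(kappa, order = order, xreg = xreg,
                 include.mean = (d == 0), method = "ML"),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(NULL)
  k <- length(stats::coef(fit)) + 1 # + innovation variance
  m <- n - d
  aicc <- fit$aic + if (m - k - 1 > 0) 2 * k * (k + 1) / (m - k - 1) else Inf
  newxreg <- if (drift) matrix(n + seq_len(horizon), dimnames = list(NULL, "drift")) else NULL
  fc <- stats::predict(fit, n.ahead = horizon, newxreg = newxreg)
  list(order = as.integer(order), drift = drift, coef = stats::coef(fit),
       sigma2 = fit$sigma2, aicc = aicc,
       forecast = as.numeric(fc$pred), resid = as.numeric(stats::residuals(fit)))
}

#' Forecast death probabilities from a Lee-Carter fit
#'
#' Maps extrapolated kappa values back to the probability scale:
#' `qhat = inv_logit(alpha + beta * kappa_hat)` for closed age groups; the
#' open terminal group is set to 1.
#'
#' @param fit An [lc_fit()].
#' @param kf A [lc_forecast_kappa()] result (or numeric kappa values).
#' @param period_step Calendar years between periods (default 5).
#' @return A mortality panel tibble of forecast schedules, one per horizon
#'   step, with `period_start` continuing the fitted periods.
#' @export
lc_forecast_q <- function(fit, kf, period_step = 5L) {
  kappa_hat <- if (inherits(kf, "kappa_forecast")) kf$forecast else as.numeric(kf)
  closed <- fit$grid$age_span > 0
  last <- max(fit$fitted_periods)
  out <- purrr::imap(kappa_hat, function(k, h) {
    q <- rep(1, nrow(fit$grid))
    q[closed] <- inv_logit(fit$alpha + fit$beta * k)
    tibble::tibble(
      country = fit$country, code = fit$code, sex = fit$sex,
      period_start = last + period_step * h,
      age_start = fit$grid$age_start, age_span = fit$grid$age_span, qx = q
    )
  }) |> purrr::list_rbind()
  validate_panel(out)
}

#' Extend a mortality panel with Lee-Carter forecasts
#'
#' Fits the logit Lee-Carter model independently for every (country, sex)
#' population in the panel — each population is assumed to continue its own
#' past mortality experience separately — extrapolates kappa, and appends
#' the forecast periods to the observed ones.
#'
#' @param panel A validated mortality panel with >= 3 periods per population.
#' @param horizon Number of 5-year periods to forecast (3 extends
#'   1990..2015 data to 2020, 2025, 2030).
#' @return The panel extended with forecast rows, sorted by country, sex,
#'   period, age.
#' @export
lc_project_panel <- function(panel, horizon = 3L) {
  pops <- dplyr::distinct(panel, .data$country, .data$sex)
  failures <- character(0)
  fc <- purrr::pmap(pops, function(country, sex) {
    tryCatch({
      fit <- lc_fit(panel, country, sex)
      lc_forecast_q(fit, lc_forecast_kappa(fit, horizon))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s/%s: %s", country, sex, conditionMessage(e)))
      NULL
    })
  }) |> purrr::list_rbind()
  if (length(failures) > 0) {
    stop(errorCondition(
      sprintf("Lee-Carter projection failed for %d population(s):\n%s",
              length(failures), paste(failures, collapse = "\n")),
      class = c("mortclubs_fit_error", "error")))
  }
  out <- dplyr::bind_rows(panel, fc) |>
    dplyr::arrange(.data$country, .data$sex, .data$period_start, .data$age_start)
  new_mortality_panel(out)
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("Logit Lee-Carter fit: %s (%s), %d periods %d-%d\n",
              x$country, x$sex, length(x$fitted_periods),
              min(x$fitted_periods), max(x$fitted_periods)))
  cat(sprintf("  rank-1 share of centered variation: %.1f%%; logit RSS %.4g\n",
              100 * x$sv_share, x$rss))
  invisible(x)
}

#' Tidy a Lee-Carter fit
#'
#' @param x An `lc_fit`.
#' @param ... Unused.
#' @return A tibble in long form: one row per parameter element, with
#'   columns `term` (`alpha`, `beta`, `kappa`), `index` (age-group start or
#'   period year) and `estimate`.
#' @export
tidy.lc_fit <- function(x, ...) {
  ages <- x$grid$age_start[x$grid$age_span > 0]
  dplyr::bind_rows(
    tibble::tibble(term = "alpha", index = ages, estimate = x$alpha),
    tibble::tibble(term = "beta", index = ages, estimate = x$beta),
    tibble::tibble(term = "kappa", index = as.numeric(x$fitted_periods),
                   estimate = x$kappa)
  )
}

#' Glance at a Lee-Carter fit
#'
#' @inheritParams tidy.lc_fit
#' @return A one-row tibble with fit summary statistics.
#' @export
glance.lc_fit <- function(x, ...) {
  tibble::tibble(
    country = x$country, sex = x$sex,
    n_periods = length(x$fitted_periods),
    n_ages = length(x$alpha),
    rss = x$rss, sv_share = x$sv_share, n_clamped = x$n_clamped
  )
}

#' Plot Lee-Carter parameters
#'
#' @param object An `lc_fit`.
#' @param ... Unused.
#' @return A ggplot with one facet per parameter (alpha and beta over age,
#'   kappa over time).
#' @export
autoplot.lc_fit <- function(object, ...) {
  df <- tidy.lc_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(
      title = sprintf("Logit Lee-Carter parameters: %s (%s)",
                      object$country, object$sex),
      x = "age-group start / period", y = "estimate"
    )
}
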