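#' Configuration for the synthetic abridged-mortality generator
#'
#' The generator plants `n_regimes` latent mortality regimes (convergence
#' clubs) and draws countries from them under a logit-scale Lee-Carter
#' generative model:
#'
#' `logit q_{x,t}^{(c,s)} = alpha_x^{(r)} + u_c + s * sex_gap
#'    + beta_x^{(r)} * kappa_t^{(r)} + eps_{x,t,c,s}`
#'
#' with `sum(beta) = 1` per regime, `kappa` linear in time with a
#' regime-specific drift and centered over the generated periods, country
#' effects `u_c ~ N(0, country_effect_sd^2)`, and iid Gaussian logit noise.
#' The defaults emulate the scale of a WPP-style extract: 5 regimes x 30
#' countries (approx. 150 of the world's populations), both sexes, the six
#' 5-year periods 1990..2015, and the default abridged age grid.
#'
#' @param n_regimes Number of latent regimes (default 5, matching the
#'   five-club world geometry).
#' @param countries_per_regime Countries drawn per regime (default 30).
#' @param periods Period lower endpoints (default `seq(1990, 2015, 5)`).
#' @param grid Abridged [age_grid()].
#' @param regime_separation Logit-scale shift between adjacent regime
#'   baselines (default 0.8).
#' @param drift_per_period Per-regime kappa decrement per 5-year period;
#'   default `seq(-1.6, -0.8, length.out = n_regimes)` — more negative
#'   (faster improvement) for the lowest-mortality regimes.
#' @param sex_gap Logit shift added to male schedules (default 0.25; male
#'   mortality exceeds female).
#' @param noise_sd Logit-scale iid noise SD (default 0.05).
#' @param country_effect_sd SD of the per-country level effect (default 0.1).
#' @param seed Integer seed; the panel is bit-reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regimes = 5L, countries_per_regime = 30L,
                             periods = seq(1990L, 2015L, by = 5L),
                             grid = age_grid(),
                             regime_separation = 0.8,
                             drift_per_period = NULL,
                             sex_gap = 0.25, noise_sd = 0.05,
                             country_effect_sd = 0.1, seed = 1L) {
  stopifnot(n_regimes >= 1, countries_per_regime >= 1, length(periods) >= 1,
            noise_sd >= 0, country_effect_sd >= 0)
  drift_per_period <- drift_per_period %||%
    seq(-1.6, -0.8, length.out = n_regimes)
  structure(list(
    n_regimes = as.integer(n_regimes),
    countries_per_regime = as.integer(countries_per_regime),
    periods = as.integer(periods), grid = grid,
    regime_separation = regime_separation,
    drift_per_period = drift_per_period,
    sex_gap = sex_gap, noise_sd = noise_sd,
    country_effect_sd = country_effect_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Baseline logit mortality schedule
#'
#' A smooth human-like abridged schedule on the logit scale: an infant
#' component decaying through childhood plus a Gompertz-type log-linear
#' adult rise, shifted by `level`. The constants are chosen so that
#' `level = 0` yields a mid-mortality population (life expectancy at birth
#' around 70 years) and levels in -2..+2 span roughly the 50-85 year range
#' observed across world regions.
#'
#' @param level Logit-scale shift (0 = mid-mortality baseline).
#' @param grid An [age_grid()].
#' @return Numeric vector of logit death probabilities for the closed
#'   groups (the open group carries probability 1 and is not returned).
#' @export
baseline_logit_schedule <- function(level = 0, grid = age_grid()) {
  closed <- grid$age_span > 0
  x <- grid$age_start[closed]
  # Gompertz-type adult rise (log-linear in age, anchored so the 95-99 group
  # is near q = 0.5 at mid level) plus an infant component decaying over
  # childhood. The infant coefficient is kept moderate so the death
  # distribution's argmax stays at adult ages over the whole usable level
  # range (the modal age is discontinuous where the infant group overtakes
  # the adult peak; schedules are kept clear of that flip so the indicator
  # varies smoothly with level). e0 = 75 at level 0, spanning ~56-90 over
  # levels +2..-2.
  -10.8 + 0.136 * x + 6.3 * exp(-x / 1.6) + level
}

#' Generate a synthetic mortality panel with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `panel` (a validated [mortality_panel] covering all
#'   countries, sexes and periods) and `truth` (list: `regimes` tibble of
#'   country, code, regime, country effect; per-regime `alpha`, `beta`,
#'   `kappa` matrices/lists as generated).
#' @export
generate_panel <- function(config = synthetic_config()) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    code
  }
  withr_seed({
    grid <- config$grid
    closed <- grid$age_span > 0
    x <- grid$age_start[closed]
    K <- config$n_regimes
    Tn <- length(config$periods)

    # regimes ordered from lowest (1) to highest (K) mortality level
    levels <- (seq_len(K) - (K + 1) / 2) * config$regime_separation
    alpha <- purrr::map(levels, \(lv) baseline_logit_schedule(lv, grid))
    beta_raw <- exp(-x / 40) # improvements concentrated at younger ages
    beta <- purrr::map(seq_len(K), \(r) beta_raw / sum(beta_raw))
    kappa <- purrr::map(seq_len(K), function(r) {
      t_idx <- seq_len(Tn)
      config$drift_per_period[r] * (t_idx - mean(t_idx))
    })

    n_countries <- K * config$countries_per_regime
    regime <- rep(seq_len(K), each = config$countries_per_regime)
    country <- sprintf("Country_%03d", seq_len(n_countries))
    code <- sprintf("C%03d", seq_len(n_countries))
    u <- stats::rnorm(n_countries, 0, config$country_effect_sd)

    combos <- tidyr::expand_grid(ci = seq_len(n_countries),
                                 sex = c("female", "male"),
                                 ti = seq_len(Tn))
    rows <- purrr::pmap(combos, function(ci, sex, ti) {
      r <- regime[ci]
      eta <- alpha[[r]] + u[ci] +
        (sex == "male") * config$sex_gap +
        beta[[r]] * kappa[[r]][ti] +
        stats::rnorm(length(x), 0, config$noise_sd)
      tibble::tibble(
        country = country[ci], code = code[ci], sex = sex,
        period_start = config$periods[ti],
        age_start = grid$age_start,
        age_span = grid$age_span,
        qx = c(inv_logit(eta), 1)
      )
    })
    panel <- validate_panel(purrr::list_rbind(rows))
    truth <- list(
      regimes = tibble::tibble(country = country, code = code,
                               regime = regime, u = u),
      alpha = alpha, beta = beta, kappa = kappa,
      levels = levels, config = config
    )
    list(panel = panel, truth = truth)
  })
}

#' Write a named synthetic fixture to disk
#'
#' Writes a canonical abridged CSV plus a `*_truth.csv` sidecar with the
#' planted regime labels. `"tiny"` is 2 regimes x 3 countries x 3 periods,
#' `"default"` is the full [synthetic_config()] default, `"stress"` has
#' overlapping regimes and high noise.
#'
#' @param name One of `"tiny"`, `"default"`, `"stress"`.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the generator.
#' @return Invisibly, paths to the panel and truth CSVs.
#' @export
write_fixture <- function(name = c("tiny", "default", "stress"), dir,
                          seed = 1L) {
  name <- match.arg(name)
  config <- switch(name,
    tiny = synthetic_config(n_regimes = 2L, countries_per_regime = 3L,
                            periods = seq(1990L, 2000L, by = 5L), seed = seed),
    default = synthetic_config(seed = seed),
    stress = synthetic_config(regime_separation = 0.2, noise_sd = 0.3,
                              country_effect_sd = 0.3, seed = seed)
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_panel(config)
  panel_path <- file.path(dir, sprintf("%s_panel.csv", name))
  truth_path <- file.path(dir, sprintf("%s_truth.csv", name))
  write_abridged_csv(sim$panel, panel_path)
  readr::write_csv(sim$truth$regimes, truth_path, progress = FALSE)
  invisible(c(panel = panel_path, truth = truth_path))
}
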