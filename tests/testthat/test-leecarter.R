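test_that("noise-free generative data is recovered exactly up to constraints", {
  sim <- generate_panel(synthetic_config(
    n_regimes = 2L, countries_per_regime = 2L, noise_sd = 0,
    country_effect_sd = 0, seed = 4L))
  fit <- lc_fit(sim$panel, "Country_001", "female")
  r <- sim$truth$regimes$regime[sim$truth$regimes$country == "Country_001"]
  expect_equal(fit$alpha, sim$truth$alpha[[r]], tolerance = 1e-6)
  expect_equal(fit$beta, sim$truth$beta[[r]], tolerance = 1e-6)
  expect_equal(fit$kappa, sim$truth$kappa[[r]], tolerance = 1e-6)
})

test_that("fits honour the identifiability constraints", {
  sim <- generate_panel(synthetic_config(n_regimes = 2L, countries_per_regime = 2L,
                                         seed = 6L))
  for (cn in c("Country_001", "Country_003")) {
    fit <- lc_fit(sim$panel, cn, "male")
    expect_equal(sum(fit$beta), 1, tolerance = 1e-8)
    expect_equal(sum(fit$kappa), 0, tolerance = 1e-8)
    # reconstruction stays a probability
    recon <- inv_logit(fit$alpha + outer(fit$beta, fit$kappa))
    expect_true(all(recon > 0 & recon < 1))
  }
})

test_that("rank-1 factorisation matches an independent power iteration", {
  sim <- generate_panel(synthetic_config(n_regimes = 1L, countries_per_regime = 1L,
                                         seed = 8L))
  fit <- lc_fit(sim$panel, "Country_001", "female")
  # rebuild the centered logit matrix and run power iteration independently
  sub <- sim$panel[sim$panel$country == "Country_001" &
                     sim$panel$sex == "female" &
                     sim$panel$age_span > 0, ]
  Z <- t(matrix(logit(pmin(pmax(sub$qx, 1e-7), 1 - 1e-7)),
                nrow = length(unique(sub$period_start)), byrow = TRUE))
  # rows of sub are ordered country/sex/period/age: one period per block
  Zc <- Z - rowMeans(Z)
  v <- stats::rnorm(ncol(Zc))
  for (i in 1:500) {
    u <- Zc %*% v; u <- u / sqrt(sum(u^2))
    v <- t(Zc) %*% u; v <- v / sqrt(sum(v^2))
  }
  u <- as.numeric(Zc %*% v)
  beta_pi <- u / sum(u)
  kappa_pi <- as.numeric(t(Zc) %*% (u / sqrt(sum(u^2)))) * sum(u) / sqrt(sum(u^2))
  expect_equal(fit$beta, beta_pi, tolerance = 1e-8)
  expect_equal(fit$kappa, kappa_pi, tolerance = 1e-6)
  # rank-1 optimality sanity floor: no random rank-1 candidate does better
  rss_fit <- sum((Zc - outer(fit$beta, fit$kappa))^2)
  set.seed(12)
  for (i in 1:100) {
    b <- stats::rnorm(nrow(Zc)); b <- b / sum(b)
    k <- stats::rnorm(ncol(Zc)); k <- k - mean(k)
    expect_gte(sum((Zc - outer(b, k))^2), rss_fit - 1e-10)
  }
})

test_that("a uniform logit shift moves alpha only", {
  sim <- generate_panel(synthetic_config(n_regimes = 1L, countries_per_regime = 1L,
                                         seed = 10L))
  fit1 <- lc_fit(sim$panel, "Country_001", "female")
  shifted <- sim$panel
  closed <- shifted$age_span > 0
  shifted$qx[closed] <- inv_logit(logit(shifted$qx[closed]) + 0.7)
  fit2 <- lc_fit(shifted, "Country_001", "female")
  expect_equal(fit2$alpha, fit1$alpha + 0.7, tolerance = 1e-9)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-9)
  expect_equal(fit2$kappa, fit1$kappa, tolerance = 1e-9)
})

test_that("kappa extrapolation reduces to random walk with drift on short series", {
  kf <- lc_forecast_kappa(c(10, 8, 6, 4, 2, 0), horizon = 2)
  expect_equal(kf$order, c(0L, 1L, 0L))
  expect_true(kf$drift)
  expect_equal(unname(kf$coef["drift"]), -2)
  expect_equal(kf$forecast, c(-2, -4))
  # constant kappa: zero drift, flat forecast
  kf0 <- lc_forecast_kappa(rep(1.5, 6), horizon = 3)
  expect_equal(kf0$forecast, rep(1.5, 3))
})

test_that("order selection on long AR(1) series beats the drift model one step ahead", {
  set.seed(123)
  n <- 200
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  kf <- lc_forecast_kappa(x, horizon = 1)
  mse_selected <- mean(kf$resid^2)
  mse_drift <- mean((diff(x) - mean(diff(x)))^2)
  expect_lt(mse_selected, mse_drift)
})

test_that("forecast probabilities are valid and reproduce fitted periods", {
  sim <- generate_panel(synthetic_config(n_regimes = 2L, countries_per_regime = 2L,
                                         seed = 13L))
  fit <- lc_fit(sim$panel, "Country_002", "male")
  # plugging a fitted kappa back in reproduces the fitted surface
  fq <- lc_forecast_q(fit, fit$kappa[3])
  recon <- inv_logit(fit$alpha + fit$beta * fit$kappa[3])
  expect_equal(fq$qx[fq$age_span > 0], recon, tolerance = 1e-12)
  # declining kappa with positive beta lowers q at every age
  kf <- lc_forecast_kappa(fit, 3)
  fq3 <- lc_forecast_q(fit, kf)
  expect_true(all(fq3$qx > 0 & fq3$qx <= 1))
  expect_equal(sort(unique(fq3$period_start)), c(2020, 2025, 2030))
  if (all(fit$beta >= 0) && all(diff(kf$forecast) < 0)) {
    wide <- tidyr::pivot_wider(fq3[fq3$age_span > 0, c("age_start", "period_start", "qx")],
                               names_from = "period_start", values_from = "qx")
    expect_true(all(wide[["2025"]] <= wide[["2020"]]))
    expect_true(all(wide[["2030"]] <= wide[["2025"]]))
  }
})

test_that("noisy drift recovery has small error and panel projection improves e0", {
  set.seed(31)
  cfg <- synthetic_config(n_regimes = 1L, countries_per_regime = 1L,
                          noise_sd = 0.05, country_effect_sd = 0,
                          drift_per_period = -1.2)
  errs <- replicate(50, {
    cfg$seed <- sample.int(1e6, 1)
    sim <- generate_panel(cfg)
    fit <- lc_fit(sim$panel, "Country_001", "female")
    kf <- lc_forecast_kappa(fit, 1)
    abs(unname(kf$coef["drift"]) - (-1.2))
  })
  expect_lt(mean(errs), 0.12) # < 10% of the true drift magnitude
  # improvement propagates: 2030 forecast e0 exceeds fitted 2015 e0
  sim <- generate_panel(synthetic_config(n_regimes = 2L, countries_per_regime = 2L,
                                         seed = 17L))
  proj <- lc_project_panel(sim$panel, 3)
  for (cn in unique(proj$country)) for (sx in c("female", "male")) {
    e2015 <- life_table(proj[proj$country == cn & proj$sex == sx &
                               proj$period_start == 2015, ])$ex[1]
    e2030 <- life_table(proj[proj$country == cn & proj$sex == sx &
                               proj$period_start == 2030, ])$ex[1]
    expect_gt(e2030, e2015)
  }
})

test_that("tidy and glance expose the fit in broom style", {
  sim <- generate_panel(synthetic_config(n_regimes = 1L, countries_per_regime = 1L,
                                         seed = 20L))
  fit <- lc_fit(sim$panel, "Country_001", "male")
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("alpha", "beta", "kappa"))
  expect_equal(nrow(td), 2 * sum(fit$grid$age_span > 0) + length(fit$kappa))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$sv_share, 0.5)
})
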