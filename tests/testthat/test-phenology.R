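step_series <- function(step_day, before = 0.3, after = 10, days = 120) {
  tibble::tibble(doy = rep(1:days, each = 24) + rep(0:23, days) / 24,
                 temperature = ifelse(rep(1:days, each = 24) >= step_day,
                                      after, before))
}

test_that("snowmelt detection follows the step and persistence rules", {
  expect_equal(detect_snowmelt(step_series(40)), 40)

  # programmed melt recovered on a noiseless generated series
  for (melt in c(147, 157, 185)) {
    tt <- gen_temperature(2020, melt, seed = 3, noise_sd = 0)
    expect_equal(detect_snowmelt(tt), melt)
  }

  # a 1-day warm spike before the true melt is ignored
  sp <- step_series(60)
  spike_days <- sp$doy >= 30 & sp$doy < 31
  sp$temperature[spike_days] <- 12
  expect_equal(detect_snowmelt(sp), 60)

  never <- tibble::tibble(doy = rep(1:100, each = 24) + rep(0:23, 100) / 24,
                          temperature = 0.3)
  expect_error(detect_snowmelt(never), "no snowmelt")
})

test_that("degree hours sum hourly excess over the base temperature", {
  t24 <- tibble::tibble(doy = 100 + (0:23) / 24, temperature = 15)
  expect_equal(compute_gdh(t24, 100, 101), 240)

  cold <- tibble::tibble(doy = 100 + (0:47) / 24, temperature = 5)
  expect_equal(compute_gdh(cold, 100, 102), 0)

  piece <- tibble::tibble(doy = 100 + (0:21) / 24,
                          temperature = c(rep(6, 10), rep(4, 10), rep(20, 2)))
  expect_equal(compute_gdh(piece, 100, 101), 10 + 0 + 30)

  # brute-force oracle on a randomized series
  set.seed(13)
  rnd <- tibble::tibble(doy = 150 + (0:499) / 24,
                        temperature = runif(500, -2, 25))
  sel <- rnd$doy >= 155 & rnd$doy < 165
  expect_equal(compute_gdh(rnd, 155, 165),
               sum(pmax(rnd$temperature[sel] - 5, 0)))
  expect_equal(compute_gdh(rnd, 155, 165, count_hours = TRUE),
               sum(rnd$temperature[sel] > 5))
  expect_warning(z <- compute_gdh(rnd, 10, 11), "empty")
  expect_equal(z, 0)
})

test_that("leaf baseline padding inserts ten 0.5 cm anchors once", {
  leaf <- tibble::tibble(doy = seq(160, 220, by = 7),
                         value = seq(1, 12, length.out = 9),
                         variable = "leaf")
  padded <- pad_leaf_baseline(leaf, snowmelt_doy = 158)
  expect_equal(nrow(padded), nrow(leaf) + 10)
  expect_equal(sum(padded$doy == 158 & padded$value == 0.5), 10)
  expect_error(pad_leaf_baseline(padded, 158), "already")

  root <- tibble::tibble(doy = 1:9, value = 1:9, variable = "root")
  expect_error(pad_leaf_baseline(root, 158), "leaf")

  # padded fit anchors near 0.5 at snowmelt on noiseless data
  leaf2 <- tibble::tibble(doy = seq(160, 230, by = 7),
                          value = 14 / (1 + exp(-0.2 * (seq(160, 230, by = 7) - 180))),
                          variable = "leaf")
  fit <- fit_growth_spline(pad_leaf_baseline(leaf2, 158))
  expect_lt(abs(predict(fit, doy = 158) - 0.5), 0.3)
})

test_that("growth spline reproduces linear and logistic trends", {
  lin <- tibble::tibble(doy = seq(100, 170, by = 7),
                        value = 2 * (seq(100, 170, by = 7) - 100))
  f <- fit_growth_spline(lin)
  grid <- 100:170
  expect_lt(max(abs(predict(f, grid) - 2 * (grid - 100))) / 140, 0.01)

  t <- seq(0, 98, by = 7)
  tru <- 40 / (1 + exp(-0.15 * (t - 25)))
  f2 <- fit_growth_spline(tibble::tibble(doy = 150 + t, value = tru))
  g2 <- seq(150, 248, by = 1)
  tru_g <- 40 / (1 + exp(-0.15 * (g2 - 150 - 25)))
  expect_lt(max(abs(predict(f2, g2) - tru_g)), 0.03 * 40)

  expect_error(fit_growth_spline(lin[1:5, ]), "fewer than 6")
})

test_that("duplicating every observation leaves the spline unchanged", {
  set.seed(14)
  t <- seq(0, 98, by = 7)
  y <- 40 / (1 + exp(-0.15 * (t - 25))) + rnorm(length(t), 0, 2)
  d1 <- tibble::tibble(doy = t, value = y)
  d2 <- dplyr::bind_rows(d1, d1)
  p1 <- predict(fit_growth_spline(d1), 0:98)
  p2 <- predict(fit_growth_spline(d2), 0:98)
  expect_lt(max(abs(p1 - p2)) / max(abs(p1)), 1e-6)
})

test_that("threshold extraction matches closed forms", {
  flat_temps <- tibble::tibble(doy = rep(1:365, each = 24) + rep(0:23, 365) / 24,
                               temperature = 15)
  # linear rise 0 -> 100 over days 0..50: t20 = 10, t80 = 40
  lin <- tibble::tibble(doy = seq(0, 50, by = 5),
                        value = 2 * seq(0, 50, by = 5))
  sm <- fit_growth_spline(lin)
  th <- extract_thresholds(sm, flat_temps, snowmelt_doy = 0)
  expect_equal(th$t20_doy, 10, tolerance = 0.3)
  expect_equal(th$t80_doy, 40, tolerance = 0.3)
  # GDH at crossing: 10 deg excess * 24 h * t
  expect_equal(th$t80_gdh, 240 * th$t80_doy, tolerance = 241)

  # noiseless logistic: crossings within a day of the analytic inverse
  t <- seq(0, 98, by = 7)
  L <- 40; k <- 0.15; m <- 25
  logi <- function(x) L / (1 + exp(-k * (x - m)))
  val <- logi(t) - logi(0)
  sm2 <- fit_growth_spline(tibble::tibble(doy = t, value = val))
  th2 <- extract_thresholds(sm2, flat_temps, snowmelt_doy = 0,
                            first_value = 0, amplitude_at = "end")
  amp <- logi(98) - logi(0)
  inv <- function(f) m + log((L / (logi(0) + f * amp)) - 1) / -k
  expect_lt(abs(th2$t20_doy - inv(0.2)), 1)
  expect_lt(abs(th2$t80_doy - inv(0.8)), 1)
  expect_equal(th2$rate_per_gdh, 0.8 * th2$amplitude / th2$t80_gdh)

  # constant series: flagged undefined
  const <- tibble::tibble(doy = seq(0, 70, by = 7), value = 5)
  smc <- fit_growth_spline(const)
  expect_warning(thc <- extract_thresholds(smc, flat_temps, 0), "amplitude")
  expect_true(is.na(thc$t20_doy) && is.na(thc$t80_doy))
})

test_that("thresholds are ordered and shift equivariant", {
  flat_temps <- tibble::tibble(doy = rep(1:365, each = 24) + rep(0:23, 365) / 24,
                               temperature = 12)
  t <- seq(0, 98, by = 7)
  logi <- function(x) 40 / (1 + exp(-0.15 * (x - 25)))
  th_at <- function(shift) {
    sm <- fit_growth_spline(tibble::tibble(doy = 150 + shift + t,
                                           value = logi(t) - logi(0)))
    extract_thresholds(sm, flat_temps, snowmelt_doy = 150 + shift,
                       first_value = 0, amplitude_at = "end")
  }
  base <- th_at(0)
  expect_lte(base$t20_doy, base$t80_doy)
  expect_lte(base$t20_gdh, base$t80_gdh)
  for (shift in c(5, 11)) {
    th <- th_at(shift)
    expect_lte(th$t20_doy, th$t80_doy)
    # pure time shift moves crossings by exactly the shift (same grid)
    expect_equal(th$t20_doy - base$t20_doy, shift, tolerance = 1e-6)
    expect_equal(th$t80_doy - base$t80_doy, shift, tolerance = 1e-6)
  }
})

test_that("rate per GDH is invariant under a pure time shift", {
  flat_temps <- tibble::tibble(doy = rep(1:365, each = 24) + rep(0:23, 365) / 24,
                               temperature = 12)
  t <- seq(0, 98, by = 7)
  logi <- function(x) 40 / (1 + exp(-0.15 * (x - 25)))
  rates <- vapply(c(0, 7), function(shift) {
    sm <- fit_growth_spline(tibble::tibble(doy = 150 + shift + t,
                                           value = logi(t) - logi(0)))
    extract_thresholds(sm, flat_temps, snowmelt_doy = 150 + shift,
                       first_value = 0, amplitude_at = "end")$rate_per_gdh
  }, numeric(1))
  expect_lt(abs(rates[2] - rates[1]) / rates[1], 0.01)
})
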