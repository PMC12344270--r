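test_that("experiment design expands to the full factorial", {
  d <- experiment_design()
  p <- design_plots(d)
  expect_equal(nrow(p), 45)
  expect_equal(nrow(p) * d$tubes_per_plot, 90)
  expect_equal(nrow(dplyr::distinct(p, .data$snow, .data$drought)), 9)
  counts <- dplyr::count(p, .data$snow, .data$drought)
  expect_true(all(counts$n == 5))
})

test_that("treatment effects validate their ranges", {
  expect_error(treatment_effects(drought_early_multiplier = -1), "positive")
  expect_error(treatment_effects(winter_loss_fraction = c(control = 1.2, `5wk` = 0.1, `10wk` = 0.1)),
               "loss")
  expect_error(treatment_effects(noise_sd_fraction = -0.1), "noise")
})

test_that("temperature series has the winter plateau and is reproducible", {
  tt <- gen_temperature(2020, 157, seed = 21)
  winter <- tt$temperature[tt$doy < 150]
  expect_equal(mean(winter), 0.3, tolerance = 0.02)
  expect_lt(sd(winter), 0.1)

  tt2 <- gen_temperature(2020, 157, seed = 21)
  expect_identical(tt, tt2)
  expect_false(identical(tt, gen_temperature(2020, 157, seed = 22)))

  mid <- tt$temperature[tt$doy >= 200 & tt$doy < 230]
  expect_gt(mean(mid), 10); expect_lt(mean(mid), 14)

  expect_error(gen_temperature(2020, 400, seed = 1), "day of year")
})

test_that("growth curves honour multipliers and the logistic closed form", {
  # all multipliers 1, no noise: observations sit on the curve and the
  # empirical crossings match the analytic ones within a scan interval
  eff1 <- treatment_effects(drought_early_multiplier = 1,
                            drought_late_multiplier = 1,
                            rewet_multiplier = 1, noise_sd_fraction = 0)
  g <- gen_growth_curve(drought = "5wk", effects = eff1, seed = 23,
                        snowmelt_doy = 150)
  expect_equal(g$observations$value, g$observations$noise_free)
  obs <- g$observations
  amp <- max(obs$value) - obs$value[1]
  emp_t20 <- obs$doy[which(obs$value >= obs$value[1] + 0.2 * amp)[1]]
  expect_lte(abs(emp_t20 - g$curve$true_t20), 7)

  # closed-form inverse of the pure logistic L/(1+e^(-k(t-m)))
  L <- 40; k <- 0.15; m <- 25
  logi <- function(x) L / (1 + exp(-k * (x - m)))
  gc <- gen_growth_curve(drought = "control", effects = eff1, seed = 1,
                         snowmelt_doy = 0, season_length_days = 98,
                         max_length = L, growth_rate = k, midpoint_day = m)
  amp_t <- logi(98) - logi(0)
  inv <- function(f) m + log(L / (logi(0) + f * amp_t) - 1) / -k
  expect_equal(gc$curve$true_t20, inv(0.2), tolerance = 0.1)
  expect_equal(gc$curve$true_t80, inv(0.8), tolerance = 0.1)

  # early multiplier 1.19 scales the week 0-5 gain by exactly 1.19
  eff <- treatment_effects(noise_sd_fraction = 0)
  g_ctrl <- gen_growth_curve("control", eff, seed = 2, snowmelt_doy = 150,
                             drought_start_doy = 150)
  g_dr <- gen_growth_curve("5wk", eff, seed = 2, snowmelt_doy = 150,
                           drought_start_doy = 150)
  gain_ctrl <- g_ctrl$curve$value(185) - g_ctrl$curve$value(150)
  gain_dr <- g_dr$curve$value(185) - g_dr$curve$value(150)
  expect_equal(gain_dr / gain_ctrl, 1.19, tolerance = 1e-3)

  expect_error(gen_growth_curve(max_length = -1), "positive")
})

test_that("curves are season-relative, non-decreasing, with ordered thresholds", {
  for (s in 1:5) {
    g <- gen_growth_curve(drought = sample(c("control", "5wk", "10wk"), 1),
                          seed = s, snowmelt_doy = 150)
    expect_equal(g$curve$value(150), 0)
    grid <- seq(150, g$curve$end_doy, by = 0.5)
    expect_true(all(diff(g$curve$value(grid)) >= -1e-9))
    expect_lte(g$curve$true_t20, g$curve$true_t80)
  }
})

test_that("image sequences are deterministic with consistent ground truth", {
  curve <- gen_growth_curve(drought = "control", seed = 24)$curve
  geom <- synth_tube_geometry()
  s1 <- gen_image_sequence(geom, curve, seed = 25)
  s2 <- gen_image_sequence(geom, curve, seed = 25)
  expect_identical(unclass(s1$scans[[8]]$upper), unclass(s2$scans[[8]]$upper))
  expect_identical(unclass(s1$scans[[8]]$truth), unclass(s2$scans[[8]]$truth))

  # per-date true lengths are non-decreasing within the season and equal
  # the curve value times the image area
  tru <- vapply(s1$scans, function(x) {
    x$truth_lengths$length_mm[x$truth_lengths$layer == "total"]
  }, numeric(1))
  expect_true(all(diff(tru) >= -1e-6))
  area <- image_area_cm2(geom)
  doys <- vapply(s1$scans, `[[`, numeric(1), "doy")
  expect_equal(tru, curve$value(doys) * area, tolerance = 0.01)

  # mask monotonicity: earlier strand sets are (near-)subsets of later
  # ones; only the frontier cap of the partially revealed strand may
  # differ by a few boundary pixels
  lost <- sum(s1$scans[[5]]$truth == 1L & s1$scans[[10]]$truth == 0L)
  expect_lte(lost, 40)

  # zero-area geometries are rejected at construction
  expect_error(tube_geometry(angle_deg = 45, tape_rows = 0, dpi = 600,
                             image_rows = 0, image_cols = 100), "positive")
})

test_that("oracle masks recover the analytic lengths within 5%", {
  for (sd_ in c(101, 202)) {
    curve <- gen_growth_curve(drought = "control", seed = sd_)$curve
    geom <- synth_tube_geometry()
    sq <- gen_image_sequence(geom, curve, seed = sd_ + 1,
                             degradations = degradation_params(FALSE, FALSE, FALSE))
    for (i in c(4, 8, 15)) {
      tru <- sq$scans[[i]]$truth_lengths$length_mm[3]
      if (tru < 2) next
      est <- skeletonize_and_measure(sq$scans[[i]]$truth)$length_mm
      expect_lt(abs(est - tru) / tru, 0.05)
    }
  }
})

test_that("winter pruning drops whole strands to the exact target", {
  curve <- gen_growth_curve(drought = "control", seed = 26)$curve
  geom <- synth_tube_geometry()
  sq <- gen_image_sequence(geom, curve, seed = 27)
  st0 <- sum(vapply(sq$state$revealed, function(s) s$total, numeric(1)))
  pr <- winter_prune_strands(sq$state, 0.15, seed = 28)
  expect_equal(pr$standing_px, 0.85 * st0, tolerance = 1e-9)
  # deterministic given seed
  pr2 <- winter_prune_strands(sq$state, 0.15, seed = 28)
  expect_identical(pr$standing_px, pr2$standing_px)
  expect_error(winter_prune_strands(sq$state, 1.1), "loss_fraction")
})

test_that("cohorts are fully determined by design and seed", {
  des <- experiment_design(n_blocks = 2, snow_levels = c("control", "removal"),
                           drought_levels = c("control", "10wk"),
                           tubes_per_plot = 1, seasons = 2020)
  c1 <- gen_cohort(des, seed = 29, include_temperature = FALSE)
  c2 <- gen_cohort(des, seed = 29, include_temperature = FALSE)
  expect_identical(c1$series, c2$series)
  expect_identical(c1$truth, c2$truth)
  c3 <- gen_cohort(des, seed = 30, include_temperature = FALSE)
  expect_false(identical(c1$series$value, c3$series$value))

  # snow removal advances the melt date, addition would delay it
  melts <- dplyr::summarise(dplyr::group_by(c1$truth, .data$snow),
                            m = mean(.data$snowmelt_doy))
  expect_lt(melts$m[melts$snow == "removal"], melts$m[melts$snow == "control"])
})
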