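#' Generate a plot's true root growth curve and noisy weekly observations
#'
#' The noiseless truth is a saturating (logistic-family) cumulative root
#' length curve, expressed relative to the snowmelt date (value 0 at
#' snowmelt, the convention for root series). Treatment effects enter as
#' multipliers on the growth *rate* within their windows: the early-drought
#' multiplier over days `[drought_start, drought_start + 35)` for both
#' drought arms, the late multiplier over `[+35, +70)` for the 10-wk arm,
#' and the rewetting multiplier for `rewet_window_days` after shelter
#' removal. Observations sample the curve at the scan dates with i.i.d.
#' Gaussian noise of sd `noise_sd_fraction * true_max`.
#'
#' Ground-truth `t20`/`t80` are the exact crossing times of 20%/80% of the
#' seasonal amplitude on the noiseless curve (solved on a fine grid with
#' linear interpolation).
#'
#' @param drought drought level: `"control"`, `"5wk"` or `"10wk"`.
#' @param effects a [treatment_effects()] list.
#' @param seed RNG seed for the observation noise.
#' @param snowmelt_doy snowmelt day of year.
#' @param drought_start_doy shelter placement day (default snowmelt + 7).
#' @param season_length_days days from snowmelt to the last scan.
#' @param scan_interval_days days between scans.
#' @param max_length seasonal asymptote of the base logistic
#'   (mm cm^-2; the field peak-year community mean is ~40).
#' @param growth_rate,midpoint_day logistic rate (per day) and midpoint
#'   (days after snowmelt).
#' @param carry standing root length carried over from previous seasons
#'   (added to observations, not to the season-relative truth).
#' @return A list with `curve` (a `growth_curve`: `value(t)` function of
#'   DOY, `true_t20`, `true_t80`, `true_max`, window bookkeeping) and
#'   `observations` (tibble `doy`, `value`, `noise_free`).
#' @export
gen_growth_curve <- function(drought = "control",
                             effects = treatment_effects(),
                             seed = 1,
                             snowmelt_doy = 157,
                             drought_start_doy = snowmelt_doy + 7,
                             season_length_days = 98,
                             scan_interval_days = 7,
                             max_length = 40,
                             growth_rate = 0.15,
                             midpoint_day = 25,
                             carry = 0) {
  if (max_length <= 0 || growth_rate <= 0) {
    stop("`max_length` and `growth_rate` must be positive", call. = FALSE)
  }
  end_doy <- snowmelt_doy + season_length_days
  mult_fun <- rate_multiplier_fun(drought, effects, snowmelt_doy,
                                  drought_start_doy)
  # integrate rate = base logistic derivative x window multiplier
  dt <- 0.05
  tg <- seq(snowmelt_doy, end_doy, by = dt)
  sig <- 1 / (1 + exp(-growth_rate * (tg - snowmelt_doy - midpoint_day)))
  rate <- max_length * growth_rate * sig * (1 - sig) * mult_fun(tg)
  cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  value_fun <- approxfun(tg, cum, rule = 2)
  true_max <- cum[length(cum)]
  crossing <- function(f) {
    i <- which(cum >= f * true_max)[1]
    if (i <= 1) return(tg[1])
    # linear interpolation between grid points for the exact crossing
    t0 <- tg[i - 1]; t1 <- tg[i]; c0 <- cum[i - 1]; c1 <- cum[i]
    t0 + (f * true_max - c0) / (c1 - c0) * (t1 - t0)
  }
  curve <- structure(list(value = value_fun,
                          true_t20 = crossing(0.2),
                          true_t80 = crossing(0.8),
                          true_max = true_max,
                          snowmelt_doy = snowmelt_doy,
                          drought_start_doy = drought_start_doy,
                          end_doy = end_doy, drought = drought,
                          carry = carry),
                     class = "growth_curve")
  scan_doy <- seq(snowmelt_doy, end_doy, by = scan_interval_days)
  noise_free <- carry + value_fun(scan_doy)
  noise_sd <- effects$noise_sd_fraction * true_max
  obs <- withr::with_seed(seed, {
    noise_free + rnorm(length(scan_doy), 0, noise_sd)
  })
  list(curve = curve,
       observations = tibble::tibble(doy = scan_doy, value = obs,
                                     noise_free = noise_free))
}

# growth-rate multiplier as a function of DOY for one drought level
rate_multiplier_fun <- function(drought, effects, snowmelt_doy,
                                drought_start_doy) {
  ds <- drought_start_doy
  early <- c(ds, ds + 35)
  late <- c(ds + 35, ds + 70)
  rw <- effects$rewet_window_days
  function(t) {
    m <- rep(1, length(t))
    if (drought %in% c("5wk", "10wk")) {
      m[t >= early[1] & t < early[2]] <- effects$drought_early_multiplier
    }
    if (drought == "10wk") {
      m[t >= late[1] & t < late[2]] <- effects$drought_late_multiplier
      m[t >= late[2] & t < late[2] + rw] <- effects$rewet_multiplier
    }
    if (drought == "5wk") {
      m[t >= early[2] & t < early[2] + rw] <- effects$rewet_multiplier
    }
    m
  }
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "<growth_curve> %s: max %.2f mm cm^-2, t20 DOY %.1f, t80 DOY %.1f\n",
    x$drought, x$true_max, x$true_t20, x$true_t80))
  invisible(x)
}
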