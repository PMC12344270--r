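#' Generate an hourly topsoil temperature series
#'
#' Emulates a 3--4 cm depth soil-temperature logger under alpine snow
#' cover: a constant 0.3 degC winter plateau (the snowpack insulates the
#' soil) with tiny jitter, then -- once the snow is gone -- a diurnal
#' sinusoid around a seasonal mean that starts near 6 degC at melt-out,
#' peaks around 12.5 degC in mid season and declines through autumn,
#' returning to the plateau at snow-in. Deterministic given the seed.
#'
#' @param season year label (drives nothing but the output label).
#' @param snowmelt_day snowmelt day of year (1--365).
#' @param seed RNG seed.
#' @param season_end_doy day of snow-in (return to plateau), default 300.
#' @param plateau_c winter plateau temperature (default 0.3 degC).
#' @param melt_mean_c,peak_mean_c seasonal-mean daily temperature at
#'   melt-out and mid season.
#' @param diurnal_amplitude_c half-range of the diurnal cycle (default 2.5).
#' @param noise_sd day-to-day random deviation of the daily mean (degC).
#' @return Tibble with `season`, `doy` (fractional, hourly) and
#'   `temperature`.
#' @export
gen_temperature <- function(season, snowmelt_day, seed,
                            season_end_doy = 300, plateau_c = 0.3,
                            melt_mean_c = 6, peak_mean_c = 12.5,
                            diurnal_amplitude_c = 2.5, noise_sd = 0.2) {
  if (!is.numeric(snowmelt_day) || snowmelt_day < 1 || snowmelt_day > 365) {
    stop("`snowmelt_day` must be a day of year within the year",
         call. = FALSE)
  }
  if (snowmelt_day >= season_end_doy) {
    stop("`snowmelt_day` must precede `season_end_doy`", call. = FALSE)
  }
  hours <- seq(0, 365 * 24 - 1)
  doy <- 1 + hours / 24
  day <- floor(doy)
  hod <- hours %% 24
  L <- season_end_doy - snowmelt_day
  u <- (day - snowmelt_day) / L
  seasonal <- ifelse(day >= snowmelt_day & day < season_end_doy,
                     melt_mean_c + (peak_mean_c - melt_mean_c) *
                       sin(pi * pmin(pmax(u, 0), 1)),
                     plateau_c)
  withr::with_seed(seed, {
    daily_dev <- rnorm(365, 0, noise_sd)
    jitter_winter <- rnorm(365, 0, 0.02)
  })
  dev <- ifelse(day >= snowmelt_day & day < season_end_doy,
                daily_dev[day], jitter_winter[day])
  diurnal <- ifelse(day >= snowmelt_day & day < season_end_doy,
                    diurnal_amplitude_c * sin(2 * pi * (hod - 9) / 24), 0)
  tibble::tibble(season = season, doy = doy,
                 temperature = seasonal + dev + diurnal)
}
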