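#' Detect snowmelt date from topsoil temperature
#'
#' Under a closed snowpack the topsoil sits at a constant ~0.3 degC; once
#' the snow is gone the diurnal signal appears and daily means rise.
#' Snowmelt is declared on the first day whose trailing 3-day running mean
#' of daily mean temperature exceeds 2 degC, provided the series never
#' afterwards returns below 1 degC for 5 or more consecutive days (which
#' would indicate a transient warm spell before the true melt-out).
#'
#' @param temps tibble with columns `doy` (fractional day of year, hourly
#'   resolution) and `temperature` (degC at 3--4 cm depth), as produced by
#'   [gen_temperature()] or read from sensor CSVs.
#' @param run_mean_days window of the trailing running mean (days).
#' @param melt_threshold running-mean threshold (degC) declaring melt.
#' @param refreeze_threshold,refreeze_run returning below
#'   `refreeze_threshold` for at least `refreeze_run` consecutive days
#'   disqualifies an earlier candidate.
#' @param persistence_days how far ahead (days) the no-refreeze condition
#'   is enforced; beyond it the ordinary autumn cool-down is allowed.
#' @return Snowmelt day of year (integer).
#' @export
detect_snowmelt <- function(temps, run_mean_days = 3, melt_threshold = 2,
                            refreeze_threshold = 1, refreeze_run = 5,
                            persistence_days = 60) {
  stopifnot(all(c("doy", "temperature") %in% names(temps)))
  day <- floor(temps$doy)
  daily <- tapply(temps$temperature, day, mean)
  days <- as.integer(names(daily))
  dm <- as.numeric(daily)
  n <- length(dm)
  if (n < run_mean_days) stop("temperature series too short", call. = FALSE)
  rm3 <- vapply(seq_len(n), function(i) {
    mean(dm[max(1, i - run_mean_days + 1):i])
  }, numeric(1))
  cold <- rm3 < refreeze_threshold
  # length of the cold run starting at each index
  run_ahead <- rev(Reduce(function(acc, x) if (x) acc + 1 else 0,
                          rev(cold), accumulate = TRUE))
  candidates <- which(rm3 > melt_threshold)
  for (i in candidates) {
    horizon <- seq(i, min(i + persistence_days - 1, n))
    in_horizon <- pmin(run_ahead[horizon], i + persistence_days - horizon)
    if (all(in_horizon < refreeze_run)) return(days[i])
  }
  stop("no snowmelt detected: series never leaves the winter plateau",
       call. = FALSE)
}

#' Growing degree hours above a base temperature
#'
#' Thermal time as the hourly sum of `max(T - base, 0)` between two days
#' of year (inclusive window start, exclusive end). Setting
#' `count_hours = TRUE` instead counts hours with `T > base`, the
#' alternative reading of a "GDH > 5 degC" heat sum.
#'
#' @param temps tibble with `doy` and `temperature` columns.
#' @param from_doy,to_doy accumulation window.
#' @param base base temperature in degC (default 5).
#' @param count_hours if `TRUE`, count hours above `base` instead of
#'   summing excess degrees.
#' @return Degree-hours (or hours) as a single number.
#' @examples
#' temps <- tibble::tibble(doy = 100 + (0:23) / 24, temperature = 15)
#' compute_gdh(temps, 100, 101)  # 24 h x 10 degC = 240
#' @export
compute_gdh <- function(temps, from_doy, to_doy, base = 5,
                        count_hours = FALSE) {
  sel <- temps$doy >= from_doy & temps$doy < to_doy
  if (!any(sel)) {
    warning("empty GDH window: returning 0")
    return(0)
  }
  x <- temps$temperature[sel]
  if (count_hours) sum(x > base) else sum(pmax(x - base, 0))
}

#' Pad a leaf growth series with its snowmelt baseline
#'
#' Leaf lengths at the day of snowmelt are set to 0.5 cm by inserting 10
#' observations of 0.5 cm at the snowmelt date, anchoring the spline fit
#' at the known post-melt starting length. Root series (which are
#' expressed relative to the first scan of the season) must not be padded.
#'
#' @param series growth tibble with at least `doy`, `value` and `variable`
#'   columns; `variable` must be `"leaf"`.
#' @param snowmelt_doy day of year of snowmelt.
#' @param baseline_cm baseline leaf length (default 0.5).
#' @param n_pad number of inserted observations (default 10).
#' @return The padded tibble, flagged so repeated padding is refused.
#' @export
pad_leaf_baseline <- function(series, snowmelt_doy, baseline_cm = 0.5,
                              n_pad = 10) {
  stopifnot(all(c("doy", "value") %in% names(series)))
  if (!is.null(series$variable) && !all(series$variable == "leaf")) {
    stop("baseline padding applies to leaf series only", call. = FALSE)
  }
  if (isTRUE(attr(series, "baseline_padded"))) {
    stop("series is already baseline-padded", call. = FALSE)
  }
  pad <- series[rep(1L, n_pad), , drop = FALSE]
  pad$doy <- snowmelt_doy
  pad$value <- baseline_cm
  out <- dplyr::arrange(dplyr::bind_rows(pad, series), .data$doy)
  attr(out, "baseline_padded") <- TRUE
  out
}

#' Fit a penalized-spline smooth to a growth series
#'
#' One thin-plate regression spline per plot (cubic penalty, smoothing
#' parameter chosen by generalized cross-validation via mgcv), evaluable
#' on a daily grid. Replicate observations at the same day are aggregated
#' to weighted means with weights normalized to mean one, which leaves the
#' fit exactly invariant under dataset duplication.
#'
#' @param series tibble with `doy` and `value` columns; at least 6
#'   observations are required.
#' @param k basis dimension; default adapts to the number of distinct days.
#' @param gamma multiplier on the GCV model-complexity penalty. The
#'   default 0.7 deliberately smooths a little less than plain GCV:
#'   saturating growth curves have a sharp shoulder that oversmoothing
#'   rounds off, which systematically delays threshold crossings
#'   (calibrated on synthetic logistic curves; see the methods vignette).
#' @return A `growth_spline` object: the mgcv fit plus its evaluation
#'   range; supports `predict()`, [tidy()] and [glance()].
#' @export
fit_growth_spline <- function(series, k = NULL, gamma = 0.7) {
  stopifnot(all(c("doy", "value") %in% names(series)))
  ok <- is.finite(series$doy) & is.finite(series$value)
  series <- series[ok, ]
  if (nrow(series) < 6) {
    stop("fewer than 6 observations: skip threshold extraction for this plot",
         call. = FALSE)
  }
  agg <- stats::aggregate(value ~ doy, data = series, FUN = mean)
  cnt <- as.numeric(table(series$doy))
  w <- cnt / mean(cnt)
  k <- k %||% min(12L, nrow(agg) - 2L)
  if (k < 3) stop("too few distinct days for a spline basis", call. = FALSE)
  fit <- mgcv::gam(value ~ s(doy, bs = "tp", k = k), data = agg,
                   weights = w, method = "GCV.Cp", gamma = gamma)
  structure(list(fit = fit, doy_range = range(agg$doy),
                 n_obs = nrow(series), n_days = nrow(agg)),
            class = "growth_spline")
}

#' @export
predict.growth_spline <- function(object, doy = NULL, ...) {
  doy <- doy %||% seq(object$doy_range[1], object$doy_range[2], by = 1)
  as.numeric(predict(object$fit, newdata = data.frame(doy = doy)))
}

#' @export
print.growth_spline <- function(x, ...) {
  cat(sprintf("<growth_spline> %d obs over DOY %g-%g, edf %.2f\n",
              x$n_obs, x$doy_range[1], x$doy_range[2],
              sum(x$fit$edf)))
  invisible(x)
}

#' Extract 20%/80% growth thresholds from a smoothed series
#'
#' The start and end of the peak growing period are the first days on
#' which the smoothed curve surpasses 20% and 80% of the seasonal
#' amplitude (maximum value minus first value, the first value being the
#' fit at snowmelt). Crossing days are located on a daily grid; each is
#' also expressed in growing degree hours accumulated from snowmelt, and
#' a max-scaled growth rate per degree hour up to the 80% crossing is
#' reported.
#'
#' @param smooth a `growth_spline` from [fit_growth_spline()].
#' @param temps hourly temperature tibble for the GDH conversion.
#' @param snowmelt_doy day of year of snowmelt (start of the season grid).
#' @param fractions thresholds as fractions of amplitude (default 0.2, 0.8).
#' @param base GDH base temperature.
#' @param first_value baseline value; `NULL` evaluates the smooth at
#'   snowmelt. Root series are expressed relative to the first scan of
#'   the season, so their baseline is 0 by construction and should be
#'   passed explicitly.
#' @param amplitude_at `"max"` (seasonal maximum anywhere on the grid)
#'   or `"end"` (fit at the last grid day). For monotone cumulative root
#'   series the two coincide up to fit wiggle; `"end"` avoids inflating
#'   the amplitude by plateau wiggle.
#' @param grid_step evaluation grid resolution in days.
#' @return A one-row tibble: `t20_doy`, `t80_doy`, `t20_gdh`, `t80_gdh`,
#'   `first_value`, `max_value`, `amplitude`, `rate_per_gdh`. All-`NA`
#'   thresholds (with a warning) when the amplitude is not positive.
#' @export
extract_thresholds <- function(smooth, temps, snowmelt_doy,
                               fractions = c(0.2, 0.8), base = 5,
                               first_value = NULL,
                               amplitude_at = c("max", "end"),
                               grid_step = 0.25) {
  amplitude_at <- match.arg(amplitude_at)
  grid <- seq(max(snowmelt_doy, smooth$doy_range[1]), smooth$doy_range[2],
              by = grid_step)
  vals <- predict(smooth, doy = grid)
  first_value <- first_value %||% vals[1]
  max_value <- if (amplitude_at == "end") vals[length(vals)] else max(vals)
  amplitude <- max_value - first_value
  out <- tibble::tibble(t20_doy = NA_real_, t80_doy = NA_real_,
                        t20_gdh = NA_real_, t80_gdh = NA_real_,
                        first_value = first_value, max_value = max_value,
                        amplitude = amplitude, rate_per_gdh = NA_real_)
  if (!is.finite(amplitude) ||
      amplitude <= max(1e-6, 1e-6 * abs(max_value))) {
    warning("non-positive seasonal amplitude: thresholds undefined")
    return(out)
  }
  cross <- vapply(fractions, function(f) {
    i <- which(vals >= first_value + f * amplitude)[1]
    if (is.na(i)) NA_real_ else grid[i]
  }, numeric(1))
  gdh <- vapply(cross, function(d) {
    if (is.na(d)) return(NA_real_)
    compute_gdh(temps, snowmelt_doy, d, base = base)
  }, numeric(1))
  out$t20_doy <- cross[1]; out$t80_doy <- cross[2]
  out$t20_gdh <- gdh[1]; out$t80_gdh <- gdh[2]
  if (is.finite(gdh[2]) && gdh[2] > 0) {
    out$rate_per_gdh <- fractions[2] * amplitude / gdh[2]
  }
  out
}
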