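#' Factorial experiment design
#'
#' Describes the snowmelt x drought field experiment the generator
#' emulates: a full 3x3 factorial (snow control/removal/addition crossed
#' with drought control/5-wk/10-wk), five spatial blocks with one plot per
#' treatment cell each, and two minirhizotron tubes per plot -- 45 plots
#' and 90 tubes under the defaults.
#'
#' @param n_blocks number of spatial blocks (default 5).
#' @param snow_levels,drought_levels treatment level labels.
#' @param plots_per_cell plots per treatment cell *per block* (default 1).
#' @param tubes_per_plot rhizotron tubes per plot (default 2).
#' @param seasons year labels covered by the simulated campaign.
#' @param scan_interval_days days between root scans (default 7).
#' @param rng_seed master seed; fully determines every generated artifact.
#' @return An `experiment_design` list; `design_plots()` expands it to a
#'   per-plot tibble.
#' @export
experiment_design <- function(n_blocks = 5,
                              snow_levels = c("control", "removal", "addition"),
                              drought_levels = c("control", "5wk", "10wk"),
                              plots_per_cell = 1,
                              tubes_per_plot = 2,
                              seasons = c(2020, 2021),
                              scan_interval_days = 7,
                              rng_seed = 20200601) {
  stopifnot(n_blocks >= 1, plots_per_cell >= 1, tubes_per_plot >= 1,
            scan_interval_days >= 1, length(seasons) >= 1)
  structure(list(n_blocks = n_blocks, snow_levels = snow_levels,
                 drought_levels = drought_levels,
                 plots_per_cell = plots_per_cell,
                 tubes_per_plot = tubes_per_plot,
                 seasons = seasons,
                 scan_interval_days = scan_interval_days,
                 rng_seed = as.integer(rng_seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  p <- design_plots(x)
  cat(sprintf(
    "<experiment_design> %d blocks x %d snow x %d drought x %d plots: %d plots, %d tubes\n",
    x$n_blocks, length(x$snow_levels), length(x$drought_levels),
    x$plots_per_cell, nrow(p), nrow(p) * x$tubes_per_plot))
  invisible(x)
}

#' @rdname experiment_design
#' @param design an `experiment_design`.
#' @export
design_plots <- function(design) {
  g <- tidyr::expand_grid(block = seq_len(design$n_blocks),
                          snow = design$snow_levels,
                          drought = design$drought_levels,
                          rep = seq_len(design$plots_per_cell))
  g$plot <- sprintf("B%d_S%s_D%s_%d", g$block, substr(g$snow, 1, 3),
                    g$drought, g$rep)
  g$block <- sprintf("block%d", g$block)
  dplyr::select(g, "plot", "block", "snow", "drought")
}

#' Programmable treatment effects
#'
#' Point effects the generator programs into the synthetic cohorts; the
#' defaults encode the field study's estimates: snow removal advances
#' snowmelt by 4.7 days and snow addition delays it by 10.8 days; drought
#' stimulates early-season (weeks 0--5) root growth by a factor 1.19;
#' continued drought (weeks 5--10 of the 10-wk arm) suppresses it (x0.78);
#' rewetting after shelter removal stimulates growth (x1.38) for
#' `rewet_window_days`; and winter removes 11% of standing root length
#' after control/5-wk seasons versus 17% after 10-wk drought.
#'
#' @param snowmelt_shift_days named shifts (days) per snow level.
#' @param drought_early_multiplier growth multiplier, drought weeks 0--5
#'   (both drought arms).
#' @param drought_late_multiplier multiplier in weeks 5--10 of the 10-wk arm.
#' @param rewet_multiplier multiplier for `rewet_window_days` after
#'   shelter removal.
#' @param rewet_window_days length of the rewetting window (days).
#' @param winter_loss_fraction named fractions in `[0, 1)` of standing
#'   length lost over winter, per drought level.
#' @param noise_sd_fraction sd of i.i.d. Gaussian observation noise as a
#'   fraction of the plot's true seasonal maximum. The field study does
#'   not characterize this measurement noise, so it is an explicit knob.
#' @param plot_sd_fraction,block_sd_fraction between-plot and
#'   between-block lognormal variation of the seasonal maximum.
#' @return A `treatment_effects` list.
#' @export
treatment_effects <- function(
    snowmelt_shift_days = c(control = 0, removal = -4.7, addition = 10.8),
    drought_early_multiplier = 1.19,
    drought_late_multiplier = 0.78,
    rewet_multiplier = 1.38,
    rewet_window_days = 28,
    winter_loss_fraction = c(control = 0.11, `5wk` = 0.11, `10wk` = 0.17),
    noise_sd_fraction = 0.05,
    plot_sd_fraction = 0.10,
    block_sd_fraction = 0.05) {
  mults <- c(drought_early_multiplier, drought_late_multiplier,
             rewet_multiplier)
  if (any(mults <= 0)) stop("multipliers must be positive", call. = FALSE)
  if (any(winter_loss_fraction < 0 | winter_loss_fraction >= 1)) {
    stop("winter loss fractions must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sd_fraction < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(snowmelt_shift_days = snowmelt_shift_days,
                 drought_early_multiplier = drought_early_multiplier,
                 drought_late_multiplier = drought_late_multiplier,
                 rewet_multiplier = rewet_multiplier,
                 rewet_window_days = rewet_window_days,
                 winter_loss_fraction = winter_loss_fraction,
                 noise_sd_fraction = noise_sd_fraction,
                 plot_sd_fraction = plot_sd_fraction,
                 block_sd_fraction = block_sd_fraction),
            class = "treatment_effects")
}

# base snowmelt day of year per season: late June 2019, early June 2020,
# early July 2021, late May 2022 (rounded field values)
base_snowmelt_doy <- function(season) {
  lut <- c(`2019` = 178L, `2020` = 157L, `2021` = 185L, `2022` = 147L)
  out <- lut[as.character(season)]
  out[is.na(out)] <- 165L
  unname(out)
}
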