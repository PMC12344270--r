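#' Generate a full synthetic cohort (all plots, seasons, optionally images)
#'
#' Expands an [experiment_design()] to per-plot growth curves across
#' seasons with the programmed treatment effects: snow levels shift each
#' plot's snowmelt date, drought levels modulate growth-rate windows, and
#' winter removes the programmed fraction of standing root length between
#' seasons. At `level = "series"` the cohort contains dated noisy
#' observations per plot; at `level = "image"` every tube additionally
#' gets a rendered scan-pair time-series with ground-truth masks.
#'
#' @param design an [experiment_design()].
#' @param effects a [treatment_effects()].
#' @param seed master seed (defaults to the design's `rng_seed`).
#' @param level `"series"` or `"image"`.
#' @param scan_offsets scan days relative to snowmelt (default: weekly
#'   over the season).
#' @param season_length_days days from snowmelt to the last scan.
#' @param drought_start_offset days from snowmelt to shelter placement.
#' @param max_length community seasonal asymptote (mm cm^-2).
#' @param snowmelt_jitter_sd between-plot sd (days) of the melt date.
#' @param include_temperature generate an hourly temperature series per
#'   plot (needed for GDH phenology; skip for budget runs).
#' @param image_geometry function `(tube_id, seed)` returning a
#'   [tube_geometry()] for image-level cohorts.
#' @param degradations [degradation_params()] for image rendering.
#' @return A `synthetic_cohort` list: `plots`, `series` (tibble with
#'   `plot`, `tube = NA`, `season`, `doy`, `value`, `noise_free`),
#'   `truth` (per plot-season ground truth), `temperature` (tibble or
#'   `NULL`), `images` (nested list or `NULL`), plus the design/effects.
#' @export
gen_cohort <- function(design = experiment_design(),
                       effects = treatment_effects(),
                       seed = NULL,
                       level = c("series", "image"),
                       scan_offsets = NULL,
                       season_length_days = 98,
                       drought_start_offset = 7,
                       max_length = 40,
                       snowmelt_jitter_sd = 1.5,
                       include_temperature = TRUE,
                       image_geometry = NULL,
                       degradations = degradation_params()) {
  level <- match.arg(level)
  seed <- seed %||% design$rng_seed
  plots <- design_plots(design)
  seasons <- design$seasons
  scan_offsets <- scan_offsets %||%
    seq(0, season_length_days, by = design$scan_interval_days)
  image_geometry <- image_geometry %||%
    function(tube_id, s) synth_tube_geometry(tube = tube_id)

  block_eff <- withr::with_seed(derive_seed(seed, 1), {
    setNames(exp(rnorm(design$n_blocks, 0, effects$block_sd_fraction)),
             sprintf("block%d", seq_len(design$n_blocks)))
  })

  series <- list(); truth <- list(); temps <- list(); images <- list()
  for (pi in seq_len(nrow(plots))) {
    p <- plots[pi, ]
    pseed <- derive_seed(seed, 100 + pi)
    pl_eff <- withr::with_seed(pseed, exp(rnorm(1, 0, effects$plot_sd_fraction)))
    L <- max_length * pl_eff * block_eff[[p$block]]
    shift <- effects$snowmelt_shift_days[[p$snow]]
    carry <- 0
    tube_states <- vector("list", design$tubes_per_plot)
    tube_ids <- sprintf("%s_T%d", p$plot, seq_len(design$tubes_per_plot))
    for (si in seq_along(seasons)) {
      season <- seasons[si]
      sseed <- derive_seed(pseed, si)
      melt <- withr::with_seed(sseed, {
        round(base_snowmelt_doy(season) + shift +
                rnorm(1, 0, snowmelt_jitter_sd))
      })
      gc <- gen_growth_curve(
        drought = p$drought, effects = effects, seed = derive_seed(sseed, 2),
        snowmelt_doy = melt,
        drought_start_doy = melt + drought_start_offset,
        season_length_days = season_length_days,
        scan_interval_days = design$scan_interval_days,
        max_length = L, carry = carry)
      scan_doys <- melt + scan_offsets
      obs <- tibble::tibble(
        plot = p$plot, block = p$block, snow = p$snow, drought = p$drought,
        season = season, doy = scan_doys,
        noise_free = carry + gc$curve$value(scan_doys))
      obs$value <- withr::with_seed(derive_seed(sseed, 3), {
        obs$noise_free + rnorm(nrow(obs),
                               0, effects$noise_sd_fraction * gc$curve$true_max)
      })
      series[[length(series) + 1]] <- obs
      loss <- effects$winter_loss_fraction[[p$drought]]
      truth[[length(truth) + 1]] <- tibble::tibble(
        plot = p$plot, block = p$block, snow = p$snow, drought = p$drought,
        season = season, snowmelt_doy = melt,
        drought_start_doy = melt + drought_start_offset,
        true_t20 = gc$curve$true_t20, true_t80 = gc$curve$true_t80,
        true_max = gc$curve$true_max, carry = carry,
        winter_loss_fraction = if (si < length(seasons)) loss else NA_real_)
      if (include_temperature) {
        temps[[length(temps) + 1]] <- dplyr::mutate(
          gen_temperature(season, melt, seed = derive_seed(sseed, 4)),
          plot = p$plot)
      }
      if (level == "image") {
        for (ti in seq_len(design$tubes_per_plot)) {
          gseed <- derive_seed(sseed, 10 + ti)
          geom <- image_geometry(tube_ids[ti], gseed)
          seqr <- gen_image_sequence(
            geometry = geom, curve = gc$curve, seed = gseed,
            dates = scan_doys, degradations = degradations,
            base_strands = tube_states[[ti]]$revealed %||% list())
          images[[tube_ids[ti]]][[as.character(season)]] <- seqr
          if (si < length(seasons)) {
            tube_states[[ti]] <- winter_prune_strands(
              seqr$state, loss, seed = derive_seed(gseed, 5))
          }
        }
      }
      carry <- (carry + gc$curve$value(gc$curve$end_doy)) * (
        if (si < length(seasons)) (1 - loss) else 1)
    }
  }
  structure(list(design = design, effects = effects, seed = seed,
                 plots = plots,
                 series = dplyr::bind_rows(series),
                 truth = dplyr::bind_rows(truth),
                 temperature = if (include_temperature) {
                   dplyr::bind_rows(temps)
                 } else NULL,
                 images = if (level == "image") images else NULL),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d plots, %d seasons, %d observations%s\n",
    nrow(x$plots), length(x$design$seasons), nrow(x$series),
    if (is.null(x$images)) "" else sprintf(", %d tube image series",
                                           length(x$images))))
  invisible(x)
}
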