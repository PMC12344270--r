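#' Reduced design and geometry for replicate end-to-end experiments
#'
#' A drought-only slice of the factorial (snow controls, three drought
#' levels, five blocks with two plots per treatment cell, one tube per
#' plot) over two seasons, scanned at the period-defining dates only:
#' snowmelt, shelter placement, end of the 5-wk and 10-wk windows, last
#' scan, and the first scan of the next season. Images are rendered in a
#' small window so that a full cohort of 30 tubes stays desk-scale;
#' trait densities (mm cm^-2) are unaffected by window size.
#'
#' @param rng_seed seed stored in the design.
#' @return A list with `design`, `scan_offsets` and `image_geometry`.
#' @export
power_experiment_setup <- function(rng_seed = 1) {
  list(design = experiment_design(n_blocks = 5, snow_levels = "control",
                                  drought_levels = c("control", "5wk", "10wk"),
                                  plots_per_cell = 2, tubes_per_plot = 1,
                                  seasons = c(2020, 2021),
                                  rng_seed = rng_seed),
       scan_offsets = c(0, 7, 42, 77, 98),
       image_geometry = function(tube_id, s) {
         synth_tube_geometry(tube = tube_id, image_rows = 220,
                             image_cols = 170)
       })
}

#' Replicate end-to-end cohorts: detection of programmed effects
#'
#' Runs `n_cohorts` independent synthetic cohorts through the full image
#' pipeline (render, preprocess, segment, skeletonize, measure) and, per
#' cohort, tests the early-drought stimulation (weeks 0--5 net change,
#' pooled drought arms vs control, block-aware permutation) and measures
#' per-plot winter loss fractions. The programmed effects are the
#' generator defaults: early-drought multiplier 1.19 and winter loss
#' 0.17 after the 10-wk drought vs 0.11 otherwise.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param seed master seed.
#' @param segmentation `"classical"` (full image pipeline) or `"oracle"`.
#' @param n_perm permutations per contrast.
#' @return A list: `per_cohort` tibble (`cohort`, `effect`, `p_value`,
#'   `loss_10wk`, `loss_other`), `detection_rate` (fraction of cohorts
#'   with p < 0.05), and `winter_loss_ratio` (pooled mean 10-wk loss over
#'   pooled mean control/5-wk loss).
#' @export
run_power_experiment <- function(n_cohorts = 20, seed = 1,
                                 segmentation = "classical",
                                 n_perm = 999) {
  setup <- power_experiment_setup(seed)
  rows <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    cseed <- derive_seed(seed, 1000 + r)
    cohort <- gen_cohort(setup$design, treatment_effects(), seed = cseed,
                         level = "image",
                         scan_offsets = setup$scan_offsets,
                         include_temperature = FALSE,
                         image_geometry = setup$image_geometry)
    series <- cohort_image_series(cohort, segmentation = segmentation)
    ch <- cohort_period_changes(series, cohort$truth)
    # contrast the first season's weeks 0-5: root standing length is still
    # moderate there, so skeleton-based measurement is at its most linear
    early <- ch$periods[ch$periods$period == "0-5wk" &
                          !ch$periods$missing_scan, ]
    early <- early[early$season == setup$design$seasons[1], ]
    early$group <- ifelse(early$drought == "control", "control", "drought")
    ct <- permutation_contrast(early, value = "delta", treatment = "group",
                               block = "block",
                               levels = c("control", "drought"),
                               n_perm = n_perm,
                               seed = derive_seed(cseed, 7))
    w <- ch$winter
    rows[[r]] <- tibble::tibble(
      cohort = r, effect = ct$effect, p_value = ct$p_value,
      loss_10wk = mean(w$percent_of_prev[w$drought == "10wk"]),
      loss_other = mean(w$percent_of_prev[w$drought != "10wk"]))
  }
  per_cohort <- dplyr::bind_rows(rows)
  list(per_cohort = per_cohort,
       detection_rate = mean(per_cohort$p_value < 0.05),
       winter_loss_ratio = mean(per_cohort$loss_10wk) /
         mean(per_cohort$loss_other))
}

# per-plot total-layer length-density series from a cohort's images
cohort_image_series <- function(cohort, segmentation = "classical") {
  traits <- list()
  for (tube_id in names(cohort$images)) {
    for (season in names(cohort$images[[tube_id]])) {
      tr <- measure_tube_series(cohort$images[[tube_id]][[season]],
                                segmentation = segmentation)
      tr$season <- as.numeric(season)
      tr$tube <- tube_id
      traits[[length(traits) + 1]] <- tr
    }
  }
  traits <- dplyr::bind_rows(traits)
  tot <- traits[traits$layer == "total", ]
  tot$plot <- sub("_T\\d+$", "", tot$tube)
  agg <- dplyr::summarise(
    dplyr::group_by(tot, .data$plot, .data$season, .data$doy),
    value = mean(.data$length_per_area), .groups = "drop")
  meta <- dplyr::distinct(cohort$series, .data$plot, .data$block,
                          .data$snow, .data$drought)
  dplyr::inner_join(agg, meta, by = "plot")
}
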