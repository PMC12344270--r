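#' Measure a tube's root-trait time-series from rendered or real scans
#'
#' For each scan date: preprocess the scan pair (tape masking, merging,
#' registration to the first date, de-striping, normalization), segment
#' roots (or take the ground-truth mask when `segmentation = "oracle"`),
#' and extract per-depth-layer traits.
#'
#' @param tube_seq one tube-season element as returned by
#'   [gen_image_sequence()] (fields `scans`, `geometry`).
#' @param segmentation `"classical"` (ridge segmenter on preprocessed
#'   frames) or `"oracle"` (generator ground truth).
#' @param params [seg_params()] for the classical path.
#' @param boundaries depth-layer boundaries (cm).
#' @return A traits tibble (one row per date x layer) as from
#'   [split_by_depth()], plus a `doy` column.
#' @export
measure_tube_series <- function(tube_seq,
                                segmentation = c("classical", "oracle"),
                                params = seg_params(),
                                boundaries = c(10, 20)) {
  segmentation <- match.arg(segmentation)
  geom <- tube_seq$geometry
  tape <- matrix(0L, 0, 0)
  reference <- NULL
  out <- vector("list", length(tube_seq$scans))
  for (i in seq_along(tube_seq$scans)) {
    sc <- tube_seq$scans[[i]]
    if (segmentation == "oracle") {
      mask <- sc$truth
    } else {
      if (nrow(tape) == 0) {
        tape <- matrix(0L, nrow(sc$upper), ncol(sc$upper))
        if (geom$tape_rows > 0) tape[seq_len(geom$tape_rows), ] <- 1L
      }
      prep <- preprocess_scan_pair(sc$upper, sc$lower, tape_mask = tape,
                                   reference = reference,
                                   overlap_px = nrow(sc$upper) +
                                     nrow(sc$lower) - geom$image_rows)
      if (is.null(reference)) reference <- prep$frame
      mask <- segment_roots(prep$frame, params = params,
                            exclude_rows = geom$tape_rows + 3)
      attr(mask, "tube") <- geom$tube
      attr(mask, "date") <- sc$doy
    }
    tr <- split_by_depth(mask, geom, boundaries = boundaries)
    tr$doy <- sc$doy
    tr$tube <- geom$tube
    out[[i]] <- tr
  }
  dplyr::bind_rows(out)
}

#' Seasonal period changes and winter losses for a cohort's series
#'
#' Computes per-plot period net changes within each season (pre-treatment,
#' drought weeks 0--5 and 5--10, autumn) and the over-winter change
#' between consecutive seasons, from any dated per-plot series (noisy
#' observations or image-derived length densities).
#'
#' @param series tibble with `plot`, `block`, `drought`, `season`, `doy`,
#'   `value`.
#' @param truth the cohort `truth` tibble (for snowmelt/shelter dates).
#' @return A list of two tibbles: `periods` (per plot-season-period
#'   deltas) and `winter` (per plot winter change with both relative
#'   measures).
#' @export
cohort_period_changes <- function(series, truth) {
  seasons <- sort(unique(series$season))
  periods_out <- list(); winter_out <- list()
  for (pl in unique(series$plot)) {
    s_pl <- series[series$plot == pl, ]
    prev_last <- NA_real_; prev_gain <- NA_real_
    for (season in seasons) {
      s <- dplyr::arrange(s_pl[s_pl$season == season, ], .data$doy)
      tr <- truth[truth$plot == pl & truth$season == season, ]
      if (nrow(s) == 0 || nrow(tr) != 1) next
      per <- season_periods(tr$snowmelt_doy, tr$drought_start_doy,
                            max(s$doy))
      pc <- period_net_change(s[, c("doy", "value")], per)
      pc$plot <- pl; pc$season <- season
      pc$block <- s$block[1]; pc$drought <- s$drought[1]
      pc$snow <- if ("snow" %in% names(s)) s$snow[1] else NA_character_
      periods_out[[length(periods_out) + 1]] <- pc
      if (!is.na(prev_last)) {
        wc <- winter_change(prev_last, s$value[1], prev_gain)
        wc$plot <- pl; wc$season <- season
        wc$block <- s$block[1]; wc$drought <- s$drought[1]
        winter_out[[length(winter_out) + 1]] <- wc
      }
      prev_last <- s$value[nrow(s)]
      prev_gain <- s$value[nrow(s)] - s$value[1]
    }
  }
  list(periods = dplyr::bind_rows(periods_out),
       winter = dplyr::bind_rows(winter_out))
}

#' Phenology thresholds for every plot-season of a cohort
#'
#' Expresses each root series relative to its first scan of the season,
#' fits the per-plot penalized spline, and extracts the 20%/80%
#' thresholds in days and growing degree hours.
#'
#' @param cohort a `synthetic_cohort` (needs `temperature`).
#' @param series optional replacement series (e.g. image-derived).
#' @return Tibble with one row per plot-season: thresholds, amplitude,
#'   rate per GDH, and the matching ground truth columns.
#' @export
cohort_phenology <- function(cohort, series = NULL) {
  series <- series %||% cohort$series
  if (is.null(cohort$temperature)) {
    stop("cohort was generated without temperature series", call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(cohort$truth))) {
    tr <- cohort$truth[i, ]
    s <- series[series$plot == tr$plot & series$season == tr$season, ]
    if (nrow(s) < 6) next
    s <- dplyr::arrange(s, .data$doy)
    rel <- tibble::tibble(doy = s$doy, value = s$value - s$value[1])
    sm <- fit_growth_spline(rel)
    temps <- cohort$temperature[cohort$temperature$plot == tr$plot &
                                  cohort$temperature$season == tr$season, ]
    # roots: baseline 0 by construction (series re-zeroed at first scan);
    # cumulative series are monotone, so the seasonal maximum sits at the
    # season end
    th <- extract_thresholds(sm, temps, tr$snowmelt_doy,
                             first_value = 0, amplitude_at = "end")
    out[[length(out) + 1]] <- dplyr::bind_cols(
      tr[, c("plot", "block", "snow", "drought", "season", "snowmelt_doy",
             "true_t20", "true_t80", "true_max")], th)
  }
  dplyr::bind_rows(out)
}

#' Pipeline configuration
#'
#' A single serializable list of every knob the end-to-end run uses;
#' round-trips losslessly through YAML.
#'
#' @param out_dir output directory for CSVs and the manifest.
#' @param seed master seed.
#' @param level `"series"` or `"image"`.
#' @param segmentation `"classical"` or `"oracle"` (image level only).
#' @param design,effects,seg,phenology parameter sublists; defaults come
#'   from [experiment_design()], [treatment_effects()], [seg_params()]
#'   and the phenology defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("rhizochron_run_"),
                            seed = 20200601, level = "series",
                            segmentation = "classical",
                            design = list(), effects = list(),
                            seg = list(), phenology = list()) {
  structure(list(out_dir = out_dir, seed = seed, level = level,
                 segmentation = segmentation, design = design,
                 effects = effects, seg = seg, phenology = phenology),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path`; `read_config()` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline: generate, measure, smooth, account, contrast
#'
#' Generates a synthetic cohort from the configured design, derives the
#' per-plot root-length series (at image level: preprocess, segment and
#' measure every rendered scan; at series level: use the simulated
#' observations), fits phenology thresholds, computes period and winter
#' changes, runs the block-aware early-drought contrast, and writes all
#' result tables plus a manifest to `config$out_dir`. Re-running with the
#' same config reproduces every CSV bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the result tibbles and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  design <- do.call(experiment_design,
                    c(config$design, list(rng_seed = config$seed)))
  effects <- do.call(treatment_effects, config$effects)
  level <- config$level
  cohort <- gen_cohort(design, effects, seed = config$seed, level = level)
  if (level == "image") {
    seg_p <- do.call(seg_params, config$seg)
    traits <- list()
    for (tube_id in names(cohort$images)) {
      for (season in names(cohort$images[[tube_id]])) {
        tr <- measure_tube_series(cohort$images[[tube_id]][[season]],
                                  segmentation = config$segmentation,
                                  params = seg_p)
        tr$season <- as.numeric(season)
        traits[[length(traits) + 1]] <- tr
      }
    }
    traits <- dplyr::bind_rows(traits)
    meta <- dplyr::distinct(cohort$series, .data$plot, .data$block,
                            .data$snow, .data$drought)
    series <- traits[traits$layer == "total",
                     c("tube", "season", "doy", "length_per_area")]
    series$plot <- sub("_T\\d+$", "", series$tube)
    series <- dplyr::summarise(
      dplyr::group_by(series, .data$plot, .data$season, .data$doy),
      value = mean(.data$length_per_area), .groups = "drop")
    series <- dplyr::inner_join(series, meta, by = "plot")
  } else {
    traits <- NULL
    series <- cohort$series
  }
  phen <- cohort_phenology(cohort, series = series)
  changes <- cohort_period_changes(series, cohort$truth)
  early <- changes$periods[changes$periods$period == "0-5wk" &
                             !changes$periods$missing_scan, ]
  early$group <- ifelse(early$drought == "control", "control", "drought")
  contrast <- permutation_contrast(early, value = "delta",
                                   treatment = "group", block = "block",
                                   levels = c("control", "drought"),
                                   seed = derive_seed(config$seed, 99))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    series = file.path(config$out_dir, "series.csv"),
    phenology = file.path(config$out_dir, "phenology.csv"),
    periods = file.path(config$out_dir, "periods.csv"),
    winter = file.path(config$out_dir, "winter.csv"),
    contrasts = file.path(config$out_dir, "contrasts.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  readr::write_csv(series, paths$series)
  readr::write_csv(phen, paths$phenology)
  readr::write_csv(changes$periods, paths$periods)
  readr::write_csv(changes$winter, paths$winter)
  readr::write_csv(tidy(contrast), paths$contrasts)
  if (!is.null(traits)) {
    paths$traits <- file.path(config$out_dir, "traits.csv")
    readr::write_csv(traits, paths$traits)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("rhizochron")),
                   seed = config$seed, level = level,
                   segmentation = config$segmentation,
                   design = config$design, effects = config$effects,
                   n_plots = nrow(cohort$plots),
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(series = series, traits = traits, phenology = phen,
                 periods = changes$periods, winter = changes$winter,
                 contrast = contrast, paths = paths))
}
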