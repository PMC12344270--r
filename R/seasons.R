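#' Seasonal treatment periods of a plot
#'
#' Partitions a growing season into the periods used for net root-length
#' accounting: pre-treatment (snowmelt until shelter placement), weeks
#' 0--5 of drought, weeks 5--10, and autumn (after the 10-wk window until
#' the last scan). Weeks are exact 35/70-day offsets from shelter
#' placement.
#'
#' @param snowmelt_doy snowmelt day of year.
#' @param drought_start_doy day the rain-out shelters were placed.
#' @param last_scan_doy last root scan of the season.
#' @return A `season_periods` tibble with `period` (`P`, `0-5wk`,
#'   `5-10wk`, `A`) and half-open `[start, end)` day windows; the final
#'   period closes at `last_scan_doy` inclusive.
#' @export
season_periods <- function(snowmelt_doy, drought_start_doy, last_scan_doy) {
  b <- c(snowmelt_doy, drought_start_doy, drought_start_doy + 35,
         drought_start_doy + 70, last_scan_doy)
  if (any(diff(b) < 0)) {
    stop("period boundaries must be ordered: snowmelt <= drought start, ",
         "and the last scan must fall after the 10-wk window", call. = FALSE)
  }
  tibble::tibble(period = factor(c("P", "0-5wk", "5-10wk", "A"),
                                 levels = c("W", "P", "0-5wk", "5-10wk", "A")),
                 start = b[1:4], end = b[2:5])
}

#' Net root-length change per seasonal period
#'
#' For each period, the net change is the value at the last scan within
#' the period minus the value at the last scan of the previous period
#' (the reference for the first period is the first scan of the season).
#' Deltas therefore telescope: their sum equals the whole-season net
#' change exactly. Periods without any scan yield `NA` with a flag,
#' never an imputation.
#'
#' @param series tibble with `doy` and `value` (root length, mm cm^-2).
#' @param periods a [season_periods()] tibble.
#' @return Tibble with `period`, `delta` (same units as `value`),
#'   `last_doy` (day of the period's defining scan) and `missing_scan`.
#' @export
period_net_change <- function(series, periods) {
  stopifnot(all(c("doy", "value") %in% names(series)))
  series <- dplyr::arrange(series, .data$doy)
  prev_val <- series$value[1]
  out <- vector("list", nrow(periods))
  for (i in seq_len(nrow(periods))) {
    p <- periods[i, ]
    inside <- if (i == nrow(periods)) {
      series$doy > p$start & series$doy <= p$end
    } else {
      series$doy > p$start & series$doy <= p$end  # last scan within period
    }
    if (!any(inside)) {
      out[[i]] <- tibble::tibble(period = p$period, delta = NA_real_,
                                 last_doy = NA_real_, missing_scan = TRUE)
      next
    }
    j <- max(which(inside))
    out[[i]] <- tibble::tibble(period = p$period,
                               delta = series$value[j] - prev_val,
                               last_doy = series$doy[j], missing_scan = FALSE)
    prev_val <- series$value[j]
  }
  dplyr::bind_rows(out)
}

#' Over-winter root-length change
#'
#' The winter change is the first scan of the new season minus the last
#' scan of the previous season. It is reported absolutely and relative to
#' two references: the previous standing length (`percent_of_prev`, the
#' "declined by X%" reading) and the previous season's gain
#' (`fraction_of_gain`, the "X% of the previous season's increase"
#' reading). Both are computed because the two denominators answer
#' different questions.
#'
#' @param prev_last root length at the last scan of the previous season.
#' @param next_first root length at the first scan of the new season.
#' @param prev_season_gain the previous season's net increase; must be
#'   positive for `fraction_of_gain`.
#' @return One-row tibble: `delta`, `percent_of_prev` (positive = loss),
#'   `fraction_of_gain`.
#' @examples
#' winter_change(40, 34, 24)  # -6 mm cm^-2, 15% of standing, 25% of gain
#' @export
winter_change <- function(prev_last, next_first, prev_season_gain = NA) {
  delta <- next_first - prev_last
  pct <- if (is.finite(prev_last) && prev_last != 0) {
    -delta / prev_last
  } else {
    warning("zero previous standing length: relative loss undefined")
    NA_real_
  }
  frac <- if (is.finite(prev_season_gain) && prev_season_gain > 0) {
    -delta / prev_season_gain
  } else NA_real_
  tibble::tibble(delta = delta, percent_of_prev = pct,
                 fraction_of_gain = frac)
}

#' Block-aware permutation contrast between treatments
#'
#' Difference of treatment means with a permutation null built by
#' shuffling treatment labels within blocks, respecting the experiment's
#' block structure without fitting a mixed model. The two-sided p-value
#' uses the add-one estimator `(1 + #|effect*| >= |effect|) / (n_perm + 1)`.
#'
#' @param data tibble with the response, treatment and block columns.
#' @param value,treatment,block column names (strings).
#' @param levels length-2 character: the two treatment levels compared;
#'   effect = mean(`levels[2]`) - mean(`levels[1]`). Defaults to the first
#'   two levels present.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return A `permutation_contrast` object; supports [tidy()]/[glance()].
#' @export
permutation_contrast <- function(data, value = "value",
                                 treatment = "treatment", block = "block",
                                 levels = NULL, n_perm = 999, seed = 1) {
  stopifnot(all(c(value, treatment, block) %in% names(data)))
  v <- data[[value]]; tr <- as.character(data[[treatment]])
  bl <- as.character(data[[block]])
  keep <- is.finite(v)
  v <- v[keep]; tr <- tr[keep]; bl <- bl[keep]
  levels <- levels %||% unique(tr)[1:2]
  if (length(unique(tr)) < 2) stop("need >= 2 treatments", call. = FALSE)
  tab <- table(bl)
  singletons <- names(tab)[tab < 2]
  if (length(singletons) > 0) {
    warning("excluding block(s) with a single plot: ",
            paste(singletons, collapse = ", "))
    sel <- !(bl %in% singletons)
    v <- v[sel]; tr <- tr[sel]; bl <- bl[sel]
  }
  eff <- function(labels) {
    mean(v[labels == levels[2]]) - mean(v[labels == levels[1]])
  }
  observed <- eff(tr)
  blocks <- split(seq_along(v), bl)
  perm_effects <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- tr
      for (idx in blocks) lab[idx] <- sample(lab[idx])
      eff(lab)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_effects) >= abs(observed))) / (n_perm + 1)
  structure(list(effect = observed, p_value = p, n_perm = n_perm,
                 levels = levels, n = length(v),
                 perm_effects = perm_effects),
            class = "permutation_contrast")
}

#' @export
print.permutation_contrast <- function(x, ...) {
  cat(sprintf(
    "<permutation_contrast> %s vs %s: effect %.4g, p = %.4g (%d perms, n = %d)\n",
    x$levels[2], x$levels[1], x$effect, x$p_value, x$n_perm, x$n))
  invisible(x)
}
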