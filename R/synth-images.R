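#' Default geometry for synthetic rhizotron scenes
#'
#' A desk-scale tube window: smaller raster and coarser resolution than
#' the 1200-DPI field scans, but with the same pixel-to-depth mapping so
#' every geometric computation is exercised unchanged.
#'
#' @param tube tube id.
#' @param image_rows,image_cols raster extent of the merged image.
#' @param dpi resolution (default 600; a 0.1 mm root is then 2.4 px wide).
#' @param angle_deg soil--tube angle.
#' @param tape_rows rows of light-blocking tape at the surface.
#' @return A [tube_geometry()].
#' @export
synth_tube_geometry <- function(tube = "T01", image_rows = 420,
                                image_cols = 300, dpi = 600,
                                angle_deg = 45, tape_rows = 12) {
  tube_geometry(tube = tube, angle_deg = angle_deg, tape_rows = tape_rows,
                dpi = dpi, image_rows = image_rows, image_cols = image_cols)
}

# draw a root width (mm): 85% of strands in 0.12-0.30 mm, the rest up to
# 0.6 mm, mirroring the observed dominance of very fine roots
sample_strand_width <- function(n) {
  fine <- runif(n) < 0.85
  ifelse(fine, runif(n, 0.12, 0.30), runif(n, 0.30, 0.60))
}

# one biased random-walk strand: downward drift, curvature-limited heading,
# reflected at the side walls; returns dense ~1 px-spaced points. Strands
# avoid already-occupied soil (roots tile the rhizotron surface rather
# than run on top of each other): when the path ahead is occupied the
# heading deflects, and a blocked strand terminates. Occasional true
# crossings remain possible at steep approach angles.
gen_strand <- function(geom, occupancy = NULL) {
  nr <- geom$image_rows; nc <- geom$image_cols
  r0 <- runif(1, geom$tape_rows + 4, geom$tape_rows + (nr - geom$tape_rows) * 0.6)
  c0 <- runif(1, 2, nc - 1)
  if (!is.null(occupancy) && occupancy[round(r0), round(c0)]) return(NULL)
  theta <- rnorm(1, 0, 0.8)  # 0 = straight down
  target_len <- pmin(rlnorm(1, log(150), 0.5), 3 * nr)
  step <- 1.0
  n_max <- ceiling(target_len / step) + 1
  pts <- matrix(NA_real_, n_max, 2)
  pts[1, ] <- c(r0, c0)
  r <- r0; cc <- c0; i <- 1
  lookahead <- 3
  while (i < n_max) {
    theta <- theta + rnorm(1, 0, 0.12) - 0.04 * theta
    theta <- max(min(theta, 1.4), -1.4)
    if (!is.null(occupancy)) {
      # deflect away from occupied soil; cross only if every try is blocked
      # and a coin flip allows it (steep crossings cost little length)
      tries <- theta + c(0, 0.5, -0.5, 1.0, -1.0)
      free <- FALSE
      for (th in tries) {
        ra <- round(r + lookahead * cos(th))
        ca <- round(cc + lookahead * sin(th))
        if (ra < 1 || ra > nr || ca < 1 || ca > nc || !occupancy[ra, ca]) {
          theta <- max(min(th, 1.4), -1.4); free <- TRUE; break
        }
      }
      if (!free && runif(1) < 0.85) break
    }
    r <- r + step * cos(theta)
    cc <- cc + step * sin(theta)
    if (cc < 2) { cc <- 4 - cc; theta <- -theta }
    if (cc > nc - 1) { cc <- 2 * (nc - 1) - cc; theta <- -theta }
    if (r > nr - 1 || r < geom$tape_rows + 2) break
    i <- i + 1
    pts[i, ] <- c(r, cc)
  }
  pts <- pts[seq_len(i), , drop = FALSE]
  if (i < 2) return(NULL)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  list(pts = pts, seg = seg, cum = c(0, cumsum(seg)),
       total = sum(seg),
       width_mm = sample_strand_width(1),
       intensity = runif(1, 165, 205))
}

# mark a strand's path (dilated by its half-width plus clearance) on the
# occupancy grid
mark_occupancy <- function(occupancy, strand, geom, clearance = 2) {
  rad <- strand$width_mm * geom$dpi / 25.4 / 2 + clearance
  ro <- floor(-rad):ceiling(rad)
  offs <- expand.grid(dr = ro, dc = ro)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, , drop = FALSE]
  pr <- round(strand$pts[, 1]); pc <- round(strand$pts[, 2])
  rr <- outer(pr, offs$dr, "+"); ccc <- outer(pc, offs$dc, "+")
  ok <- rr >= 1 & rr <= nrow(occupancy) & ccc >= 1 & ccc <= ncol(occupancy)
  occupancy[cbind(rr[ok], ccc[ok])] <- TRUE
  occupancy
}

# truncate a strand's polyline to `len_px`, interpolating the cut point
truncate_strand <- function(strand, len_px) {
  if (len_px >= strand$total) return(strand)
  if (len_px <= 0) return(NULL)
  i <- which(strand$cum >= len_px)[1]
  frac <- (len_px - strand$cum[i - 1]) / (strand$cum[i] - strand$cum[i - 1])
  cut <- strand$pts[i - 1, ] + frac * (strand$pts[i, ] - strand$pts[i - 1, ])
  pts <- rbind(strand$pts[seq_len(i - 1), , drop = FALSE], cut)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  out <- strand
  out$pts <- pts; out$seg <- seg; out$cum <- c(0, cumsum(seg))
  out$total <- sum(seg)
  out
}

# analytic per-depth-layer length (mm) of a set of (possibly truncated)
# strands: each polyline segment is assigned by its midpoint row
strand_layer_lengths <- function(strands, geom, boundaries = c(10, 20)) {
  labels <- layer_labels_from_boundaries(boundaries)
  mm_per_px <- 25.4 / geom$dpi
  sums <- setNames(numeric(length(labels)), labels)
  for (s in strands) {
    if (is.null(s) || length(s$seg) == 0) next
    mid_r <- (s$pts[-1, 1] + s$pts[-nrow(s$pts), 1]) / 2
    depth <- suppressWarnings(depth_of_row(mid_r, geom))
    cuts <- c(0, boundaries[-length(boundaries)], Inf)
    li <- pmin(pmax(findInterval(depth, cuts), 1L), length(labels))
    for (k in seq_along(labels)) {
      sums[k] <- sums[k] + sum(s$seg[li == k]) * mm_per_px
    }
  }
  tibble::tibble(layer = c(labels, "total"),
                 length_mm = c(unname(sums), sum(sums)))
}

# stamp strands onto canvas; returns list(image, mask)
render_strands <- function(strands, geom, background) {
  nr <- geom$image_rows; nc <- geom$image_cols
  img <- background
  mask <- matrix(0L, nr, nc)
  for (s in strands) {
    if (is.null(s) || nrow(s$pts) < 2) next
    w_px <- max(s$width_mm * geom$dpi / 25.4, 1)
    rad <- w_px / 2
    ro <- floor(-rad):ceiling(rad)
    offs <- expand.grid(dr = ro, dc = ro)
    offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 + 0.25, , drop = FALSE]
    pr <- round(s$pts[, 1]); pc <- round(s$pts[, 2])
    rr <- outer(pr, offs$dr, "+"); ccc <- outer(pc, offs$dc, "+")
    ok <- rr >= 1 & rr <= nr & ccc >= 1 & ccc <= nc
    idx <- cbind(rr[ok], ccc[ok])
    mask[idx] <- 1L
    img[idx] <- pmax(img[idx], s$intensity + rnorm(nrow(idx), 0, 6))
  }
  mask[seq_len(geom$tape_rows), ] <- 0L
  img[seq_len(geom$tape_rows), ] <- 232
  list(image = pmin(pmax(img, 0), 255), mask = mask)
}

soil_background <- function(geom) {
  nr <- geom$image_rows; nc <- geom$image_cols
  coarse <- matrix(rnorm(nr * nc), nr, nc)
  coarse <- unclass_mat(EBImage::gblur(coarse, sigma = 6))
  coarse <- coarse / max(sd(coarse), 1e-9)
  90 + 14 * coarse + matrix(rnorm(nr * nc, 0, 6), nr, nc)
}

#' Default image degradations
#'
#' @param stripes add additive column banding (fraction of affected
#'   columns and maximum offset).
#' @param shift apply a random integer planar shift per date (max px).
#' @param brightness per-date global brightness drift (max offset).
#' @return A named list of degradation settings.
#' @export
degradation_params <- function(stripes = TRUE, shift = TRUE,
                               brightness = TRUE) {
  list(stripes = stripes, stripe_col_fraction = 0.12, stripe_max = 18,
       shift = shift, shift_max = 5,
       brightness = brightness, brightness_max = 12)
}

apply_degradations <- function(img, deg, is_reference) {
  shift <- c(dy = 0L, dx = 0L)
  if (isTRUE(deg$shift) && !is_reference) {
    shift <- c(dy = sample(-deg$shift_max:deg$shift_max, 1),
               dx = sample(-deg$shift_max:deg$shift_max, 1))
    img <- translate_px(img, shift[["dy"]], shift[["dx"]])
  }
  if (isTRUE(deg$stripes)) {
    nc <- ncol(img)
    cols <- which(runif(nc) < deg$stripe_col_fraction)
    if (length(cols) > 0) {
      img[, cols] <- sweep(img[, cols, drop = FALSE], 2,
                           runif(length(cols), -deg$stripe_max,
                                 deg$stripe_max), "+")
    }
  }
  if (isTRUE(deg$brightness)) {
    img <- img + runif(1, -deg$brightness_max, deg$brightness_max)
  }
  list(image = pmin(pmax(img, 0), 255), shift = shift)
}

#' Render a rhizotron scan time-series with known ground truth
#'
#' Renders a growing set of biased random-walk root strands on a textured
#' soil background, one scan pair per date. Strands extend from their tips
#' ("frontier growth"): at each date whole strands plus a partial prefix
#' of the next are revealed so the drawn polyline length exactly equals
#' the growth curve's standing length times the image area. Per-date true
#' lengths per depth layer are recorded analytically from the polylines.
#' Optional degradations (column stripes, per-date planar drift,
#' brightness drift) are applied after the ground-truth mask is taken, so
#' truth is expressed in the reference (first image) coordinates.
#'
#' @param geometry a [tube_geometry()] (see [synth_tube_geometry()]).
#' @param curve a `growth_curve` from [gen_growth_curve()].
#' @param seed RNG seed; the full output is deterministic given it.
#' @param dates scan days of year (default: the curve's weekly scan grid).
#' @param degradations a [degradation_params()] list.
#' @param base_strands strands carried over from a previous season (from
#'   `state$revealed` after [winter_prune_strands()]).
#' @param overlap_px rows shared by the upper and lower scan of a pair.
#' @return A list with `scans` (per date: `upper`, `lower`, `truth`,
#'   `truth_lengths`, `applied_shift`, `doy`), `geometry`, and `state`
#'   (revealed strands and standing length, for the next season).
#' @export
gen_image_sequence <- function(geometry, curve, seed, dates = NULL,
                               degradations = degradation_params(),
                               base_strands = list(), overlap_px = 20) {
  if (image_area_cm2(geometry) <= 0) {
    stop("geometry image area must be positive", call. = FALSE)
  }
  area <- image_area_cm2(geometry)
  px_per_mm <- geometry$dpi / 25.4
  dates <- dates %||% seq(curve$snowmelt_doy, curve$end_doy, by = 7)
  max_new_px <- curve$value(curve$end_doy) * area * px_per_mm

  withr::with_seed(seed, {
    background <- soil_background(geometry)
    occupancy <- matrix(FALSE, geometry$image_rows, geometry$image_cols)
    for (s in base_strands) occupancy <- mark_occupancy(occupancy, s, geometry)
    pool <- list()
    tot <- 0
    tries <- 0
    while (tot < max_new_px * 1.02 + 50 && tries < 10000) {
      tries <- tries + 1
      s <- gen_strand(geometry, occupancy = occupancy)
      if (is.null(s) || s$total < 10) next
      pool[[length(pool) + 1]] <- s
      occupancy <- mark_occupancy(occupancy, s, geometry)
      tot <- tot + s$total
    }
    pool_cum <- cumsum(vapply(pool, `[[`, numeric(1), "total"))

    scans <- vector("list", length(dates))
    revealed <- base_strands
    for (di in seq_along(dates)) {
      t <- dates[di]
      target_px <- curve$value(t) * area * px_per_mm
      n_full <- sum(pool_cum <= target_px)
      revealed_new <- pool[seq_len(n_full)]
      rem <- target_px - (if (n_full > 0) pool_cum[n_full] else 0)
      if (n_full < length(pool) && rem > 0) {
        part <- truncate_strand(pool[[n_full + 1]], rem)
        if (!is.null(part)) revealed_new <- c(revealed_new, list(part))
      }
      revealed <- c(base_strands, revealed_new)
      rs <- render_strands(revealed, geometry, background)
      deg <- apply_degradations(rs$image, degradations,
                                is_reference = di == 1)
      pair <- split_scan_pair(deg$image, geometry, overlap_px)
      scans[[di]] <- list(
        doy = t,
        upper = pair$upper, lower = pair$lower,
        truth = root_mask(rs$mask, dpi = geometry$dpi,
                          tube = geometry$tube, date = t,
                          provenance = "oracle"),
        truth_lengths = strand_layer_lengths(revealed, geometry),
        applied_shift = deg$shift)
    }
  })
  list(scans = scans, geometry = geometry,
       state = list(revealed = revealed,
                    standing_mm = sum(vapply(revealed, function(s) s$total,
                                             numeric(1))) / px_per_mm))
}

# split a merged raster into the upper/lower scan pair with overlap
split_scan_pair <- function(img, geometry, overlap_px) {
  nr <- nrow(img)
  h_up <- ceiling((nr + overlap_px) / 2)
  upper <- scan_frame(img[seq_len(h_up), , drop = FALSE],
                      dpi = geometry$dpi, tube = geometry$tube,
                      position = "upper")
  lower <- scan_frame(img[(h_up - overlap_px + 1):nr, , drop = FALSE],
                      dpi = geometry$dpi, tube = geometry$tube,
                      position = "lower")
  list(upper = upper, lower = lower, overlap_px = overlap_px)
}

#' Remove strands over winter
#'
#' Winter root loss removes whole strands (roots disappear, they do not
#' erode): strands are dropped at random until the standing length falls
#' to the target, and the last dropped strand is partially retained
#' (tip-trimmed) so the inter-season drop equals the programmed loss
#' fraction exactly.
#'
#' @param state the `state` element returned by [gen_image_sequence()].
#' @param loss_fraction fraction of standing root length lost, in `[0, 1)`.
#' @param seed RNG seed choosing which strands die.
#' @return A new `state` whose standing length is
#'   `(1 - loss_fraction) * standing`.
#' @export
winter_prune_strands <- function(state, loss_fraction, seed = 1) {
  if (loss_fraction < 0 || loss_fraction >= 1) {
    stop("`loss_fraction` must lie in [0, 1)", call. = FALSE)
  }
  strands <- state$revealed
  withr::local_seed(seed)
  totals <- vapply(strands, function(s) s$total, numeric(1))
  target <- sum(totals) * (1 - loss_fraction)
  ord <- sample(length(strands))
  keep_px <- 0
  kept <- list()
  for (i in ord) {
    if (keep_px + totals[i] <= target) {
      kept <- c(kept, strands[i])
      keep_px <- keep_px + totals[i]
    } else if (target - keep_px > 1e-9) {
      # tip-trim the first strand that would overshoot, landing exactly
      part <- truncate_strand(strands[[i]], target - keep_px)
      if (!is.null(part)) {
        kept <- c(kept, list(part))
        keep_px <- target
      }
    }
  }
  list(revealed = kept, standing_px = keep_px)
}
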