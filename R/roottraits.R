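#' Diameter class labels
#'
#' Root length is reported in eleven diameter classes: 0--1 mm in 0.1 mm
#' steps plus a `>1` class. Binning is half-open (`[0.0, 0.1)`, ...,
#' `[0.9, 1.0)`), so a diameter of exactly 1.0 mm falls in the `>1` class.
#'
#' @return Character vector of the 11 class labels.
#' @export
diameter_class_labels <- function() {
  lo <- seq(0, 0.9, by = 0.1)
  c(sprintf("%.1f-%.1f", lo, lo + 0.1), ">1")
}

#' Per-skeleton-pixel root diameters
#'
#' Diameter at each skeleton pixel is twice the Euclidean distance
#' transform of the mask, minus one pixel (the transform measures centre
#' to centre, so a one-pixel-wide line maps to one pixel diameter).
#' Branch points (skeleton pixels with three or more neighbours) are
#' flagged so summary statistics can exclude junction inflation; their
#' length still participates in binning so totals are conserved.
#'
#' @param mask a [root_mask()] or binary matrix.
#' @param skeleton 0/1 matrix from [thin_mask()]; computed if `NULL`.
#' @param dpi scan resolution; from mask attribute if absent.
#' @return A tibble with one row per skeleton pixel: `row`, `col`,
#'   `diameter_mm`, `length_px` (that pixel's length increment),
#'   `branch_point`.
#' @export
measure_diameters <- function(mask, skeleton = NULL, dpi = NULL) {
  dpi <- dpi %||% attr(mask, "dpi") %||% 1200
  m <- unclass_mat(mask)
  skel <- if (is.null(skeleton)) thin_mask(m) else unclass_mat(skeleton)
  if (!any(skel == 1L)) {
    return(tibble::tibble(row = integer(), col = integer(),
                          diameter_mm = numeric(), length_px = numeric(),
                          branch_point = logical()))
  }
  dt <- unclass_mat(EBImage::distmap(m))
  inc <- skeleton_length_increments(skel)$increments
  nb <- shift_mat(skel, 1, 0) + shift_mat(skel, -1, 0) +
    shift_mat(skel, 0, 1) + shift_mat(skel, 0, -1) +
    shift_mat(skel, 1, 1) + shift_mat(skel, 1, -1) +
    shift_mat(skel, -1, 1) + shift_mat(skel, -1, -1)
  idx <- which(skel == 1L, arr.ind = TRUE)
  d_px <- pmax(2 * dt[idx] - 1, 1)
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                 diameter_mm = d_px * 25.4 / dpi,
                 length_px = inc[idx],
                 branch_point = nb[idx] >= 3)
}

#' Bin root length by diameter class
#'
#' @param lengths per-pixel (or per-segment) length increments.
#' @param diameters matching diameters in mm; must be non-negative.
#' @return A tibble with `class` (all 11 labels, ordered) and `length`
#'   (same unit as `lengths`); class sums conserve the total exactly.
#' @export
bin_by_diameter <- function(lengths, diameters) {
  if (length(lengths) != length(diameters)) {
    stop("`lengths` and `diameters` must have equal length", call. = FALSE)
  }
  if (any(diameters < 0)) stop("negative diameter", call. = FALSE)
  labels <- diameter_class_labels()
  cls <- findInterval(diameters, seq(0, 1, by = 0.1),
                      rightmost.closed = FALSE)  # 1..10 below 1 mm, 11 above
  cls <- pmin(cls, 11L)
  sums <- vapply(seq_len(11), function(k) sum(lengths[cls == k]), numeric(1))
  tibble::tibble(class = factor(labels, levels = labels), length = sums)
}

#' Cylindrical root surface area
#'
#' Surface area as the sum of `pi * d_i * l_i` over skeleton length
#' increments, modelling each increment as a cylinder of local diameter.
#'
#' @param lengths length increments (mm).
#' @param diameters matching diameters (mm).
#' @return Area in mm^2.
#' @export
surface_area <- function(lengths, diameters) {
  if (length(lengths) != length(diameters)) {
    stop("`lengths` and `diameters` must have equal length", call. = FALSE)
  }
  sum(pi * diameters * lengths)
}

#' Vertical soil depth of an image row
#'
#' Along-tube distance from the soil surface (the tape edge) converts to
#' vertical depth through the soil--tube angle:
#' `depth = (row - tape_rows) * 2.54/dpi * sin(angle)`. Rows above the
#' soil surface map to depth 0 (with a warning).
#'
#' @param row image row index (1-based; may be a vector).
#' @param geom a [tube_geometry()].
#' @return Vertical depth in cm.
#' @examples
#' g <- tube_geometry(angle_deg = 45, tape_rows = 0, dpi = 1200,
#'                    image_rows = 20000, image_cols = 100)
#' depth_of_row(1 + 10 / (2.54 / 1200), g)  # 10 cm along tube -> 7.071 cm
#' @export
depth_of_row <- function(row, geom) {
  s_cm <- (row - 1 - geom$tape_rows) * (2.54 / geom$dpi)
  if (any(s_cm < 0)) {
    warning("row(s) above the soil surface: depth set to 0")
    s_cm <- pmax(s_cm, 0)
  }
  s_cm * sin(geom$angle_deg * pi / 180)
}

layer_labels_from_boundaries <- function(boundaries) {
  b <- c(0, boundaries)
  sprintf("%g-%g", b[-length(b)], b[-1])
}

#' Root traits per soil depth layer
#'
#' Skeletonizes the mask once, measures per-pixel length increments and
#' diameters, assigns each skeleton pixel to a depth layer via
#' [depth_of_row()] (half-open layers; the deepest layer extends to the
#' image bottom), and reports per-layer and total records: length, surface
#' area, diameter-class breakdown, and length per unit image area.
#'
#' @param mask a [root_mask()] or binary matrix, congruent with the
#'   merged image described by `geom`.
#' @param geom a [tube_geometry()].
#' @param boundaries depth-layer boundaries in cm (default `c(10, 20)`
#'   giving layers 0--10 and 10--20, the latter reaching the tube bottom).
#' @param skeleton optional precomputed skeleton.
#' @return A tibble with one row per layer plus a `"total"` row: `tube`,
#'   `date`, `layer`, `length_mm`, `area_mm2`, `image_area_cm2`,
#'   `length_per_area` (mm cm^-2) and one `class_*` column per diameter
#'   class.
#' @export
split_by_depth <- function(mask, geom, boundaries = c(10, 20),
                           skeleton = NULL) {
  dpi <- geom$dpi
  px_info <- measure_diameters(mask, skeleton = skeleton, dpi = dpi)
  labels <- layer_labels_from_boundaries(boundaries)
  area_cm2 <- image_area_cm2(geom)
  class_lab <- diameter_class_labels()
  class_cols <- paste0("class_", gsub(">", "gt", gsub("-", "_", class_lab)))
  mm_per_px <- 25.4 / dpi

  date_val <- attr(mask, "date") %||% NA
  if (length(date_val) != 1) date_val <- NA

  one_record <- function(sub, layer) {
    len_mm <- sum(sub$length_px) * mm_per_px
    bins <- bin_by_diameter(sub$length_px * mm_per_px, sub$diameter_mm)
    out <- tibble::tibble(
      tube = attr(mask, "tube") %||% geom$tube,
      date = date_val,
      layer = layer,
      length_mm = len_mm,
      area_mm2 = surface_area(sub$length_px * mm_per_px, sub$diameter_mm),
      image_area_cm2 = area_cm2,
      length_per_area = len_mm / area_cm2)
    out[class_cols] <- as.list(bins$length)
    out
  }

  if (nrow(px_info) == 0) {
    return(dplyr::bind_rows(lapply(c(labels, "total"), function(l) {
      one_record(px_info, l)
    })))
  }
  depth <- suppressWarnings(depth_of_row(px_info$row, geom))
  cuts <- c(0, boundaries[-length(boundaries)], Inf)
  layer_idx <- findInterval(depth, cuts, rightmost.closed = FALSE)
  layer_idx <- pmin(pmax(layer_idx, 1L), length(labels))
  recs <- lapply(seq_along(labels), function(i) {
    one_record(px_info[layer_idx == i, , drop = FALSE], labels[i])
  })
  recs <- c(recs, list(one_record(px_info, "total")))
  dplyr::bind_rows(recs)
}

#' Express a trait record per unit rhizotron image area
#'
#' @param record a trait tibble with a `length_mm` column.
#' @param geom a [tube_geometry()]; its unmasked image area must be > 0.
#' @return `record` with `image_area_cm2` and `length_per_area`
#'   (mm cm^-2) set.
#' @export
normalize_per_area <- function(record, geom) {
  area <- image_area_cm2(geom)
  if (!is.finite(area) || area <= 0) {
    stop("image area must be positive", call. = FALSE)
  }
  dplyr::mutate(record, image_area_cm2 = area,
                length_per_area = .data$length_mm / area)
}

#' Specific root length
#'
#' SRL (m g^-1) of washed root samples: length divided by dry mass.
#'
#' @param length_m root length in m.
#' @param dry_mass_g dry mass in g; must be positive.
#' @return SRL in m g^-1 (vectorized).
#' @export
compute_srl <- function(length_m, dry_mass_g) {
  if (any(dry_mass_g <= 0)) {
    stop("`dry_mass_g` must be positive", call. = FALSE)
  }
  length_m / dry_mass_g
}
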