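#' Rhizotron scan frames and binary root masks
#'
#' A `scan_frame` is a grayscale raster (numeric matrix, values in 0--255)
#' with the acquisition metadata the pipeline needs: dots-per-inch, tube id,
#' scan date and scanner position (`"upper"`/`"lower"` half of the tube, or
#' `"merged"`). Row 1 is the soil-surface end of the tube; rows increase
#' along the tube into the soil and columns span the unrolled circumference.
#'
#' @param pixels numeric matrix, values in `[0, 255]`.
#' @param dpi scan resolution in dots per inch (field scanners: 1200).
#' @param tube,date,position optional metadata carried through the pipeline.
#' @return A `scan_frame` object (matrix subclass).
#' @examples
#' fr <- scan_frame(matrix(runif(100, 0, 255), 10, 10), dpi = 1200)
#' dim(fr)
#' @export
scan_frame <- function(pixels, dpi = 1200, tube = NA_character_,
                       date = NA, position = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255] and contain no NA", call. = FALSE)
  }
  if (!is.numeric(dpi) || length(dpi) != 1 || dpi <= 0) {
    stop("`dpi` must be a single positive number", call. = FALSE)
  }
  structure(pixels, class = c("scan_frame", "matrix"),
            dpi = dpi, tube = tube, date = date, position = position)
}

# rebuild a frame from new pixels, keeping metadata of `template`
frame_like <- function(pixels, template, clip = TRUE) {
  if (clip) pixels <- pmin(pmax(pixels, 0), 255)
  scan_frame(unclass_mat(pixels),
             dpi = attr(template, "dpi") %||% 1200,
             tube = attr(template, "tube") %||% NA_character_,
             date = attr(template, "date") %||% NA,
             position = attr(template, "position") %||% NA_character_)
}

unclass_mat <- function(x) {
  x <- as.matrix(x)
  attributes(x) <- list(dim = dim(x))
  x
}

#' @export
print.scan_frame <- function(x, ...) {
  cat(sprintf("<scan_frame> %d x %d px, %g dpi, tube=%s date=%s position=%s\n",
              nrow(x), ncol(x), attr(x, "dpi"),
              attr(x, "tube"), format(attr(x, "date")), attr(x, "position")))
  invisible(x)
}

#' Binary root mask
#'
#' A raster congruent with its source frame in which 1 marks root pixels and
#' 0 soil, together with the provenance of the segmentation (`"classical"`
#' for the built-in ridge segmenter, `"oracle"` for generator ground truth,
#' `"imported"` for masks produced elsewhere, e.g. by a neural model).
#'
#' @param pixels matrix of 0/1 (or logical).
#' @param dpi dots per inch of the source frame.
#' @param tube,date metadata.
#' @param provenance one of `"classical"`, `"oracle"`, `"imported"`.
#' @return A `root_mask` object (integer matrix subclass).
#' @export
root_mask <- function(pixels, dpi = 1200, tube = NA_character_, date = NA,
                      provenance = c("classical", "oracle", "imported")) {
  provenance <- match.arg(provenance)
  m <- unclass_mat(pixels)
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop("mask values must be 0/1", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  structure(m, class = c("root_mask", "matrix"),
            dpi = dpi, tube = tube, date = date, provenance = provenance)
}

#' @export
print.root_mask <- function(x, ...) {
  cat(sprintf("<root_mask> %d x %d px (%.2f%% root), provenance=%s\n",
              nrow(x), ncol(x), 100 * mean(x), attr(x, "provenance")))
  invisible(x)
}

#' Read / write 8-bit grayscale PNG rasters
#'
#' Thin wrappers over the png package keeping the pipeline's
#' row-1-at-soil-surface orientation and 0--255 value convention.
#'
#' @param path file path.
#' @param dpi,tube,date,position metadata attached to the returned frame.
#' @return `read_scan_png()` returns a [scan_frame()]; `write_scan_png()`
#'   returns `path` invisibly.
#' @export
read_scan_png <- function(path, dpi = 1200, tube = NA_character_,
                          date = NA, position = NA_character_) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  scan_frame(round(a * 255), dpi = dpi, tube = tube, date = date,
             position = position)
}

#' @param frame a [scan_frame()] or [root_mask()].
#' @rdname read_scan_png
#' @export
write_scan_png <- function(frame, path) {
  m <- unclass_mat(frame)
  if (inherits(frame, "root_mask")) m <- m * 255
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Minirhizotron tube geometry
#'
#' Physical and optical parameters that map image pixels to soil depth:
#' the soil--tube angle, the number of image rows hidden by light-blocking
#' tape at the soil surface, the scan resolution, and the merged-image
#' extent. The field installation aimed at 45 degrees; realized angles
#' ranged roughly 32--61 degrees with a mean near 42.7.
#'
#' @param tube tube identifier.
#' @param angle_deg soil--tube angle in degrees, strictly between 0 and 90.
#' @param tape_rows image rows covered by tape at the soil-surface end.
#' @param dpi scan resolution (dots per inch).
#' @param image_rows,image_cols extent of the merged image in pixels.
#' @return A `tube_geometry` list object.
#' @examples
#' g <- tube_geometry("T01", angle_deg = 42.7, tape_rows = 40,
#'                    dpi = 1200, image_rows = 15000, image_cols = 2000)
#' depth_of_row(5000, g)
#' @export
tube_geometry <- function(tube = NA_character_, angle_deg = 45, tape_rows = 0,
                          dpi = 1200, image_rows, image_cols) {
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg >= 90) {
    stop("`angle_deg` must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  if (tape_rows < 0) stop("`tape_rows` must be >= 0", call. = FALSE)
  if (dpi <= 0) stop("`dpi` must be positive", call. = FALSE)
  if (image_rows <= 0 || image_cols <= 0) {
    stop("image extent must be positive", call. = FALSE)
  }
  structure(list(tube = tube, angle_deg = angle_deg, tape_rows = tape_rows,
                 dpi = dpi, image_rows = as.integer(image_rows),
                 image_cols = as.integer(image_cols)),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf(
    "<tube_geometry> tube=%s angle=%.1f deg, tape_rows=%d, %d x %d px @ %g dpi (area %.1f cm^2)\n",
    x$tube, x$angle_deg, x$tape_rows, x$image_rows, x$image_cols, x$dpi,
    image_area_cm2(x)))
  invisible(x)
}

#' Unmasked image area of a tube in cm^2
#'
#' The soil-facing image area below the tape, used to express root length
#' per unit rhizotron image area (mm cm^-2).
#'
#' @param geom a [tube_geometry()].
#' @return Area in cm^2.
#' @export
image_area_cm2 <- function(geom) {
  px_cm <- 2.54 / geom$dpi
  (geom$image_rows - geom$tape_rows) * px_cm * geom$image_cols * px_cm
}
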