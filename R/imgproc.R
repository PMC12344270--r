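#' Blacken the light-blocking tape region of a scan
#'
#' The upper scan of each tube shows the light-blocking tape wrapped around
#' the tube near the soil surface; those pixels carry no root signal and are
#' replaced by black (0) using a per-tube binary mask.
#'
#' @param frame a [scan_frame()].
#' @param mask binary matrix congruent with `frame`; 1 marks tape pixels.
#' @return A [scan_frame()] with masked pixels set to 0.
#' @export
apply_tape_mask <- function(frame, mask) {
  m <- unclass_mat(mask)
  if (!all(dim(m) == dim(frame))) {
    stop("tape mask dimensions must match the frame", call. = FALSE)
  }
  px <- unclass_mat(frame)
  px[m != 0] <- 0
  frame_like(px, frame, clip = FALSE)
}

#' Merge the upper and lower scan of a tube into one image
#'
#' Two scans are needed to cover a tube's belowground extent; they are
#' stacked vertically into a single raster. Within the overlap band the
#' upper frame's pixels take precedence.
#'
#' @param upper,lower [scan_frame()]s of equal width.
#' @param overlap_px number of rows shared by the bottom of `upper` and the
#'   top of `lower` (default 0, i.e. plain concatenation).
#' @return A merged [scan_frame()] with
#'   `nrow(upper) + nrow(lower) - overlap_px` rows, `position = "merged"`.
#' @export
merge_scan_pair <- function(upper, lower, overlap_px = 0L) {
  if (ncol(upper) != ncol(lower)) {
    stop("scan pair must have equal widths", call. = FALSE)
  }
  if (overlap_px < 0 || overlap_px > nrow(lower)) {
    stop("`overlap_px` must be between 0 and nrow(lower)", call. = FALSE)
  }
  lo <- unclass_mat(lower)
  keep <- if (overlap_px < nrow(lo)) {
    lo[(overlap_px + 1):nrow(lo), , drop = FALSE]
  } else {
    lo[0, , drop = FALSE]
  }
  out <- rbind(unclass_mat(upper), keep)
  res <- frame_like(out, upper, clip = FALSE)
  attr(res, "position") <- "merged"
  res
}

# integer translation with zero fill; positive dy moves content down (towards
# larger row indices), positive dx towards larger columns
translate_px <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rs) > 0 && length(cs) > 0 && rs[1] <= rs[length(rs)] &&
      cs[1] <= cs[length(cs)]) {
    out[rs, cs] <- m[rs - dy, cs - dx]
  }
  out
}

# integer planar shift of `frame` relative to `reference` by phase
# correlation; returns c(dy, dx) such that translating frame by (dy, dx)
# aligns it to the reference
phase_correlation_shift <- function(frame, reference) {
  a <- unclass_mat(reference); b <- unclass_mat(frame)
  Fa <- fft(a); Fb <- fft(b)
  R <- Fb * Conj(Fa)
  mod <- Mod(R)
  mod[mod < .Machine$double.eps] <- 1
  r <- Re(fft(R / mod, inverse = TRUE))
  ij <- which(r == max(r), arr.ind = TRUE)[1, ]
  dy <- unname(ij[1]) - 1L
  dx <- unname(ij[2]) - 1L
  if (dy > nrow(a) / 2) dy <- dy - nrow(a)
  if (dx > ncol(a) / 2) dx <- dx - ncol(a)
  c(dy = -dy, dx = -dx)
}

#' Register a scan to the tube's reference image
#'
#' Estimates the integer planar shift between `frame` and `reference` by
#' phase correlation and returns the frame translated onto the reference,
#' with out-of-canvas pixels filled with 0. Only rigid planar shifts are
#' modelled: the tubes are rigid, so the repeated scans differ by scanner
#' placement, not deformation.
#'
#' @param frame,reference [scan_frame()]s of identical dimensions.
#' @return A list with `frame` (the registered [scan_frame()]) and `shift`
#'   (`c(dy, dx)` in pixels, the translation that was applied).
#' @export
register_to_reference <- function(frame, reference) {
  if (!all(dim(frame) == dim(reference))) {
    stop("frame and reference must have identical dimensions", call. = FALSE)
  }
  if (sd(frame) == 0 || sd(reference) == 0) {
    warning("flat (zero-variance) image: returning zero shift")
    return(list(frame = frame, shift = c(dy = 0L, dx = 0L)))
  }
  sh <- phase_correlation_shift(frame, reference)
  out <- translate_px(unclass_mat(frame), sh[["dy"]], sh[["dx"]])
  list(frame = frame_like(out, frame, clip = FALSE), shift = sh)
}

#' Suppress column striping artifacts
#'
#' Flatbed-type tube scanners leave additive column banding. Column medians
#' are robustly detrended with a wide running median and the residual
#' per-column offset subtracted; output is clipped to `[0, 255]`.
#' Stripe-free images pass through essentially unchanged.
#'
#' @param frame a [scan_frame()].
#' @param trend_halfwidth half-width (columns) of the running-median
#'   detrend window; the default adapts to image width.
#' @param min_offset offsets at or below this magnitude (grey levels) are
#'   ignored: ordinary column-median jitter of stripe-free images stays
#'   untouched, only genuine banding is corrected.
#' @return A de-striped [scan_frame()].
#' @export
remove_stripes <- function(frame, trend_halfwidth = NULL, min_offset = 2.5) {
  px <- unclass_mat(frame)
  nc <- ncol(px)
  if (nc < 5) return(frame)
  col_med <- apply(px, 2, median)
  hw <- trend_halfwidth %||% max(10L, ceiling(nc / 16))
  k <- min(2L * hw + 1L, if (nc %% 2 == 1) nc else nc - 1L)
  trend <- runmed(col_med, k = k, endrule = "median")
  offset <- col_med - trend
  offset[abs(offset) <= min_offset] <- 0
  out <- sweep(px, 2, offset, "-")
  frame_like(out, frame)
}

#' Percentile-based contrast and brightness normalization
#'
#' Linearly rescales intensities so the `low_pct` and `high_pct` intensity
#' percentiles map to 0 and 255, clipping beyond. Brings scans taken under
#' varying illumination onto a common intensity scale before segmentation.
#'
#' @param frame a [scan_frame()].
#' @param low_pct,high_pct percentile anchors as fractions,
#'   `0 <= low_pct < high_pct <= 1` (defaults 0.01 / 0.99).
#' @param max_gain upper bound on the rescaling gain (default unbounded).
#'   The pipeline bounds it at 2: an (almost) root-free scan has hardly
#'   any genuine contrast, and amplifying its soil texture to the full
#'   range would only hand noise to the segmenter.
#' @return A normalized [scan_frame()].
#' @export
normalize_contrast <- function(frame, low_pct = 0.01, high_pct = 0.99,
                               max_gain = Inf) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 1)) {
    stop("need 0 <= low_pct < high_pct <= 1", call. = FALSE)
  }
  px <- unclass_mat(frame)
  q <- quantile(px, c(low_pct, high_pct), names = FALSE, type = 7)
  if (diff(q) == 0) {
    warning("constant image: contrast normalization skipped")
    return(frame)
  }
  gain <- min(255 / (q[2] - q[1]), max_gain)
  out <- (px - q[1]) * gain
  frame_like(out, frame)
}

#' Standard preprocessing of one scan pair
#'
#' Applies the full preparation chain used before segmentation: tape
#' masking on the upper scan, merging of the pair, registration to the
#' tube's reference image (the first merged image of the time-series,
#' if given), de-striping and percentile normalization.
#'
#' @param upper,lower [scan_frame()]s of one tube and date.
#' @param tape_mask binary matrix congruent with `upper`, or `NULL`.
#' @param reference merged reference [scan_frame()] or `NULL` to skip
#'   registration.
#' @param overlap_px rows of overlap between the scans.
#' @return A list with the merged, preprocessed `frame` and the estimated
#'   registration `shift`.
#' @export
preprocess_scan_pair <- function(upper, lower, tape_mask = NULL,
                                 reference = NULL, overlap_px = 0L) {
  if (!is.null(tape_mask)) upper <- apply_tape_mask(upper, tape_mask)
  merged <- merge_scan_pair(upper, lower, overlap_px = overlap_px)
  shift <- c(dy = 0L, dx = 0L)
  if (!is.null(reference)) {
    reg <- register_to_reference(merged, reference)
    merged <- reg$frame
    shift <- reg$shift
  }
  merged <- remove_stripes(merged)
  merged <- normalize_contrast(merged, max_gain = 2)
  list(frame = merged, shift = shift)
}
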