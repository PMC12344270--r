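#' Segmentation parameters for the classical ridge segmenter
#'
#' Roots appear as bright curvilinear ridges on the darker soil background.
#' The segmenter computes a multiscale Hessian ridge (tubeness) response
#' over the expected root-width range, applies hysteresis thresholding and
#' removes small connected components. Defaults were tuned once on a
#' held-out synthetic scene set and frozen.
#'
#' @param scale_range_mm root widths (mm) spanned by the analysis scales.
#' @param n_scales number of log-spaced scales across that range.
#' @param threshold_hi,threshold_lo hysteresis thresholds on the ridge
#'   response (intensity units of the normalized 0--255 frame).
#' @param intensity_k robust brightness gate: candidate root pixels must
#'   be brighter than `median + intensity_k * MAD` of the frame. Roots
#'   are bright outliers over the soil background, so the gate removes
#'   the dim halo the ridge response leaves around each root while
#'   adapting to scene brightness.
#' @param min_object_px connected components smaller than this are removed.
#' @param max_hole_px enclosed background holes up to this size are
#'   filled: speckle holes inside a root stroke would otherwise fragment
#'   the skeleton into spurious loops that inflate length.
#' @return A `seg_params` list.
#' @export
seg_params <- function(scale_range_mm = c(0.1, 0.6), n_scales = 3,
                       threshold_hi = 15, threshold_lo = 5,
                       intensity_k = 3,
                       min_object_px = 30, max_hole_px = 25) {
  stopifnot(length(scale_range_mm) == 2, all(scale_range_mm > 0),
            scale_range_mm[1] <= scale_range_mm[2],
            threshold_lo <= threshold_hi, min_object_px >= 0,
            intensity_k >= 0, max_hole_px >= 0)
  structure(list(scale_range_mm = scale_range_mm, n_scales = n_scales,
                 threshold_hi = threshold_hi, threshold_lo = threshold_lo,
                 intensity_k = intensity_k,
                 min_object_px = min_object_px, max_hole_px = max_hole_px),
            class = "seg_params")
}

# scale-normalized bright-ridge response: -lambda2 * sigma^2 where lambda2
# is the more negative Hessian eigenvalue of the Gaussian-smoothed image;
# finite-difference Hessian via index shifts (replicated borders)
ridge_response <- function(px, sigma) {
  sm <- unclass_mat(EBImage::gblur(px, sigma = sigma))
  nr <- nrow(sm); nc <- ncol(sm)
  up <- sm[c(1, seq_len(nr - 1)), ]; down <- sm[c(seq_len(nr - 1) + 1, nr), ]
  left <- sm[, c(1, seq_len(nc - 1))]; right <- sm[, c(seq_len(nc - 1) + 1, nc)]
  hrr <- up + down - 2 * sm
  hcc <- left + right - 2 * sm
  ul <- sm[c(1, seq_len(nr - 1)), c(1, seq_len(nc - 1))]
  dr_ <- sm[c(seq_len(nr - 1) + 1, nr), c(seq_len(nc - 1) + 1, nc)]
  ur <- sm[c(1, seq_len(nr - 1)), c(seq_len(nc - 1) + 1, nc)]
  dl <- sm[c(seq_len(nr - 1) + 1, nr), c(1, seq_len(nc - 1))]
  hrc <- (ul + dr_ - ur - dl) / 4
  tr <- hrr + hcc
  disc <- sqrt(pmax((hrr - hcc)^2 + 4 * hrc^2, 0))
  l_low <- (tr - disc) / 2   # more negative eigenvalue on bright ridges
  l_high <- (tr + disc) / 2
  resp <- pmax(-l_low, 0) * sigma^2
  # blob suppression (Frangi): a ridge has l_high ~ 0 while a bright blob
  # has both eigenvalues comparably negative; damp the latter
  ratio2 <- ifelse(l_low < 0 & l_high < 0, (l_high / l_low)^2, 0)
  resp * exp(-ratio2 / 0.5)
}

#' Segment roots in a preprocessed scan
#'
#' Deterministic classical stand-in for a trained pixel classifier: a
#' multiscale Hessian ridge detector over root-width scales, hysteresis
#' thresholding and small-object removal. Any externally produced mask
#' (e.g. from a neural model) can be scored through the same
#' [evaluate_segmentation()] interface.
#'
#' @param frame a preprocessed [scan_frame()].
#' @param params a [seg_params()] list.
#' @param exclude_rows top image rows excluded from the mask (the black
#'   tape band plus a small margin: the tape/soil step edge otherwise
#'   reads as a spurious bright ridge).
#' @return A [root_mask()] with provenance `"classical"`.
#' @export
segment_roots <- function(frame, params = seg_params(), exclude_rows = 0) {
  dpi <- attr(frame, "dpi") %||% 1200
  w_px <- params$scale_range_mm * dpi / 25.4
  # top scale capped: beyond sigma ~4 px the ridge filter starts answering
  # to coarse soil texture; wider roots are still captured through their
  # hysteresis-connected cores
  sigmas <- exp(seq(log(max(w_px[1] / 2, 0.8)),
                    log(min(max(w_px[2] / 2, 0.9), 4)),
                    length.out = params$n_scales))
  if (max(w_px) >= min(dim(frame)) / 2 || max(sigmas) >= min(dim(frame)) / 4) {
    stop("scale range outside image resolution: root widths of ",
         paste(signif(w_px, 3), collapse = "-"),
         " px do not fit a ", nrow(frame), " x ", ncol(frame), " image",
         call. = FALSE)
  }
  px <- unclass_mat(frame)
  resp <- matrix(0, nrow(px), ncol(px))
  for (s in sigmas) resp <- pmax(resp, ridge_response(px, s))
  med <- median(px)
  mad_px <- median(abs(px - med)) * 1.4826
  # in very sparse scenes percentile normalization clips roots at the top
  # of the range while stretching soil noise; cap the gate just below the
  # ceiling so clipped roots always remain candidates
  gate <- px > min(med + params$intensity_k * mad_px, 245)
  strong <- resp >= params$threshold_hi & gate
  weak <- resp >= params$threshold_lo & gate
  mask <- hysteresis_select(strong, weak)
  if (exclude_rows > 0) mask[seq_len(min(exclude_rows, nrow(mask))), ] <- 0L
  mask <- fill_small_holes(mask, params$max_hole_px)
  mask <- drop_small_components(mask, params$min_object_px)
  root_mask(mask, dpi = dpi, tube = attr(frame, "tube"),
            date = attr(frame, "date"), provenance = "classical")
}

# fill enclosed background holes below max_px: speckle holes inside root
# strokes fragment the skeleton into spurious loops and branches that
# inflate length, while genuine soil windows between crossing roots are
# larger and stay open
fill_small_holes <- function(mask, max_px) {
  if (max_px <= 0 || !any(mask == 1L)) return(mask)
  inv <- 1L - mask
  lbl <- unclass_mat(EBImage::bwlabel(inv))
  border_labels <- unique(c(lbl[1, ], lbl[nrow(lbl), ], lbl[, 1],
                            lbl[, ncol(lbl)]))
  sizes <- tabulate(lbl[lbl > 0])
  hole_ids <- setdiff(which(sizes <= max_px), border_labels)
  if (length(hole_ids) > 0) mask[lbl %in% hole_ids] <- 1L
  mask
}

# keep weak-threshold components that contain at least one strong pixel
hysteresis_select <- function(strong, weak) {
  if (!any(weak)) return(matrix(0L, nrow(weak), ncol(weak)))
  lbl <- unclass_mat(EBImage::bwlabel(weak))
  keep <- unique(lbl[strong & lbl > 0])
  out <- matrix(0L, nrow(weak), ncol(weak))
  out[lbl %in% keep & lbl > 0] <- 1L
  out
}

drop_small_components <- function(mask, min_px) {
  if (min_px <= 0 || !any(mask == 1L)) return(mask)
  lbl <- unclass_mat(EBImage::bwlabel(mask))
  sizes <- tabulate(lbl[lbl > 0])
  small <- which(sizes < min_px)
  mask[lbl %in% small] <- 0L
  mask
}

#' Score a segmentation against ground truth
#'
#' Pixelwise precision (`TP / (TP + FP)`), recall (`TP / (TP + FN)`) and
#' their harmonic mean. An empty prediction against a non-empty truth
#' scores precision 0; two empty masks score 1.
#'
#' @param pred,truth congruent [root_mask()]s or binary matrices.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `n_pixels`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  p <- unclass_mat(pred) != 0
  t_ <- unclass_mat(truth) != 0
  if (!all(dim(p) == dim(t_))) {
    stop("prediction and truth dimensions differ", call. = FALSE)
  }
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_)
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_pixels = length(p))
}
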