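# Morphological skeletonization (Guo-Hall two-subiteration thinning) and
# raster length estimation by polygonal resampling of traced chains.
# These primitives back every root-length figure the pipeline reports, so
# they are implemented and validated against analytic oracles rather than
# delegated.

# shift a matrix by (dr, dc), zero fill: out[r, c] = m[r - dr, c - dc]
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Guo--Hall two-subiteration thinning (compiled). Produces 8-connected,
#' one-pixel-wide skeletons with few staircase artifacts, which keeps the
#' downstream chain-based length estimator low-bias.
#'
#' @param mask binary matrix (or [root_mask()]); nonzero = foreground.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
thin_mask <- function(mask) {
  m <- unclass_mat(mask) != 0
  storage.mode(m) <- "integer"
  if (!any(m == 1L)) return(m)
  guo_hall_thin(m)
}

# Count skeleton adjacency steps. Axial edges are counted to the east and
# south; diagonal edges only when no shared axial neighbour completes a
# triangle (in which case the path runs through the corner pixel and the
# diagonal is a shortcut, not a step).
skeleton_edge_counts <- function(skel) {
  s <- unclass_mat(skel) != 0
  storage.mode(s) <- "integer"
  e  <- s * shift_mat(s, 0, -1)
  so <- s * shift_mat(s, -1, 0)
  se <- s * shift_mat(s, -1, -1)
  sw <- s * shift_mat(s, -1, 1)
  se_ok <- se * ((shift_mat(s, 0, -1) + shift_mat(s, -1, 0)) == 0L)
  sw_ok <- sw * ((shift_mat(s, 0, 1) + shift_mat(s, -1, 0)) == 0L)
  list(axial = e + so, diag = se_ok + sw_ok,
       n_axial = sum(e) + sum(so), n_diag = sum(se_ok) + sum(sw_ok))
}

# Kimura corner-count length from axial/diagonal step counts
kimura_length <- function(n_axial, n_diag) {
  sqrt(n_diag^2 + (n_diag + n_axial / 2)^2) + n_axial / 2
}

# skeleton endpoints (exactly one 8-neighbour); tip correction adds the
# local root radius lost by thinning: max(EDT - 1, 0) per endpoint, which
# is zero for one-pixel-wide lines
tip_correction <- function(skel, edt) {
  s <- unclass_mat(skel) != 0
  storage.mode(s) <- "integer"
  nb <- shift_mat(s, 1, 0) + shift_mat(s, -1, 0) +
    shift_mat(s, 0, 1) + shift_mat(s, 0, -1) +
    shift_mat(s, 1, 1) + shift_mat(s, 1, -1) +
    shift_mat(s, -1, 1) + shift_mat(s, -1, -1)
  corr <- matrix(0, nrow(s), ncol(s))
  ends <- s == 1L & nb == 1L
  corr[ends] <- pmax(edt[ends] - 1, 0)
  corr
}

# Per-pixel length increments: each retained edge contributes half its raw
# length (1 or sqrt(2)) to both endpoints, then all increments are rescaled
# so they sum exactly to the polygonal path total; endpoint pixels
# additionally receive the tip correction when the distance transform is
# supplied. Guarantees exact conservation under any partition of skeleton
# pixels (depth layers, diameter classes).
skeleton_length_increments <- function(skel, edt = NULL) {
  ec <- skeleton_edge_counts(skel)
  s <- unclass_mat(skel) != 0
  storage.mode(s) <- "integer"
  inc <- matrix(0, nrow(s), ncol(s))
  half <- function(edge_mat, dr, dc, w) {
    # edge between (r, c) and (r + dr, c + dc): edge_mat marks (r, c)
    inc <<- inc + w / 2 * edge_mat                     # near endpoint
    inc <<- inc + w / 2 * shift_mat(edge_mat, dr, dc)  # far endpoint
  }
  e  <- s * shift_mat(s, 0, -1)
  so <- s * shift_mat(s, -1, 0)
  se_ok <- (s * shift_mat(s, -1, -1)) *
    ((shift_mat(s, 0, -1) + shift_mat(s, -1, 0)) == 0L)
  sw_ok <- (s * shift_mat(s, -1, 1)) *
    ((shift_mat(s, 0, 1) + shift_mat(s, -1, 0)) == 0L)
  # e marks the pixel having an E neighbour, so the S, SE, SW counterparts
  half(e, 0, 1, 1); half(so, 1, 0, 1)
  half(se_ok, 1, 1, sqrt(2)); half(sw_ok, 1, -1, sqrt(2))
  raw_total <- ec$n_axial + sqrt(2) * ec$n_diag
  total <- skeleton_path_length(s, 4L)
  if (raw_total > 0) inc <- inc * (total / raw_total)
  if (!is.null(edt)) {
    corr <- tip_correction(skel, edt)
    inc <- inc + corr
    total <- total + sum(corr)
  }
  list(increments = inc, length_px = total)
}

#' Skeletonize a root mask and measure total root length
#'
#' Thins the mask to a one-pixel skeleton, traces its chain paths
#' (8-connected, shortcut diagonals excluded) and measures each path by
#' polygonal resampling: the sum of Euclidean chords between chain points
#' four steps apart, with a closing chord for the remainder. Unlike pure
#' step-count corner formulas -- whose orientation-dependent bias reaches
#' ~2.7% on shallow oblique lines -- the resampled estimate stays within
#' about 1% of analytic length at every orientation (lines, arcs,
#' circles). Pixel length converts to mm via `25.4 / dpi`.
#'
#' @param mask a [root_mask()] or binary matrix.
#' @param dpi scan resolution; taken from the mask attribute if absent.
#' @param tip_correction add the local root radius (from the distance
#'   transform, `max(EDT - 1, 0)`) at each skeleton endpoint. Useful for
#'   masks whose strokes end flat (thinning erodes such tips); masks of
#'   real or rendered roots end in rounded caps that already compensate,
#'   so the default is off.
#' @return A list with `length_mm`, `length_px`, and the `skeleton`
#'   (0/1 integer matrix).
#' @examples
#' m <- matrix(0L, 20, 120); m[10, 10:110] <- 1L
#' skeletonize_and_measure(m, dpi = 1200)$length_mm  # 100 px = 2.117 mm
#' @export
skeletonize_and_measure <- function(mask, dpi = NULL, tip_correction = FALSE) {
  dpi <- dpi %||% attr(mask, "dpi") %||% 1200
  skel <- thin_mask(mask)
  if (!any(skel == 1L)) {
    return(list(length_mm = 0, length_px = 0, skeleton = skel))
  }
  edt <- if (tip_correction) {
    unclass_mat(EBImage::distmap(unclass_mat(mask)))
  } else NULL
  sli <- skeleton_length_increments(skel, edt = edt)
  list(length_mm = sli$length_px * 25.4 / dpi, length_px = sli$length_px,
       skeleton = skel)
}
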