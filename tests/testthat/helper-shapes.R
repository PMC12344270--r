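# analytic raster shapes used as length/diameter oracles

# strip class/metadata so raster contents can be compared directly
strip <- function(x) {
  x <- as.matrix(x)
  attributes(x) <- list(dim = dim(x))
  x
}

draw_bar <- function(nrow_, ncol_, row_center, col_from, col_to, width) {
  m <- matrix(0L, nrow_, ncol_)
  half <- (width - 1) / 2
  m[(row_center - floor(half)):(row_center + ceiling(half)),
    col_from:col_to] <- 1L
  m
}

draw_diag <- function(size, n_steps, width = 3, offset = 10) {
  m <- matrix(0L, size, size)
  for (i in 0:n_steps) {
    r <- offset + i
    m[(r - (width %/% 2)):(r + (width %/% 2)), offset + i] <- 1L
  }
  m
}

draw_ring <- function(r_out, r_in, size = ceiling(2 * r_out) + 20) {
  cx <- size / 2
  d <- sqrt(outer((1:size - cx)^2, (1:size - cx)^2, "+"))
  matrix(as.integer(d <= r_out & d >= r_in), size, size)
}

# smooth oblique stroke: discs of radius width/2 stamped at fine spacing
# along the continuous line, as a scanned root would appear
draw_oblique <- function(angle_rad, length_px, width = 3, pad = 15) {
  nr <- ceiling(abs(length_px * sin(angle_rad))) + 2 * pad
  nc <- ceiling(length_px * cos(angle_rad)) + 2 * pad
  m <- matrix(0L, nr, nc)
  rad <- width / 2
  # stamp centres inset by the cap radius so the stroke spans length_px
  t <- seq(rad, length_px - rad, by = 0.25)
  pr <- pad + t * sin(angle_rad); pc <- pad + t * cos(angle_rad)
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                     dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 0.25, ]
  rr <- outer(round(pr), off$dr, "+"); cc <- outer(round(pc), off$dc, "+")
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  m[cbind(rr[ok], cc[ok])] <- 1L
  m
}

# soil-textured frame with a set of drawn strands, for segmentation tests
synthetic_scene <- function(seed = 1, n_dates = 15, drought = "control",
                            degradations = degradation_params()) {
  curve <- gen_growth_curve(drought = drought, seed = seed)$curve
  geom <- synth_tube_geometry()
  list(seq = gen_image_sequence(geom, curve, seed = seed + 1000,
                                degradations = degradations),
       geom = geom, curve = curve)
}

# preprocess one scan pair of a generated sequence the way the pipeline does
prep_scan <- function(seqr, i, reference = NULL) {
  geom <- seqr$geometry
  sc <- seqr$scans[[i]]
  tape <- matrix(0L, nrow(sc$upper), ncol(sc$upper))
  if (geom$tape_rows > 0) tape[seq_len(geom$tape_rows), ] <- 1L
  ov <- nrow(sc$upper) + nrow(sc$lower) - geom$image_rows
  preprocess_scan_pair(sc$upper, sc$lower, tape_mask = tape,
                       reference = reference, overlap_px = ov)
}
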