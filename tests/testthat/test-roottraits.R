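test_that("skeleton length matches analytic length on canonical shapes", {
  # 1-px horizontal line spanning 101 px: 100 px path
  m <- matrix(0L, 20, 120); m[10, 10:110] <- 1L
  res <- skeletonize_and_measure(m, dpi = 1200)
  expect_equal(res$length_px, 100)
  expect_equal(res$length_mm, 100 * 25.4 / 1200, tolerance = 1e-10)

  # 45-degree diagonal of 101 px: 100 * sqrt(2)
  d <- matrix(0L, 130, 130)
  for (i in 0:100) d[12 + i, 12 + i] <- 1L
  expect_equal(skeletonize_and_measure(d, dpi = 1200)$length_px,
               100 * sqrt(2), tolerance = 1e-6)

  # thick circle radius 200: skeleton within 2% of circumference
  ring <- draw_ring(201.5, 198.5, 440)
  est <- skeletonize_and_measure(ring)$length_px
  expect_lt(abs(est - 2 * pi * 200) / (2 * pi * 200), 0.02)
})

test_that("length estimator stays within 2% on a suite of oracle shapes", {
  cases <- list(
    list(m = draw_bar(40, 360, 20, 30, 330, 3), len = 300),
    list(m = draw_bar(40, 360, 20, 30, 330, 2), len = 300),
    list(m = draw_bar(40, 460, 22, 30, 430, 4), len = 400),
    list(m = t(draw_bar(40, 360, 20, 30, 330, 3)), len = 300),
    list(m = draw_diag(340, 300, 3), len = 300 * sqrt(2)),
    list(m = draw_diag(340, 300, 2), len = 300 * sqrt(2)),
    list(m = draw_ring(101.5, 98.5), len = 2 * pi * 100),
    list(m = draw_ring(151.5, 148.5), len = 2 * pi * 150),
    list(m = draw_ring(152, 148), len = 2 * pi * 150),
    list(m = draw_oblique(pi / 6, 320, 3), len = 320),
    list(m = draw_oblique(pi / 8, 320, 3), len = 320),
    list(m = draw_oblique(0.2, 400, 2), len = 400))
  for (case in cases) {
    est <- skeletonize_and_measure(case$m)$length_px
    expect_lt(abs(est - case$len) / case$len, 0.02)
  }
})

test_that("per-pixel increments sum exactly to the corner-count total", {
  shapes <- list(draw_ring(101.5, 98.5), draw_diag(200, 160, 3),
                 draw_bar(40, 360, 20, 30, 330, 3))
  for (m in shapes) {
    skel <- thin_mask(m)
    sli <- rhizochron:::skeleton_length_increments(skel)
    expect_equal(sum(sli$increments), sli$length_px, tolerance = 1e-9)
  }
})

test_that("diameters recover known stroke widths", {
  # constant-width 0.25 mm strand at 1200 dpi: 11.8 px wide
  w_px <- round(0.25 * 1200 / 25.4)
  m <- draw_bar(60, 420, 30, 20, 400, w_px)
  di <- measure_diameters(m, dpi = 1200)
  med <- median(di$diameter_mm[!di$branch_point])
  expect_lt(abs(med - 0.25), 25.4 / 1200 + 1e-9)  # within one pixel

  # 1-px line: one pixel diameter
  l1 <- matrix(0L, 20, 120); l1[10, 10:110] <- 1L
  d1 <- measure_diameters(l1, dpi = 1200)
  expect_equal(median(d1$diameter_mm), 25.4 / 1200, tolerance = 1e-9)

  # two strands 0.2 / 0.8 mm: both modes recovered
  w1 <- round(0.2 * 1200 / 25.4); w2 <- round(0.8 * 1200 / 25.4)
  m2 <- draw_bar(120, 420, 25, 20, 400, w1) +
    draw_bar(120, 420, 85, 20, 400, w2)
  d2 <- measure_diameters(m2, dpi = 1200)
  top <- d2$diameter_mm[d2$row < 60]; bottom <- d2$diameter_mm[d2$row >= 60]
  expect_lt(abs(median(top) - 0.2), 0.03)
  expect_lt(abs(median(bottom) - 0.8), 0.03)
})

test_that("diameter binning is half-open, conserving, and rejects negatives", {
  b <- bin_by_diameter(rep(1, 10), rep(0.25, 10))
  expect_equal(b$length[b$class == "0.2-0.3"], 10)
  expect_equal(sum(b$length), 10)

  b1 <- bin_by_diameter(5, 1.0)
  expect_equal(b1$length[b1$class == ">1"], 5)
  b2 <- bin_by_diameter(5, 0.1)
  expect_equal(b2$length[b2$class == "0.1-0.2"], 5)

  set.seed(7)
  lens <- runif(500); dias <- rexp(500, 4)
  bm <- bin_by_diameter(lens, dias)
  expect_equal(sum(bm$length), sum(lens), tolerance = 1e-3 * sum(lens) * 0.001)

  expect_error(bin_by_diameter(1, -0.1), "negative")
})

test_that("surface area follows the cylindrical model", {
  expect_equal(surface_area(10, 0.3), pi * 0.3 * 10)
  expect_equal(surface_area(numeric(0), numeric(0)), 0)
  set.seed(8)
  # stable diameter distribution: length and area strongly correlated
  lens <- matrix(runif(50 * 20, 0.5, 2), 50)
  dias <- matrix(0.25 * exp(rnorm(50 * 20, 0, 0.08)), 50)
  totl <- rowSums(lens)
  tota <- vapply(1:50, function(i) surface_area(lens[i, ], dias[i, ]),
                 numeric(1))
  expect_gte(cor(totl, tota), 0.95)
})

test_that("row depth inverts the tube trigonometry", {
  g45 <- tube_geometry(angle_deg = 45, tape_rows = 0, dpi = 1200,
                       image_rows = 30000, image_cols = 100)
  row10 <- 1 + 10 / (2.54 / 1200)  # 10 cm along the tube
  expect_equal(depth_of_row(row10, g45), 10 * sin(pi / 4), tolerance = 1e-9)
  expect_equal(depth_of_row(row10, g45), 7.0711, tolerance = 1e-4)

  # mean field geometry: 30.53 cm along tube at 42.7 degrees is 20.7 cm deep
  g427 <- tube_geometry(angle_deg = 42.7, tape_rows = 0, dpi = 1200,
                        image_rows = 30000, image_cols = 100)
  row2070 <- 1 + 30.53 / (2.54 / 1200)
  expect_equal(depth_of_row(row2070, g427), 20.7, tolerance = 0.01)

  g89 <- tube_geometry(angle_deg = 89.999, tape_rows = 0, dpi = 1200,
                       image_rows = 30000, image_cols = 100)
  expect_equal(depth_of_row(row10, g89), 10, tolerance = 1e-4)

  expect_warning(d0 <- depth_of_row(1, tube_geometry(
    angle_deg = 45, tape_rows = 10, dpi = 1200,
    image_rows = 100, image_cols = 10)), "surface")
  expect_equal(unname(d0), 0)
})

test_that("depth splitting partitions length and area exactly", {
  # geometry: 45 deg, 600 dpi, rows span ~25 cm depth
  g <- tube_geometry(angle_deg = 45, tape_rows = 0, dpi = 600,
                     image_rows = 8400, image_cols = 60)
  # strand entirely above the 10 cm boundary row
  boundary_row <- 10 / sin(pi / 4) / (2.54 / 600)  # ~3341
  m <- matrix(0L, 8400, 60)
  m[500:2500, 30] <- 1L
  tr <- split_by_depth(m, g)
  expect_equal(tr$length_mm[tr$layer == "10-20"], 0)
  expect_gt(tr$length_mm[tr$layer == "0-10"], 0)

  # uniform vertical strand: layer lengths proportional to row extent
  m2 <- matrix(0L, 8400, 60); m2[10:8390, 30] <- 1L
  tr2 <- split_by_depth(m2, g)
  upper <- tr2$length_mm[tr2$layer == "0-10"]
  lower <- tr2$length_mm[tr2$layer == "10-20"]
  expect_equal(upper / (upper + lower), boundary_row / 8381, tolerance = 0.02)

  # partition: layers sum to total (within 0.5%); class sums to total
  set.seed(9)
  m3 <- matrix(0L, 8400, 60)
  for (s in 1:6) {
    r0 <- sample(100:8000, 1); m3[r0:(r0 + 300), sample(5:55, 1)] <- 1L
  }
  tr3 <- split_by_depth(m3, g)
  tot <- tr3[tr3$layer == "total", ]
  lay <- tr3[tr3$layer != "total", ]
  expect_equal(sum(lay$length_mm), tot$length_mm,
               tolerance = 0.005 * tot$length_mm)
  class_cols <- grep("^class_", names(tr3), value = TRUE)
  expect_equal(sum(tot[, class_cols]), tot$length_mm,
               tolerance = 0.001 * tot$length_mm)
  expect_equal(sum(lay$area_mm2), tot$area_mm2,
               tolerance = 0.005 * tot$area_mm2)
})

test_that("per-area normalization and SRL are plain quotients with guards", {
  rec <- tibble::tibble(length_mm = 21600)
  g <- tube_geometry(angle_deg = 45, tape_rows = 0, dpi = 1200,
                     image_rows = round(sqrt(540) / (2.54 / 1200)),
                     image_cols = round(sqrt(540) / (2.54 / 1200)))
  out <- normalize_per_area(rec, g)
  expect_equal(out$length_per_area, 21600 / out$image_area_cm2)
  expect_equal(out$length_per_area, 40, tolerance = 0.01)

  expect_equal(normalize_per_area(tibble::tibble(length_mm = 0), g)$length_per_area, 0)
  # doubling both length and area leaves the density unchanged
  g2 <- tube_geometry(angle_deg = 45, tape_rows = 0, dpi = 1200,
                      image_rows = g$image_rows * 2, image_cols = g$image_cols)
  expect_equal(normalize_per_area(tibble::tibble(length_mm = 43200), g2)$length_per_area,
               out$length_per_area, tolerance = 1e-6)

  expect_equal(compute_srl(149, 1), 149)
  expect_equal(compute_srl(0, 2), 0)
  expect_equal(compute_srl(30, 0.2), 150)
  expect_error(compute_srl(10, 0), "positive")
})

test_that("mm-valued outputs are scale equivariant in dpi", {
  m1 <- draw_bar(60, 360, 30, 30, 330, 3)
  # double resolution: upsample shape by 2 in both axes
  m2 <- matrix(0L, 120, 720)
  idx <- which(m1 == 1L, arr.ind = TRUE)
  for (dr in 0:1) for (dc in 0:1) {
    m2[cbind(2 * idx[, 1] - dr, 2 * idx[, 2] - dc)] <- 1L
  }
  len1 <- skeletonize_and_measure(m1, dpi = 600)$length_mm
  len2 <- skeletonize_and_measure(m2, dpi = 1200)$length_mm
  expect_lt(abs(len2 - len1) / len1, 0.01)
})
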