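test_that("tape masking zeroes exactly the masked pixels", {
  set.seed(1)
  fr <- scan_frame(matrix(runif(200 * 100, 10, 250), 200, 100), dpi = 600)
  empty <- matrix(0L, 200, 100)
  expect_equal(strip(apply_tape_mask(fr, empty)), strip(fr))

  full <- matrix(1L, 200, 100)
  expect_true(all(apply_tape_mask(fr, full) == 0))

  top <- matrix(0L, 200, 100); top[1:100, ] <- 1L
  out <- apply_tape_mask(fr, top)
  expect_true(all(out[1:100, ] == 0))
  expect_identical(strip(out)[101:200, ], strip(fr)[101:200, ])

  expect_error(apply_tape_mask(fr, matrix(0L, 10, 10)), "dimensions")
})

test_that("scan pair merging stacks with upper precedence in the overlap", {
  set.seed(2)
  up <- scan_frame(matrix(runif(2000 * 50, 0, 255), 2000, 50))
  lo <- scan_frame(matrix(runif(2000 * 50, 0, 255), 2000, 50))

  m0 <- merge_scan_pair(up, lo, overlap_px = 0)
  expect_equal(nrow(m0), 4000)
  expect_identical(strip(m0), rbind(strip(up), strip(lo)))

  mfull <- merge_scan_pair(up, up, overlap_px = nrow(up))
  expect_identical(strip(mfull), strip(up))

  m150 <- merge_scan_pair(up, lo, overlap_px = 150)
  expect_equal(nrow(m150), 2000 + 2000 - 150)
  # merge inverse: splitting at the seam recovers both inputs outside
  # the overlap
  expect_identical(strip(m150)[1:2000, ], strip(up))
  expect_identical(strip(m150)[2001:3850, ], strip(lo)[151:2000, ])

  expect_error(merge_scan_pair(up, scan_frame(matrix(0, 10, 49))), "width")
})

test_that("phase-correlation registration recovers planar shifts exactly", {
  set.seed(3)
  base <- matrix(runif(200 * 150), 200, 150)
  k <- outer(dnorm(-3:3), dnorm(-3:3)); k <- k / sum(k)
  base <- as.matrix(EBImage::filter2(base, k)) * 255
  ref <- scan_frame(base)

  same <- register_to_reference(ref, ref)
  expect_equal(unname(same$shift), c(0L, 0L))

  for (case in list(c(3, 5), c(-7, 2), c(10, -10))) {
    shifted <- scan_frame(rhizochron:::translate_px(base, case[1], case[2]))
    reg <- register_to_reference(shifted, ref)
    expect_equal(unname(reg$shift), -case)
    # registered content matches reference away from the zero-filled rim
    inner_r <- 15:185; inner_c <- 15:135
    expect_gt(cor(as.vector(reg$frame[inner_r, inner_c]),
                  as.vector(base[inner_r, inner_c])), 0.99)
  }

  expect_warning(reg0 <- register_to_reference(
    scan_frame(matrix(100, 50, 50)), scan_frame(matrix(100, 50, 50))),
    "flat")
  expect_equal(unname(reg0$shift), c(0L, 0L))
})

test_that("integer shift estimate stays within 1 px of brute-force
           cross-correlation for subpixel true shifts", {
  set.seed(4)
  base <- matrix(runif(120 * 120), 120, 120)
  k <- outer(dnorm(-2:2), dnorm(-2:2)); k <- k / sum(k)
  base <- as.matrix(EBImage::filter2(base, k))
  # subpixel shift (2.5, 0) via interpolation of rows
  sub <- (base[1:118, ] + base[2:119, ]) / 2  # +0.5 px
  sub <- rbind(matrix(0, 2, 120), sub)        # +2 more
  frame <- scan_frame(pmin(pmax(sub * 255, 0), 255))
  reff <- scan_frame(pmin(pmax(base[1:120, ] * 255, 0), 255))
  est <- register_to_reference(frame, reff)$shift

  # brute-force cross-correlation over +-10 px
  best <- c(NA, NA); best_v <- -Inf
  for (dy in -10:10) for (dx in -10:10) {
    sh <- rhizochron:::translate_px(unclass(frame), dy, dx)
    v <- sum(sh * unclass(reff))
    if (v > best_v) { best_v <- v; best <- c(dy, dx) }
  }
  expect_lte(max(abs(unname(est) - best)), 1)
})

test_that("de-striping removes column banding and passes clean images", {
  set.seed(5)
  clean <- matrix(runif(300 * 160, 60, 140), 300, 160)
  k <- outer(dnorm(-3:3), dnorm(-3:3)); k <- k / sum(k)
  clean <- as.matrix(EBImage::filter2(clean, k))
  fr <- scan_frame(clean)

  out <- remove_stripes(fr)
  expect_lte(max(abs(out - clean)), 2)

  striped <- clean
  striped[, seq(8, 160, by = 8)] <- striped[, seq(8, 160, by = 8)] + 20
  ds <- remove_stripes(scan_frame(pmin(striped, 255)))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_gte(rmse(striped, clean) / rmse(strip(ds), clean), 5)

  flat <- scan_frame(matrix(77, 64, 64))
  expect_equal(strip(remove_stripes(flat)), matrix(77, 64, 64))

  # idempotence: a second pass changes almost nothing
  twice <- remove_stripes(ds)
  expect_lte(max(abs(strip(twice) - strip(ds))), 2)
})

test_that("percentile normalization maps anchors to the full range", {
  spanning <- scan_frame(matrix(seq(0, 255, length.out = 10000), 100, 100))
  out <- normalize_contrast(spanning, 0, 1)
  expect_equal(strip(out), strip(spanning), tolerance = 1e-10)

  two <- scan_frame(matrix(c(50, 100), 10, 10))
  out2 <- normalize_contrast(two, 0, 1)
  expect_equal(sort(unique(as.vector(out2))), c(0, 255))

  set.seed(6)
  u <- scan_frame(matrix(runif(300 * 300, 0, 255), 300, 300))
  out3 <- normalize_contrast(u, 0.01, 0.99)
  expect_gte(mean(out3 > 0 & out3 < 255), 0.975)

  expect_warning(out4 <- normalize_contrast(scan_frame(matrix(5, 10, 10))),
                 "constant")
  expect_equal(as.vector(out4), rep(5, 100))

  expect_error(normalize_contrast(u, 0.9, 0.1), "low_pct")
})
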