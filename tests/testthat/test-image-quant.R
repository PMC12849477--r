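# Image-quantification pipeline: contrast stretch, segmentation, size and
# ROI filters, raw-intensity measurement, per-image normalization.

test_that("contrast stretch follows the shared percentile convention", {
  img <- matrix(0:99, nrow = 10)           # uniform 0..99
  out <- contrast_stretch(img, 2, 98)
  lo <- percentile(0:99, 2); hi <- percentile(0:99, 98)
  expect_equal(out[img == 98], 1.0)        # at/above p98 maps to 1
  expect_equal(out[img == 0], 0.0)
  mid <- img > lo & img < hi
  expect_equal(out[mid], (img[mid] - lo) / (hi - lo))

  expect_warning(z <- contrast_stretch(matrix(5, 20, 20)), "degenerate")
  expect_true(all(z == 0))

  # affine invariance: a*x + b (a > 0) stretches identically
  expect_equal(contrast_stretch(3 * img + 17), contrast_stretch(img))
})

test_that("classical segmentation recovers well-separated disks", {
  set.seed(1)
  centers <- as.matrix(expand.grid(x = seq(30, 220, by = 38),
                                   y = seq(30, 220, by = 38)))[1:25, ]
  fld <- make_grid_field(centers, rep(500, 25), radius = 6)
  seg <- segment_cells(contrast_stretch(fld$image))
  expect_equal(nrow(seg$objects), 25)

  # small field so the disks exceed 2% of pixels and survive the 2-98
  # stretch; equal intensities put the global threshold near half-max, where
  # the blurred disk edge crosses at the true radius, and the smoothing
  # scale is kept small relative to the disk radius so the area is unbiased
  two <- make_grid_field(rbind(c(20, 32), c(40, 32)), c(500, 500),
                         radius = 6, width = 64, height = 64)
  seg2 <- segment_cells(contrast_stretch(two$image), sigma = 1)
  expect_equal(nrow(seg2$objects), 2)
  expect_true(all(abs(seg2$objects$area_px - pi * 36) / (pi * 36) < 0.15))

  blank <- segment_cells(matrix(0, 64, 64))
  expect_equal(nrow(blank$objects), 0)
})

test_that("segmentation accepts an external segmenter through the adapter seam", {
  stretched <- matrix(0, 100, 100)
  stretched[45:55, 45:55] <- 0.9
  external <- function(x) {
    m <- matrix(0L, nrow(x), ncol(x))
    m[x > 0.5] <- 1L
    m
  }
  seg <- segment_cells(stretched, method = external)
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$area_px, 121)
  expect_error(segment_cells(stretched, method = "nope"), "unknown method")
})

test_that("smallest-fraction filter removes exactly floor(f*N) by area with label-order ties", {
  objs <- data.frame(label = 1:1000, area_px = sample(1001:2000),
                     centroid_x = 0, centroid_y = 0)
  seg <- filter_small_objects(make_seg(objs), 0.03)
  expect_equal(nrow(seg$removed), 30)
  expect_equal(nrow(seg$objects), 970)
  expect_lte(max(seg$removed$area_px), min(seg$objects$area_px))
  # conservation
  expect_equal(nrow(seg$objects) + nrow(seg$removed), 1000)

  # floor rounding edge: N = 10, fraction 0.03 -> nothing removed
  small <- filter_small_objects(make_seg(objs[1:10, ]), 0.03)
  expect_equal(nrow(small$removed), 0)

  # all-equal areas: deterministic label-order tie-break, lowest labels out
  ties <- data.frame(label = 1:100, area_px = 50, centroid_x = 0,
                     centroid_y = 0)
  segt <- filter_small_objects(make_seg(ties), 0.03)
  expect_equal(segt$removed$label, 1:3)
})

test_that("central ROI retains centroids strictly inside the inscribed circle", {
  mk <- function(x, y) make_seg(data.frame(label = seq_along(x), area_px = 10,
                                           centroid_x = x, centroid_y = y))
  center <- central_roi_filter(mk(128, 128), 256, 256)
  expect_equal(nrow(center$objects), 1)
  corner <- central_roi_filter(mk(0, 0), 256, 256)
  expect_equal(nrow(corner$objects), 0)

  # geometric oracle: uniform centroids on a square, fraction 0.5 -> ~pi/4
  set.seed(99)
  n <- 4000
  seg <- central_roi_filter(mk(runif(n, 0, 256), runif(n, 0, 256)), 256, 256)
  expect_lt(abs(nrow(seg$objects) / n - pi / 4),
            3 * sqrt(pi / 4 * (1 - pi / 4) / n))
})

test_that("intensity measurement reads only the raw image", {
  img <- matrix(7, 64, 64)
  lm <- matrix(0L, 64, 64); lm[10:20, 10:20] <- 1L; lm[40:50, 40:50] <- 2L
  seg <- structure(list(label_map = lm, objects = comphet:::summarize_labels(lm)),
                   class = "segmentation")
  m <- measure_intensities(img, seg)
  expect_equal(m$mean_raw_intensity, c(7, 7))

  fld <- make_grid_field(rbind(c(80, 80)), 90, radius = 6, background = 10)
  segf <- structure(list(label_map = fld$mask,
                         objects = comphet:::summarize_labels(fld$mask)),
                    class = "segmentation")
  expect_equal(measure_intensities(fld$image, segf)$mean_raw_intensity, 100)

  expect_error(measure_intensities(matrix(0, 3, 3), seg), "shape")

  # measurement purity: with the mask held fixed (ground-truth segmenter
  # through the adapter seam), changing the stretch percentiles leaves
  # every raw mean untouched -- the stretch feeds segmentation only
  centers <- as.matrix(expand.grid(x = seq(90, 166, by = 38),
                                   y = seq(90, 166, by = 38)))
  dense <- make_grid_field(centers, seq(300, 1100, length.out = nrow(centers)),
                           radius = 6)
  pin_mask <- function(x) dense$mask
  q1 <- quantify_image(dense$image, quant_config(p_low = 2, p_high = 98,
                                                 segmentation = pin_mask))
  q2 <- quantify_image(dense$image, quant_config(p_low = 10, p_high = 90,
                                                 segmentation = pin_mask))
  expect_equal(nrow(q1), nrow(centers))
  expect_identical(q1$mean_raw_intensity, q2$mean_raw_intensity)
  expect_identical(q1$relative_intensity, q2$relative_intensity)
})

test_that("per-image min-max normalization maps to 0-100 and is affine invariant", {
  rec <- data.frame(mean_raw_intensity = c(10, 20, 30))
  expect_equal(normalize_per_image(rec)$relative_intensity, c(0, 50, 100))
  expect_warning(single <- normalize_per_image(
    data.frame(mean_raw_intensity = 5)), "equal")
  expect_equal(single$relative_intensity, 0)
  shifted <- data.frame(mean_raw_intensity = c(10, 20, 30) * 2 + 100)
  expect_equal(normalize_per_image(shifted)$relative_intensity,
               normalize_per_image(rec)$relative_intensity)
})

test_that("full quantification composes the stages in the documented order", {
  # 25 cells, all inside the central ROI: floor(0.03*25) = 0 removed by the
  # size filter, so every cell should be reported
  centers <- as.matrix(expand.grid(x = seq(90, 166, by = 19),
                                   y = seq(90, 166, by = 19)))[1:25, ]
  set.seed(7)
  truth <- runif(25, 200, 2000)
  fld <- make_grid_field(centers, truth, radius = 5)
  rec <- quantify_image(fld$image, source_id = "grid")
  expect_equal(nrow(rec), 25)
  expect_true(all(rec$relative_intensity >= 0 & rec$relative_intensity <= 100))
  # measured raw means track the painted intensities
  mg <- vapply(seq_len(nrow(rec)), function(i) {
    which.min((centers[, 1] - rec$centroid_x[i])^2 +
              (centers[, 2] - rec$centroid_y[i])^2)
  }, integer(1))
  expect_gt(cor(truth[mg], rec$mean_raw_intensity, method = "spearman"), 0.99)

  blank <- quantify_image(matrix(100L, 64, 64))
  expect_equal(nrow(blank), 0)
})

test_that("a linear background gradient does not distort relative intensities", {
  # identical-truth cells across the gradient must get similar raw means:
  # the gradient only adds a few counts relative to the cell signal
  centers <- as.matrix(expand.grid(x = seq(90, 166, by = 19),
                                   y = seq(90, 166, by = 19)))[1:25, ]
  fld <- make_grid_field(centers, rep(800, 25), radius = 5)
  grad <- matrix(rep(seq_len(256) - 1, each = 256) * 0.1, nrow = 256)
  rec <- quantify_image(fld$image + grad)
  expect_equal(nrow(rec), 25)
  spread <- diff(range(rec$mean_raw_intensity))
  expect_lt(spread / mean(rec$mean_raw_intensity), 0.05)
})
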