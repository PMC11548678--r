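test_that("circle detection finds the cell on the pre-contact frame", {
  f0 <- fixture_frame0()
  est <- detect_initial_circle(f0)
  expect_s3_class(est, "circle_estimate")
  expect_lte(abs(est$radius - 150), 2)       # 75 um at 2 px/um
  expect_lte(abs(est$center["x"] - ncol(f0) / 2), 2)
  expect_lte(abs(est$center["y"] - nrow(f0) / 2), 2)
  # determinism
  est2 <- detect_initial_circle(f0)
  expect_identical(est, est2)
})

test_that("circle detection fails cleanly on a featureless frame", {
  blank <- matrix(40, 200, 200)
  expect_error(detect_initial_circle(blank), class = "pm_detection_error")
})

test_that("roi extraction crops the expanded bounding square with offset", {
  frame <- matrix(0, 400, 400)
  circle <- structure(list(center = c(x = 200, y = 200), radius = 100),
                      class = "circle_estimate")
  r0 <- extract_roi(frame, circle, detection_config(roi_margin = 0))
  expect_equal(dim(r0$image), c(201, 201))
  r3 <- extract_roi(frame, circle, detection_config(roi_margin = 0.3))
  expect_equal(dim(r3$image), c(261, 261))
  # near-edge circle: crop clips, offset still maps roi -> frame coords
  edge <- structure(list(center = c(x = 30, y = 30), radius = 50),
                    class = "circle_estimate")
  re <- extract_roi(frame, edge, detection_config(roi_margin = 0))
  expect_equal(unname(re$offset), c(0, 0))
  expect_equal(dim(re$image), c(80, 80))
})

test_that("contour detection recovers the cell outline area", {
  seq_out <- fixture_sequence()
  f <- read_frame(file.path(seq_out$dir, "frame_003.png"))  # depth 50
  circ <- detect_initial_circle(fixture_frame0())
  roi <- extract_roi(f, circ)
  contour <- detect_contour(roi$image)
  gt <- penetromech:::ground_truth(fixture_cell(), fixture_dp(), 50)
  truth_area_px <- penetromech:::polygon_area(gt$contour * 2)  # 2 px/um
  expect_lte(abs(penetromech:::polygon_area(contour) - truth_area_px) /
               truth_area_px, 0.03)
})

test_that("contour detection fails on empty or speckle-only input", {
  expect_error(detect_contour(matrix(40, 150, 150)),
               class = "pm_detection_error")
  speck <- matrix(40, 150, 150)
  speck[40:42, 40:42] <- 200
  speck[100:102, 110:112] <- 200
  expect_error(detect_contour(speck), class = "pm_detection_error")
})

test_that("metrics are zero for identical contours and scale-invariant", {
  th <- seq(0, 2 * pi, length.out = 720)[-720]
  poly <- cbind(x = 100 + 80 * cos(th), y = 100 + 90 * sin(th))
  m <- compute_metrics(poly, poly, 0.5, 0)
  expect_equal(m$width_reduction_um, 0)
  expect_equal(m$invaginate_um, 0)
  # halving the resolution and doubling um/px leaves um metrics unchanged
  seq_out <- fixture_sequence()
  circ <- detect_initial_circle(fixture_frame0())
  f <- read_frame(file.path(seq_out$dir, "frame_004.png"))  # depth 75
  c0 <- detect_contour(extract_roi(fixture_frame0(), circ)$image)
  cd <- detect_contour(extract_roi(f, circ)$image)
  m1 <- compute_metrics(c0, cd, 0.5, 75)
  m2 <- compute_metrics(c0 * 2, cd * 2, 0.25, 75)
  expect_equal(m2$width_reduction_um, m1$width_reduction_um,
               tolerance = 1e-12)
  expect_equal(m2$invaginate_um, m1$invaginate_um, tolerance = 1e-12)
})

test_that("calibration is the radius ratio and rejects bad input", {
  expect_equal(calibrate(75, 150), 0.5)
  expect_equal(calibrate(75, 75), 1)
  expect_error(calibrate(0, 100), class = "pm_parameter_error")
  expect_error(calibrate(75, -1), class = "pm_parameter_error")
  f0 <- fixture_frame0()
  est <- detect_initial_circle(f0)
  expect_lte(abs(calibrate(75, est$radius) - 0.5) / 0.5, 0.02)
})

test_that("sequence analysis echoes the manifest and sorts by depth", {
  seq_out <- fixture_sequence()
  rec <- analyze_sequence(seq_out$manifest_path)
  expect_equal(nrow(rec), nrow(seq_out$manifest))
  expect_equal(rec$depth_um, sort(seq_out$manifest$depth_um))
  # shuffled manifest (keeping the pre-contact frame first) gives the same
  # sorted records
  man <- read_manifest(seq_out$manifest_path)
  shuffled <- man[c(1, 5, 3, 8, 2, 7, 4, 6), ]
  rec2 <- analyze_sequence(shuffled)
  expect_equal(rec2, rec, ignore_attr = TRUE)
})

test_that("per-frame detection errors on the fixture stay within 2 px", {
  seq_out <- fixture_sequence()
  rec <- analyze_sequence(seq_out$manifest_path)
  m <- merge(seq_out$truth, rec, by = "depth_um")
  px <- rec$um_per_px[1]
  expect_true(all(abs(m$width_reduction_um.x - m$width_reduction_um.y) <=
                    2 * px))
  expect_true(all(abs(m$invaginate_um.x - m$invaginate_um.y) <= 2 * px))
})

test_that("a corrupted frame is skipped with a warning, not zero-filled", {
  seq_out <- fixture_sequence()
  dir <- file.path(tempdir(), "pm_corrupt")
  dir.create(dir, showWarnings = FALSE)
  file.copy(file.path(seq_out$dir, seq_out$manifest$frame), dir,
            overwrite = TRUE)
  write_frame(matrix(40, 480, 480), file.path(dir, "frame_004.png"))
  utils::write.csv(seq_out$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  expect_warning(
    rec <- analyze_sequence(file.path(dir, "manifest.csv")),
    class = "pm_frame_skipped_warning")
  expect_equal(nrow(rec), nrow(seq_out$manifest) - 1)
  expect_false(75 %in% rec$depth_um)
})

test_that("frames round-trip through PNG and TIFF readers", {
  img <- matrix(as.integer(round(seq(0, 255, length.out = 50 * 40))), 50, 40)
  p <- tempfile(fileext = ".png")
  write_frame(img, p)
  expect_identical(read_frame(p), img)
  tp <- tempfile(fileext = ".tif")
  tiff::writeTIFF(img / 255, tp)
  expect_identical(read_frame(tp), img)
})
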