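test_that("undeformed contour is a circle with zero deformation metrics", {
  cell <- fixture_cell(); dp <- fixture_dp()
  poly <- generate_contour(cell, dp, 0)
  radii <- sqrt(poly[, 1]^2 + poly[, 2]^2)
  expect_equal(range(radii), c(75, 75), tolerance = 1e-12)
  gt <- penetromech:::ground_truth(cell, dp, 0)
  expect_equal(gt$width_reduction_true, 0)
  expect_equal(gt$invaginate_true, 0)
})

test_that("zero gains leave the contour and the rendered frame unchanged", {
  cell <- fixture_cell()
  dp0 <- deformation_params(compression_gain = 0, invagination_gain = 0)
  p0 <- generate_contour(cell, dp0, 0)
  p50 <- generate_contour(cell, dp0, 50)
  expect_equal(unclass(p50), unclass(p0))
  img <- imaging_spec()
  f0 <- render_frame(p0, cell, img)$image
  f50 <- render_frame(p50, cell, img)$image
  expect_identical(f50, f0)
})

test_that("ground-truth metrics agree with an independent brute-force scan", {
  cell <- fixture_cell(); dp <- fixture_dp()
  for (depth in c(1, 20, 50, 90, 130)) {
    gt <- penetromech:::ground_truth(cell, dp, depth)
    p0 <- generate_contour(cell, dp, 0)
    expect_gte(nrow(gt$contour), 3600)
    expect_equal(gt$width_reduction_true,
                 brute_x_extent(p0) - brute_x_extent(gt$contour),
                 tolerance = 1e-9)
    expect_equal(gt$invaginate_true,
                 brute_invaginate(gt$contour),
                 tolerance = 1e-9)
  }
})

test_that("deformation metrics grow with depth while the notch is uncapped", {
  cell <- fixture_cell(); dp <- fixture_dp()
  sched <- depth_schedule(dp)
  wr <- iv <- tip <- numeric(length(sched))
  for (i in seq_along(sched)) {
    gt <- penetromech:::ground_truth(cell, dp, sched[i])
    wr[i] <- gt$width_reduction_true
    iv[i] <- gt$invaginate_true
    band <- abs(gt$contour[, 2]) <= dp$needle_radius + 1e-9 &
      gt$contour[, 1] > -Inf
    right <- band & gt$contour[, 1] > 0
    tip[i] <- min(gt$contour[right, 1])
  }
  expect_true(all(diff(wr) >= -1e-9))
  # the notch tip never crosses the cell center, by the cap
  expect_true(all(tip > 0))
  uncapped <- tip > 0.01 * cell$outer_radius + 1e-9
  expect_true(all(diff(iv[uncapped]) >= -1e-9))
})

test_that("depth and parameter validation raises classed errors", {
  cell <- fixture_cell(); dp <- fixture_dp()
  expect_error(generate_contour(cell, dp, 200), class = "pm_range_error")
  expect_error(generate_contour(cell, dp, -1), class = "pm_parameter_error")
  big_needle <- deformation_params(needle_radius = 60)
  expect_error(generate_contour(cell, big_needle, 10),
               class = "pm_parameter_error")
})

test_that("rendering is deterministic and noise leaves ground truth alone", {
  cell <- fixture_cell(); dp <- fixture_dp()
  poly <- generate_contour(cell, dp, 50)
  img0 <- imaging_spec(noise_sigma = 0)
  expect_identical(render_frame(poly, cell, img0)$image,
                   render_frame(poly, cell, img0)$image)
  imgA <- imaging_spec(noise_sigma = 8, seed = 1)
  imgB <- imaging_spec(noise_sigma = 8, seed = 2)
  fA <- render_frame(poly, cell, imgA); fB <- render_frame(poly, cell, imgB)
  expect_false(identical(fA$image, fB$image))
  expect_identical(fA$image, render_frame(poly, cell, imgA)$image)
  expect_equal(fA$contour_px, fB$contour_px)
})

test_that("rendered cell spans the expected pixel diameter at the midline", {
  cell <- fixture_cell(); dp <- fixture_dp()
  img <- imaging_spec(px_per_um = 2)
  fr <- render_frame(generate_contour(cell, dp, 0), cell, img)$image
  midline <- fr[round(nrow(fr) / 2), ]
  lit <- sum(midline != img$background_gray)
  expect_lte(abs(lit - 300), 2)
})

test_that("oversized contours are rejected at render time", {
  cell <- cell_spec(outer_radius = 200, zp_thickness = 20)
  dp <- fixture_dp()
  poly <- generate_contour(cell, dp, 0)
  expect_error(render_frame(poly, cell, imaging_spec()),
               class = "pm_render_error")
})

test_that("generate_sequence writes a consistent manifest and ground truth", {
  out <- fixture_sequence()
  expect_equal(nrow(out$manifest), 8)
  expect_equal(out$manifest$depth_um, c(0, 1, 25, 50, 75, 100, 125, 130))
  expect_true(all(file.exists(file.path(out$dir, out$manifest$frame))))
  truth <- read.csv(out$truth_path)
  expect_equal(names(truth),
               c("depth_um", "width_reduction_um", "invaginate_um"))
  expect_equal(truth$depth_um, out$manifest$depth_um)
})

test_that("stress curves follow the cubic power-law generative model", {
  m <- default_stress_model()
  curves <- generate_stress_curves(m$alpha1, m$beta, radii = c(5, 10, 15),
                                   depths = c(1, 25, 50, 75, 100),
                                   noise_cv = 0)
  # noiseless curves equal the model exactly, including the printed example
  f75 <- curves[[2]]$forces[curves[[2]]$depths == 75]
  expect_equal(f75, 5.613e-6 * 10^0.4997 * 75^3, tolerance = 1e-12)
  expect_equal(f75, 7.48, tolerance = 1e-3)
  # exact cubic depth scaling on every curve
  for (cv in curves) {
    d <- cv$depths; f <- cv$forces
    expect_equal(f[-1] / f[1], (d[-1] / d[1])^3, tolerance = 1e-12)
  }
  # zero depth gives zero force; unit radius collapses to the cubic law
  z <- generate_stress_curves(1e-5, 0.7, radii = 2, depths = c(0, 10),
                              noise_cv = 0)
  expect_equal(z[[1]]$forces[1], 0)
  u <- generate_stress_curves(12.55e-6, 0.4997, radii = 1,
                              depths = c(10, 20), noise_cv = 0)
  expect_equal(u[[1]]$forces, 12.55e-6 * c(10, 20)^3, tolerance = 1e-12)
})

test_that("stress-curve noise is seeded and validated", {
  a <- generate_stress_curves(1e-5, 0.5, 10, c(10, 20), noise_cv = 0.1,
                              seed = 3)
  b <- generate_stress_curves(1e-5, 0.5, 10, c(10, 20), noise_cv = 0.1,
                              seed = 3)
  c <- generate_stress_curves(1e-5, 0.5, 10, c(10, 20), noise_cv = 0.1,
                              seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(generate_stress_curves(1e-5, 0.5, 10, 10, noise_cv = -1),
               class = "pm_parameter_error")
})
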