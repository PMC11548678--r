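test_that("cubic fit recovers exact data and the one-point solution", {
  d <- c(1, seq(5, 130, by = 5))
  fit <- fit_cubic(stress_curve(d, 12.55e-6 * d^3, needle_radius = 5))
  expect_equal(unname(coef(fit)), 12.55e-6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  one <- fit_cubic(stress_curve(c(0, 10), c(0, 1e-2), needle_radius = 5))
  expect_equal(unname(coef(one)), 1e-5, tolerance = 1e-12)
  expect_error(fit_cubic(c(0, 0), c(1, 2)), class = "pm_parameter_error")
})

test_that("cubic fit on noisy seeded curves recovers the coefficient", {
  d <- c(1, seq(5, 130, by = 5))
  cv <- generate_stress_curves(17.8e-6, 0, radii = 1, depths = d,
                               noise_cv = 0.01, seed = 11)[[1]]
  expect_lte(abs(unname(coef(fit_cubic(cv))) - 17.8e-6) / 17.8e-6, 0.01)
})

test_that("closed-form cubic coefficient equals iterative least squares", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    d <- sort(runif(n, 1, 130))
    f <- runif(1, 1e-6, 1e-4) * d^3 * (1 + rnorm(n, 0, 0.05))
    closed <- unname(coef(fit_cubic(stress_curve(d, pmax(f, 0),
                                                 needle_radius = 1))))
    # independent 1-d minimizer of the same objective
    iter <- optimize(function(a) sum((pmax(f, 0) - a * d^3)^2),
                     interval = c(0, 1e-3), tol = 1e-18)$minimum
    expect_equal(closed, iter, tolerance = 1e-9)
    expect_lte(sum((pmax(f, 0) - closed * d^3)^2),
               sum((pmax(f, 0) - iter * d^3)^2) + 1e-12)
  }
})

test_that("power-law fit recovers exact inputs to 1e-9", {
  r <- c(5, 7.5, 9, 10, 12.5, 15)
  a <- 2e-6 * r^0.5
  fit <- fit_power_law(r, a)
  expect_equal(unname(coef(fit)["alpha1"]), 2e-6, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["beta"]), 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("power-law fit is scale-equivariant in the coefficient", {
  r <- c(5, 7.5, 9, 10, 12.5, 15)
  a <- c(12.55, 15.07, 17.01, 17.80, 20.50, 21.45) * 1e-6
  f1 <- fit_power_law(r, a)
  f2 <- fit_power_law(r, 3.5 * a)
  expect_equal(unname(coef(f2)["alpha1"]) / unname(coef(f1)["alpha1"]), 3.5,
               tolerance = 1e-9)
  expect_equal(unname(coef(f2)["beta"]), unname(coef(f1)["beta"]),
               tolerance = 1e-9)
})

test_that("power-law fit validates input and exposes the log-log method", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), class = "pm_parameter_error")
  expect_error(fit_power_law(c(1, 2, -3), c(1, 2, 3)),
               class = "pm_domain_error")
  r <- c(5, 10, 15); a <- 1e-6 * r^0.4
  ll <- fit_power_law(r, a, method = "loglog")
  expect_equal(unname(coef(ll)["beta"]), 0.4, tolerance = 1e-9)
})

test_that("power-law exponent is recovered under moderate noise", {
  errs <- vapply(1:100, function(s) {
    r <- c(5, 7.5, 9, 10, 12.5, 15)
    a <- with_seed_local(s, 2e-6 * r^0.5 * (1 + rnorm(6, 0, 0.02)))
    unname(coef(fit_power_law(r, a))["beta"]) - 0.5
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.03)
})

test_that("joint fit recovers exact generating parameters", {
  m <- default_stress_model()
  curves <- generate_stress_curves(m$alpha1, m$beta,
                                   radii = c(5, 7.5, 9, 10, 12.5, 15),
                                   depths = c(1, seq(5, 130, 5)),
                                   noise_cv = 0)
  fit <- fit_joint(curves)
  expect_equal(unname(coef(fit)["alpha1"]), m$alpha1, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["beta"]), m$beta, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("joint fit agrees with the two-stage estimate on cubic families", {
  d <- c(1, seq(5, 130, 5))
  alphas <- c(12.55, 15.07, 17.01, 17.80, 20.50, 21.45) * 1e-6
  radii <- c(5, 7.5, 9, 10, 12.5, 15)
  curves <- Map(function(a, r) stress_curve(d, a * d^3, needle_radius = r),
                alphas, radii)
  joint <- fit_joint(curves)
  stage <- fit_power_law(radii, alphas)
  expect_equal(unname(coef(joint)["beta"]), unname(coef(stage)["beta"]),
               tolerance = 1e-6)
  expect_equal(unname(coef(joint)["alpha1"]), unname(coef(stage)["alpha1"]),
               tolerance = 1e-6)
})

test_that("joint fit rejects degenerate inputs", {
  d <- c(1, 10, 20)
  c1 <- stress_curve(d, 1e-5 * d^3, needle_radius = 5)
  expect_error(fit_joint(list(c1)), class = "pm_rank_deficiency_error")
  z1 <- stress_curve(d, rep(0, 3), needle_radius = 5)
  z2 <- stress_curve(d, rep(0, 3), needle_radius = 10)
  expect_error(fit_joint(list(z1, z2)), class = "pm_fit_error")
})

test_that("stress_fit methods expose coefficients, residuals and predictions", {
  d <- c(1, seq(5, 130, 5))
  cv <- stress_curve(d, 1.5e-5 * d^3, needle_radius = 8)
  fit <- fit_cubic(cv)
  expect_named(coef(fit), "alpha")
  expect_equal(length(residuals(fit)), length(d))
  expect_equal(predict(fit, 10), unname(coef(fit)) * 1000)
  expect_equal(fitted(fit) + residuals(fit), cv$forces)
  expect_output(print(fit), "cubic")
  joint <- fit_stress_model("joint", list(
    cv, stress_curve(d, 2e-5 * d^3, needle_radius = 12)))
  expect_s3_class(joint, "joint_fit")
  expect_equal(predict(joint, data.frame(r = 8, d = 10)),
               unname(coef(joint)["alpha1"]) * 8^unname(coef(joint)["beta"]) * 1000,
               tolerance = 1e-9)
})

test_that("pearson correlation handles the standard and degenerate cases", {
  x <- c(1, 2, 4, 8)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, rep(1, 4)),
               class = "pm_undefined_correlation_error")
  expect_error(pearson(x, x[1:3]), class = "pm_parameter_error")
})

test_that("deformation comparison joins on depth and reports correlations", {
  df <- data.frame(depth_um = c(1, 5, 10, 15),
                   width_reduction_um = c(0.1, 0.5, 1.2, 1.9),
                   invaginate_um = c(0.5, 2.4, 5.1, 7.7))
  cmp <- compare_deformation(df, df)
  expect_equal(cmp$width_reduction, 1)
  expect_equal(cmp$invaginate, 1)
  expect_true(all(cmp$pass))
  shifted <- df; shifted$depth_um <- df$depth_um + 100
  expect_error(compare_deformation(df, shifted),
               class = "pm_insufficient_overlap_error")
  jitter <- df; jitter$depth_um <- df$depth_um + 0.4  # inside 0.5 um tol
  expect_equal(compare_deformation(df, jitter)$n_matched, 4)
})

test_that("packaged coefficient table matches its CSV copy", {
  tab <- fem_alpha_coefficients()
  csv <- read.csv(system.file("extdata", "fem_alpha_75um.csv",
                              package = "penetromech"))
  expect_equal(tab, csv, ignore_attr = TRUE)
  expect_equal(nrow(tab), 6)
})
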