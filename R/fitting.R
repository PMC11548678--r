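#' Stress-depth curve container
#'
#' A force-versus-penetration-depth series tagged with the needle radius it
#' was recorded at and the cell radius of the preparation.
#'
#' @param depths Strictly increasing penetration depths, um.
#' @param forces Non-negative forces, uN, same length as `depths`.
#' @param needle_radius Injection micropipette radius, um.
#' @param cell_radius Cell outer radius, um.
#' @return An object of class `stress_curve`.
#' @export
stress_curve <- function(depths, forces, needle_radius, cell_radius = 75) {
  if (length(depths) != length(forces)) {
    pm_stop("depths and forces must have equal length", "pm_parameter_error")
  }
  if (length(depths) == 0 || any(diff(depths) <= 0)) {
    pm_stop("depths must be non-empty and strictly increasing",
            "pm_parameter_error")
  }
  if (any(forces < 0)) {
    pm_stop("forces must be >= 0", "pm_parameter_error")
  }
  stopifnot_scalar_num(needle_radius, "needle_radius", positive = TRUE)
  structure(
    list(depths = as.numeric(depths), forces = as.numeric(forces),
         needle_radius = needle_radius, cell_radius = cell_radius),
    class = "stress_curve"
  )
}

#' @export
print.stress_curve <- function(x, ...) {
  cat(sprintf(
    "Stress curve: r = %g um, R = %g um, %d depths in [%g, %g] um, F up to %.3g uN\n",
    x$needle_radius, x$cell_radius, length(x$depths), min(x$depths),
    max(x$depths), max(x$forces)))
  invisible(x)
}

new_stress_fit <- function(kind, params, fitted, observed, data, extra = list()) {
  res <- observed - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((observed - mean(observed))^2)
  structure(
    c(list(kind = kind, params = params,
           r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
           residuals = res, fitted = fitted, observed = observed,
           n_points = length(observed), data = data),
      extra),
    class = c(paste0(kind, "_fit"), "stress_fit")
  )
}

#' Fit the cubic force-depth law to one stress curve
#'
#' Fits `F = alpha * d^3` by least squares. The minimizer is the closed form
#' `alpha = sum(F_i d_i^3) / sum(d_i^6)`; goodness of fit is
#' `R^2 = 1 - SS_res / SS_tot` about the mean force.
#'
#' @param curve A [stress_curve()], or depths when `forces` is given.
#' @param forces Optional forces, uN, when `curve` is a depth vector.
#' @return A `cubic_fit` / `stress_fit` object; `coef()` returns `alpha`.
#' @examples
#' d <- c(1, seq(5, 130, 5))
#' fit <- fit_cubic(stress_curve(d, 12.55e-6 * d^3, needle_radius = 5))
#' coef(fit)
#' @export
fit_cubic <- function(curve, forces = NULL) {
  if (!inherits(curve, "stress_curve")) {
    curve <- stress_curve(curve, forces, needle_radius = 1)
  }
  d <- curve$depths; f <- curve$forces
  if (length(d) < 2) {
    pm_stop("at least 2 points are required", "pm_parameter_error")
  }
  d6 <- sum(d^6)
  if (d6 == 0) {
    pm_stop("all depths are zero: cubic fit is degenerate",
            "pm_degenerate_fit_error")
  }
  alpha <- sum(f * d^3) / d6
  new_stress_fit("cubic", c(alpha = alpha), alpha * d^3, f, curve)
}

# A few Gauss-Newton steps to polish an LM solution to near machine
# precision; steps that do not decrease the residual sum are rejected.
gn_polish <- function(par, resid_fn, jac_fn, n = 4L) {
  ss <- sum(resid_fn(par)^2)
  for (i in seq_len(n)) {
    r <- resid_fn(par)
    J <- jac_fn(par)
    step <- tryCatch(qr.solve(J, r), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- list(a1 = par$a1 + step[1], b = par$b + step[2])
    ss_cand <- sum(resid_fn(cand)^2)
    if (!is.finite(ss_cand) || ss_cand > ss * (1 + 1e-12)) break
    par <- cand; ss <- ss_cand
  }
  par
}

# Levenberg-Marquardt fit of y ~ a1 * x^b in linear space.
power_nls <- function(x, y, start) {
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - p$a1 * x^p$b,
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-15,
                                         ftol = 1e-15)
  )
  if (fit$info < 1 || fit$info > 4) {
    pm_stop(paste0("power-law fit did not converge: ", fit$message),
            "pm_fit_error")
  }
  gn_polish(fit$par,
            function(p) y - p$a1 * x^p$b,
            function(p) cbind(x^p$b, p$a1 * x^p$b * log(x)))
}

#' Fit the radius power law to per-radius cubic coefficients
#'
#' Fits `alpha = alpha1 * r^beta` to (needle radius, cubic coefficient)
#' pairs by unweighted nonlinear least squares in linear space
#' (Levenberg-Marquardt, relative parameter tolerance below 1e-12, at most
#' 200 iterations), initialized from the log-log linear regression. The log-log
#' estimate itself is available with `method = "loglog"`.
#'
#' @param radii Needle radii, um (>= 3 values, all positive).
#' @param alphas Cubic coefficients, one per radius (all positive).
#' @param method `"nls"` (default) or `"loglog"`.
#' @return A `power_law_fit` / `stress_fit` object; `coef()` returns
#'   `alpha1` and `beta`.
#' @examples
#' tab <- fem_alpha_coefficients()
#' coef(fit_power_law(tab$radius_um, tab$alpha))
#' @export
fit_power_law <- function(radii, alphas, method = c("nls", "loglog")) {
  method <- match.arg(method)
  if (length(radii) != length(alphas) || length(radii) < 3) {
    pm_stop("at least 3 (radius, alpha) pairs are required",
            "pm_parameter_error")
  }
  if (any(radii <= 0) || any(alphas <= 0)) {
    pm_stop("radii and alphas must be positive", "pm_domain_error")
  }
  ll <- stats::lm(log(alphas) ~ log(radii))
  start <- list(a1 = exp(unname(stats::coef(ll)[1])),
                b = unname(stats::coef(ll)[2]))
  par <- if (method == "nls") power_nls(radii, alphas, start) else start
  params <- c(alpha1 = par$a1, beta = par$b)
  new_stress_fit("power_law", params, par$a1 * radii^par$b, alphas,
                 data.frame(radius_um = radii, alpha = alphas),
                 extra = list(method = method))
}

#' Jointly fit the intracellular-stress model to several curves
#'
#' Fits `F = alpha1 * r^beta * d^3` to all pooled (r, d, F) triples of a set
#' of stress curves by nonlinear least squares, initialized from the
#' two-stage procedure (a cubic fit per curve followed by the radius power
#' law). `R^2` is computed over the pooled data about the pooled mean force.
#'
#' @param curves List of [stress_curve()] objects with at least two distinct
#'   needle radii.
#' @return A `joint_fit` / `stress_fit` object; `coef()` returns `alpha1`
#'   and `beta`.
#' @examples
#' m <- default_stress_model()
#' curves <- generate_stress_curves(m$alpha1, m$beta, radii = c(5, 10, 15),
#'                                  depths = seq(5, 130, 5), noise_cv = 0)
#' coef(fit_joint(curves))
#' @export
fit_joint <- function(curves) {
  if (inherits(curves, "stress_curve")) curves <- list(curves)
  radii <- vapply(curves, function(cv) cv$needle_radius, numeric(1))
  if (length(unique(radii)) < 2) {
    pm_stop("joint fit needs curves at >= 2 distinct needle radii",
            "pm_rank_deficiency_error")
  }
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(r = cv$needle_radius, d = cv$depths, F = cv$forces)
  }))
  if (all(df$F == 0)) {
    pm_stop("all forces are zero: joint fit is degenerate", "pm_fit_error")
  }

  # Two-stage initialization: per-curve cubic coefficient, then power law.
  alphas <- vapply(curves, function(cv) unname(coef(fit_cubic(cv))), numeric(1))
  ok <- alphas > 0
  if (sum(ok) < 2) pm_stop("too few curves with positive force", "pm_fit_error")
  stage1 <- NULL
  if (sum(ok) >= 3) {
    stage1 <- fit_power_law(radii[ok], alphas[ok])
    start <- list(a1 = unname(coef(stage1)["alpha1"]),
                  b = unname(coef(stage1)["beta"]))
  } else {
    # two curves: the power law through both points, in closed form
    i <- which(ok)
    b0 <- diff(log(alphas[i])) / diff(log(radii[i]))
    start <- list(a1 = alphas[i[1]] / radii[i[1]]^b0, b = b0)
  }

  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) df$F - p$a1 * df$r^p$b * df$d^3,
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-15,
                                         ftol = 1e-15)
  )
  if (fit$info < 1 || fit$info > 4) {
    pm_stop(paste0("joint fit did not converge: ", fit$message),
            "pm_fit_error")
  }
  par <- gn_polish(fit$par,
                   function(p) df$F - p$a1 * df$r^p$b * df$d^3,
                   function(p) cbind(df$r^p$b * df$d^3,
                                     p$a1 * df$r^p$b * log(df$r) * df$d^3))
  params <- c(alpha1 = par$a1, beta = par$b)
  new_stress_fit("joint", params, par$a1 * df$r^par$b * df$d^3,
                 df$F, df, extra = list(two_stage = stage1))
}

#' One front door to the three stress-model fits
#'
#' @param kind `"cubic"`, `"power_law"` or `"joint"`.
#' @param ... Passed to [fit_cubic()], [fit_power_law()] or [fit_joint()].
#' @return A `stress_fit` object.
#' @export
fit_stress_model <- function(kind = c("cubic", "power_law", "joint"), ...) {
  switch(match.arg(kind),
         cubic = fit_cubic(...),
         power_law = fit_power_law(...),
         joint = fit_joint(...))
}

#' @export
coef.stress_fit <- function(object, ...) object$params

#' @export
residuals.stress_fit <- function(object, ...) object$residuals

#' @export
fitted.stress_fit <- function(object, ...) object$fitted

#' @export
print.stress_fit <- function(x, ...) {
  lab <- c(cubic = "cubic force-depth law F = alpha * d^3",
           power_law = "radius power law alpha = alpha1 * r^beta",
           joint = "joint stress model F = alpha1 * r^beta * d^3")[x$kind]
  cat(sprintf("%s\n", lab))
  cat("  ", paste(sprintf("%s = %.6g", names(x$params), x$params),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  R-squared %.6f on %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
summary.stress_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residuals: min %.3g, median %.3g, max %.3g\n",
              min(object$residuals), stats::median(object$residuals),
              max(object$residuals)))
  invisible(object)
}

#' @export
predict.cubic_fit <- function(object, newdata, ...) {
  d <- if (missing(newdata)) object$data$depths else newdata
  unname(object$params["alpha"]) * d^3
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  r <- if (missing(newdata)) object$data$radius_um else newdata
  unname(object$params["alpha1"]) * r^unname(object$params["beta"])
}

#' @export
predict.joint_fit <- function(object, newdata, ...) {
  nd <- if (missing(newdata)) object$data else newdata
  unname(object$params["alpha1"]) * nd$r^unname(object$params["beta"]) * nd$d^3
}

#' @export
plot.stress_fit <- function(x, ...) {
  if (x$kind == "power_law") {
    graphics::plot(x$data$radius_um, x$observed, xlab = "needle radius (um)",
                   ylab = "cubic coefficient alpha", ...)
    r <- seq(min(x$data$radius_um), max(x$data$radius_um), length.out = 100)
    graphics::lines(r, predict(x, r))
  } else if (x$kind == "joint") {
    graphics::plot(x$data$d, x$observed, col = factor(x$data$r),
                   xlab = "penetration depth (um)", ylab = "force (uN)", ...)
    for (r in unique(x$data$r)) {
      d <- sort(unique(x$data$d[x$data$r == r]))
      graphics::lines(d, predict(x, data.frame(r = r, d = d)))
    }
  } else {
    graphics::plot(x$data$depths, x$observed,
                   xlab = "penetration depth (um)", ylab = "force (uN)", ...)
    d <- seq(min(x$data$depths), max(x$data$depths), length.out = 100)
    graphics::lines(d, predict(x, d))
  }
  invisible(x)
}

#' Pearson product-moment correlation of two series
#'
#' @param series_a,series_b Equal-length numeric vectors (length >= 3), each
#'   with nonzero variance.
#' @return Correlation in [-1, 1].
#' @export
pearson <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 3) {
    pm_stop("series must have equal length >= 3", "pm_parameter_error")
  }
  if (stats::var(series_a) == 0 || stats::var(series_b) == 0) {
    pm_stop("correlation undefined for zero-variance series",
            "pm_undefined_correlation_error")
  }
  stats::cor(series_a, series_b)
}

#' Validate one deformation series against another
#'
#' Joins two deformation tables on penetration depth (inner join within
#' `depth_tol`) and reports the Pearson correlation of their
#' width-reduction and invaginate series, mirroring how simulated and
#' experimental depth-deformation curves are compared. A series pair passes
#' at `threshold` (default 0.99).
#'
#' @param sim,exp Data frames with columns `depth_um`, `width_reduction_um`,
#'   `invaginate_um` (e.g. from [analyze_sequence()] or a ground-truth CSV).
#' @param depth_tol Depth matching tolerance, um.
#' @param threshold Pass threshold on each correlation.
#' @return An object of class `deformation_comparison`: correlations, pass
#'   flags and the number of matched depths.
#' @export
compare_deformation <- function(sim, exp, depth_tol = 0.5, threshold = 0.99) {
  idx <- vapply(sim$depth_um, function(d) {
    j <- which(abs(exp$depth_um - d) <= depth_tol)
    if (length(j)) j[which.min(abs(exp$depth_um[j] - d))] else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  if (sum(keep) < 3) {
    pm_stop("fewer than 3 matched depths between the two series",
            "pm_insufficient_overlap_error")
  }
  s <- sim[keep, ]; e <- exp[idx[keep], ]
  cw <- pearson(s$width_reduction_um, e$width_reduction_um)
  ci <- pearson(s$invaginate_um, e$invaginate_um)
  structure(
    list(width_reduction = cw, invaginate = ci, n_matched = sum(keep),
         threshold = threshold,
         pass = c(width_reduction = cw >= threshold,
                  invaginate = ci >= threshold)),
    class = "deformation_comparison"
  )
}

#' @export
print.deformation_comparison <- function(x, ...) {
  cat(sprintf("Deformation curve comparison (%d matched depths):\n",
              x$n_matched))
  cat(sprintf("  width reduction: r = %.4f (%s)\n", x$width_reduction,
              if (x$pass["width_reduction"]) "pass" else "FAIL"))
  cat(sprintf("  invaginate:      r = %.4f (%s)\n", x$invaginate,
              if (x$pass["invaginate"]) "pass" else "FAIL"))
  cat(sprintf("  threshold %.2f\n", x$threshold))
  invisible(x)
}

#' Per-radius cubic coefficients from reference FEM penetration simulations
#'
#' The cubic coefficients `alpha` of `F = alpha * d^3`, with their
#' goodness-of-fit, obtained from finite-element penetration simulations of
#' a 75 um oocyte with six injection micropipette radii. These pairs are the
#' input of the radius power-law fit that yields the reference model
#' `F = 5.613e-6 * r^0.4997 * d^3` (see [default_stress_model()]). Also
#' shipped as `inst/extdata/fem_alpha_75um.csv`.
#'
#' @return Data frame with columns `radius_um`, `alpha`, `r_squared`.
#' @export
fem_alpha_coefficients <- function() {
  data.frame(
    radius_um = c(5, 7.5, 9, 10, 12.5, 15),
    alpha = c(12.55e-6, 15.07e-6, 17.01e-6, 17.80e-6, 20.50e-6, 21.45e-6),
    r_squared = c(0.9993, 0.9995, 0.9999, 0.9999, 0.9996, 0.9998)
  )
}
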