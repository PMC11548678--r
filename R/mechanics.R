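#' Dimensionless bracket of the point-load membrane model
#'
#' The point-load model expresses the force needed to depress a clamped
#' stiff membrane (here the zona pellucida) with a micropipette as a
#' prefactor linear in membrane stiffness and depression depth times a
#' dimensionless function of `zeta = c / a`, the ratio of the pipette radius
#' to the depression radius. The typeset source of the bracket is ambiguous;
#' this reconstruction,
#' \deqn{B(\zeta) = \frac{3 (1 - \zeta^2)(1 - \zeta^2 + \ln \zeta^2)}
#'                      {3 - 4\zeta^2 + 2 \ln \zeta^2 + \zeta^4},}
#' is isolated here as the single swappable definition. It is positive and
#' strictly increasing on the working range `zeta` in (0, 0.85], matching the
#' model's documented behavior (stress rises nonlinearly with `zeta`); all
#' downstream contracts (force linear in depth/stiffness/thickness, zero at
#' zero depression, monotone `zeta` response) are independent of the exact
#' grouping.
#'
#' @param zeta Pipette-to-depression radius ratio, in (0, 1).
#' @return Dimensionless bracket value.
#' @export
point_load_bracket <- function(zeta) {
  if (any(zeta <= 0) || any(zeta >= 1)) {
    pm_stop("zeta must lie in (0, 1)", "pm_domain_error")
  }
  z2 <- zeta^2
  3 * (1 - z2) * (1 - z2 + log(z2)) / (3 - 4 * z2 + 2 * log(z2) + z2^2)
}

#' Parameters of the point-load membrane model
#'
#' @param E Membrane elastic modulus, Pa.
#' @param v Poisson ratio.
#' @param h Membrane thickness, um.
#' @param a Depression radius, um.
#' @param c Micropipette radius, um; `zeta = c / a` must lie in (0, 1).
#' @param wd Depression depth, um (>= 0).
#' @return An object of class `point_load_params`.
#' @export
point_load_params <- function(E = 20000, v = 0.499, h = 20, a = 55,
                              c = 10, wd = 0) {
  stopifnot_scalar_num(E, "E", positive = TRUE)
  stopifnot_scalar_num(h, "h", positive = TRUE)
  stopifnot_scalar_num(a, "a", positive = TRUE)
  stopifnot_scalar_num(c, "c", positive = TRUE)
  stopifnot_scalar_num(wd, "wd")
  if (wd < 0) pm_stop("wd must be >= 0", "pm_domain_error")
  if (v <= 0 || v > 0.499 + 1e-9) {
    pm_stop("v must lie in (0, 0.499]", "pm_domain_error")
  }
  zeta <- c / a
  if (zeta <= 0 || zeta >= 1) {
    pm_stop("zeta = c / a must lie in (0, 1)", "pm_domain_error")
  }
  structure(list(E = E, v = v, h = h, a = a, c = c, wd = wd, zeta = zeta),
            class = "point_load_params")
}

#' Point-load membrane force
#'
#' Evaluates the point-load model
#' `F = 2 pi E h wd / (3 a^2 (1 - v)) * B(zeta)` with the bracket of
#' [point_load_bracket()]. The force is exactly linear in the depression
#' depth `wd`, the membrane modulus `E` and thickness `h`, and increases
#' with `zeta` over the bracket's working range.
#'
#' Units: E in Pa, lengths in um; the returned force is in uN
#' (1 Pa * um^2 = 1e-12 N = 1e-6 uN, folded into the conversion below).
#'
#' @param p A [point_load_params()].
#' @return Force in uN.
#' @examples
#' point_load_force(point_load_params(wd = 10))
#' @export
point_load_force <- function(p) {
  stopifnot(inherits(p, "point_load_params"))
  # Lengths in um, E in Pa; the residual unit conversion to uN is folded
  # into the trailing constant (Pa * um^2 = 1e-12 N = 1e-6 uN).
  pref <- 2 * pi * p$E * p$h * p$wd / (3 * p$a^2 * (1 - p$v))
  pref * point_load_bracket(p$zeta) * 1e-6
}

#' Empirical intracellular-stress model
#'
#' Constructs the power-law intracellular-stress model
#' `F = alpha1 * r^beta * d^3` (force in uN; needle radius `r` and
#' penetration depth `d` in um), with its fitted validity ranges.
#'
#' @param alpha1 Multiplicative coefficient (> 0).
#' @param beta Radius exponent.
#' @param cell_radius Cell radius the model was fitted for, um.
#' @param depth_range,radius_range Validity ranges (um) used for warnings.
#' @return An object of class `stress_model`.
#' @export
stress_model <- function(alpha1, beta, cell_radius = 75,
                         depth_range = c(1, 130), radius_range = c(5, 15)) {
  stopifnot_scalar_num(alpha1, "alpha1", positive = TRUE)
  stopifnot_scalar_num(beta, "beta")
  structure(
    list(alpha1 = alpha1, beta = beta, cell_radius = cell_radius,
         depth_range = depth_range, radius_range = radius_range),
    class = "stress_model"
  )
}

#' @export
print.stress_model <- function(x, ...) {
  cat(sprintf(
    "Intracellular stress model (cell radius %g um):\n  F = %.4g * r^%.4g * d^3  [uN; r, d in um]\n",
    x$cell_radius, x$alpha1, x$beta))
  cat(sprintf("  fitted for d in [%g, %g] um, r in [%g, %g] um\n",
              x$depth_range[1], x$depth_range[2],
              x$radius_range[1], x$radius_range[2]))
  invisible(x)
}

#' Reference stress models by cell radius
#'
#' `stress_model_catalog()` lists the power-law stress models fitted to
#' finite-element penetration simulations of oocytes of 70, 75 and 80 um
#' outer radius (20 um ZP in all cases); `default_stress_model()` retrieves
#' one by cell radius, defaulting to the 75 um model
#' `F = 5.613e-6 * r^0.4997 * d^3`.
#'
#' @param cell_radius Cell outer radius in um (70, 75 or 80).
#' @return A [stress_model()] (or a named list of them for the catalog).
#' @examples
#' default_stress_model()
#' default_stress_model(70)
#' @export
default_stress_model <- function(cell_radius = 75) {
  cat <- stress_model_catalog()
  key <- as.character(cell_radius)
  if (!key %in% names(cat)) {
    pm_stop(sprintf("no reference stress model for cell radius %g um (have %s)",
                    cell_radius, paste(names(cat), collapse = ", ")),
            "pm_no_model_error")
  }
  cat[[key]]
}

#' @rdname default_stress_model
#' @export
stress_model_catalog <- function() {
  list(
    `70` = stress_model(8.270e-6, 0.4227, cell_radius = 70),
    `75` = stress_model(5.613e-6, 0.4997, cell_radius = 75),
    `80` = stress_model(6.520e-6, 0.3635, cell_radius = 80)
  )
}

#' Evaluate the empirical stress model
#'
#' @param m A [stress_model()].
#' @param r Needle radius (um), scalar or vector.
#' @param d Penetration depth (um), scalar or vector.
#' @param warn Warn when `r` or `d` leaves the model's fitted range.
#' @return Force in uN (vectorized over `r`, `d`).
#' @examples
#' empirical_stress(default_stress_model(), r = 10, d = 75)
#' @export
empirical_stress <- function(m, r, d, warn = TRUE) {
  stopifnot(inherits(m, "stress_model"))
  if (any(r < 0) || any(d < 0)) {
    pm_stop("r and d must be >= 0", "pm_domain_error")
  }
  if (warn) {
    if (any(r != 0 & (r < m$radius_range[1] | r > m$radius_range[2]))) {
      pm_warn(sprintf("needle radius outside fitted range [%g, %g] um",
                      m$radius_range[1], m$radius_range[2]),
              "pm_validity_warning")
    }
    if (any(d != 0 & (d < m$depth_range[1] | d > m$depth_range[2]))) {
      pm_warn(sprintf("penetration depth outside fitted range [%g, %g] um",
                      m$depth_range[1], m$depth_range[2]),
              "pm_validity_warning")
    }
  }
  m$alpha1 * r^m$beta * d^3
}

#' @export
predict.stress_model <- function(object, newdata, ...) {
  if (missing(newdata) || !all(c("r", "d") %in% names(newdata))) {
    pm_stop("newdata with columns `r` and `d` is required", "pm_parameter_error")
  }
  empirical_stress(object, newdata$r, newdata$d, warn = FALSE)
}
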