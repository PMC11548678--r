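#' Geometry and elasticity of the modeled oocyte
#'
#' Bundles the geometric and elastic parameters of the two-layer oocyte model:
#' a cytoplasm sphere wrapped in a stiff zona pellucida (ZP) shell. Defaults
#' correspond to a porcine oocyte with a 75 um outer radius, a 20 um ZP and
#' near-incompressible material (Poisson ratio 0.499), with Young's moduli of
#' 784 Pa (cytoplasm) and 20 kPa (ZP).
#'
#' @param outer_radius Outer (ZP) radius in um.
#' @param zp_thickness ZP shell thickness in um.
#' @param cytoplasm_radius Cytoplasm radius in um; must equal
#'   `outer_radius - zp_thickness`.
#' @param E_cytoplasm Young's modulus of the cytoplasm, Pa.
#' @param E_zp Young's modulus of the ZP, Pa.
#' @param poisson_ratio Poisson ratio (shared by both layers).
#' @return An object of class `cell_spec`.
#' @examples
#' cell_spec()
#' cell_spec(outer_radius = 80, zp_thickness = 20, cytoplasm_radius = 60)
#' @export
cell_spec <- function(outer_radius = 75, zp_thickness = 20,
                      cytoplasm_radius = outer_radius - zp_thickness,
                      E_cytoplasm = 784, E_zp = 20000,
                      poisson_ratio = 0.499) {
  stopifnot_scalar_num(outer_radius, "outer_radius", positive = TRUE)
  stopifnot_scalar_num(zp_thickness, "zp_thickness", positive = TRUE)
  stopifnot_scalar_num(cytoplasm_radius, "cytoplasm_radius", positive = TRUE)
  stopifnot_scalar_num(E_cytoplasm, "E_cytoplasm", positive = TRUE)
  stopifnot_scalar_num(E_zp, "E_zp", positive = TRUE)
  stopifnot_scalar_num(poisson_ratio, "poisson_ratio")
  if (abs(cytoplasm_radius + zp_thickness - outer_radius) > 1e-9) {
    pm_stop("cytoplasm_radius + zp_thickness must equal outer_radius",
            "pm_parameter_error")
  }
  if (poisson_ratio <= 0 || poisson_ratio > 0.499 + 1e-9) {
    pm_stop("poisson_ratio must lie in (0, 0.499]", "pm_parameter_error")
  }
  structure(
    list(outer_radius = outer_radius, zp_thickness = zp_thickness,
         cytoplasm_radius = cytoplasm_radius, E_cytoplasm = E_cytoplasm,
         E_zp = E_zp, poisson_ratio = poisson_ratio),
    class = "cell_spec"
  )
}

#' @export
print.cell_spec <- function(x, ...) {
  cat("Oocyte model:\n")
  cat(sprintf("  outer radius %g um (ZP %g um + cytoplasm %g um)\n",
              x$outer_radius, x$zp_thickness, x$cytoplasm_radius))
  cat(sprintf("  E_cytoplasm %g Pa, E_zp %g Pa, Poisson %g\n",
              x$E_cytoplasm, x$E_zp, x$poisson_ratio))
  invisible(x)
}

#' Parameters of the parametric deformation model
#'
#' Controls how the synthetic cell contour deforms with penetration depth:
#' the cell is compressed along the penetration (X) axis, elongated along Y
#' (optionally preserving cross-section area as a stand-in for
#' incompressibility), and carved with a needle-width notch whose depth grows
#' linearly with penetration depth.
#'
#' The default depth schedule follows the experimental protocol: an initial
#' 1 um contact step followed by 5 um increments up to `max_depth`
#' (`depth_schedule()`).
#'
#' @param needle_radius Injection micropipette radius, um.
#' @param max_depth Largest penetration depth of the schedule, um.
#' @param depth_step Increment of the depth schedule, um.
#' @param compression_gain Fractional reduction of the X semi-axis at
#'   `max_depth` (dimensionless). Default 0.15 puts the width reduction at
#'   full depth near 20 um for a 75 um cell.
#' @param invagination_gain Notch depth gained per um of penetration
#'   (dimensionless).
#' @param area_preservation If `TRUE`, the Y semi-axis is chosen so the
#'   ellipse area equals the undeformed circle's.
#' @return An object of class `deformation_params`.
#' @examples
#' dp <- deformation_params(needle_radius = 10)
#' depth_schedule(dp)
#' @export
deformation_params <- function(needle_radius = 10, max_depth = 130,
                               depth_step = 5, compression_gain = 0.15,
                               invagination_gain = 0.6,
                               area_preservation = TRUE) {
  stopifnot_scalar_num(needle_radius, "needle_radius", positive = TRUE)
  stopifnot_scalar_num(max_depth, "max_depth", positive = TRUE)
  stopifnot_scalar_num(depth_step, "depth_step", positive = TRUE)
  stopifnot_scalar_num(compression_gain, "compression_gain", nonneg = TRUE)
  stopifnot_scalar_num(invagination_gain, "invagination_gain", nonneg = TRUE)
  if (compression_gain >= 1) {
    pm_stop("compression_gain must be < 1", "pm_parameter_error")
  }
  structure(
    list(needle_radius = needle_radius, max_depth = max_depth,
         depth_step = depth_step, compression_gain = compression_gain,
         invagination_gain = invagination_gain,
         area_preservation = isTRUE(area_preservation)),
    class = "deformation_params"
  )
}

#' @rdname deformation_params
#' @param dp A `deformation_params` object.
#' @export
depth_schedule <- function(dp) {
  c(1, seq(dp$depth_step, dp$max_depth, by = dp$depth_step))
}

#' Rasterization parameters for synthetic frames
#'
#' @param px_per_um Pixels per um.
#' @param image_width,image_height Raster size in px.
#' @param cell_gray,zp_gray,background_gray Intensities (0-255) of the
#'   cytoplasm interior, the ZP ring and the background.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (intensity units); 0 disables noise.
#' @param seed Integer seed for the noise; `NULL` uses the current RNG state.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(px_per_um = 2, image_width = 480, image_height = 480,
                         cell_gray = 120, zp_gray = 200, background_gray = 40,
                         noise_sigma = 0, seed = NULL) {
  stopifnot_scalar_num(px_per_um, "px_per_um", positive = TRUE)
  stopifnot_scalar_num(image_width, "image_width", positive = TRUE)
  stopifnot_scalar_num(image_height, "image_height", positive = TRUE)
  stopifnot_scalar_num(noise_sigma, "noise_sigma", nonneg = TRUE)
  for (g in c(cell_gray, zp_gray, background_gray)) {
    if (g < 0 || g > 255) pm_stop("gray levels must be in [0, 255]",
                                  "pm_parameter_error")
  }
  structure(
    list(px_per_um = px_per_um, image_width = as.integer(image_width),
         image_height = as.integer(image_height), cell_gray = cell_gray,
         zp_gray = zp_gray, background_gray = background_gray,
         noise_sigma = noise_sigma, seed = seed),
    class = "imaging_spec"
  )
}
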