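#' Deformed cell contour at a given penetration depth
#'
#' Builds the parametric stand-in for the deformed cell outline: an
#' axis-aligned ellipse compressed along the penetration (X) axis with
#' semi-axis `a_x = R * (1 - compression_gain * depth / max_depth)`, elongated
#' along Y (by area preservation when enabled), with a needle-width notch
#' carved into the +X side. The notch reaches from the contour shoulder at
#' `|y| = needle_radius` down to
#' `x = x_shoulder - invagination_gain * depth`, capped so the notch tip stays
#' right of the cell center. The needle is taken to approach from +X; image
#' coordinates have x rightward and y downward.
#'
#' Ground-truth deformation metrics are always derived from the returned
#' polygon by exhaustive vertex scans (see [contour_metrics()]), never from
#' closed-form expressions.
#'
#' @param cell A [cell_spec()].
#' @param dp A [deformation_params()].
#' @param depth Penetration depth in um, `0 <= depth <= max_depth`.
#' @param n_vertices Number of vertices on the elliptical part of the polygon.
#' @return A two-column matrix (columns `x`, `y`, um, origin at the cell
#'   center) tracing a simple closed polygon counter-clockwise. The first
#'   vertex is not repeated.
#' @examples
#' poly <- generate_contour(cell_spec(), deformation_params(), depth = 50)
#' contour_metrics(poly)
#' @export
generate_contour <- function(cell, dp, depth, n_vertices = 3600) {
  stopifnot(inherits(cell, "cell_spec"), inherits(dp, "deformation_params"))
  stopifnot_scalar_num(depth, "depth", nonneg = TRUE)
  if (depth > dp$max_depth) {
    pm_stop(sprintf("depth %g um outside [0, %g]", depth, dp$max_depth),
            "pm_range_error")
  }
  R <- cell$outer_radius
  r <- dp$needle_radius
  if (r >= cell$cytoplasm_radius) {
    pm_stop("needle_radius must be smaller than the cytoplasm radius",
            "pm_parameter_error")
  }

  shrink <- 1 - dp$compression_gain * depth / dp$max_depth
  ax <- R * shrink
  ay <- if (dp$area_preservation) R^2 / ax else R
  if (r >= ay) {
    pm_stop("notch wider than the deformed cell", "pm_parameter_error")
  }

  invag <- dp$invagination_gain * depth
  # Outer (ZP) contour; cap keeps the notch tip right of the cell center.
  x_sh <- if (invag > 0) ax * cos(asin(r / ay)) else NA_real_
  x_tip <- if (invag > 0) max(x_sh - invag, 0.01 * R) else NA_real_
  outer <- notched_ellipse(ax, ay, r, x_tip, n_vertices)

  # Cytoplasm contour: same relative compression on the cytoplasm axes; the
  # needle carries the ZP ring ahead of it, so the inner notch tip trails the
  # outer one by the ZP thickness (same notch half-width).
  k <- cell$cytoplasm_radius / R
  tip_in <- if (invag > 0) {
    max(x_tip - cell$zp_thickness, 0.01 * cell$cytoplasm_radius)
  } else NA_real_
  inner <- notched_ellipse(ax * k, ay * k, r, tip_in, n_vertices)

  structure(outer, inner = inner)
}

# Axis-aligned ellipse with an optional rectangular notch of half-width
# needle_r carved on the +X side down to x = tip_x. tip_x = NA, or a tip
# beyond the shoulder, yields the plain ellipse.
notched_ellipse <- function(ax, ay, needle_r, tip_x, n_vertices) {
  th0 <- if (is.na(tip_x)) 0 else asin(min(needle_r / ay, 1))
  x_sh <- ax * cos(th0)
  if (is.na(tip_x) || tip_x >= x_sh) {
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    return(cbind(x = ax * cos(theta), y = ay * sin(theta)))
  }
  theta <- seq(th0, 2 * pi - th0, length.out = n_vertices)
  ell <- cbind(x = ax * cos(theta), y = ay * sin(theta))
  # Notch wall: bottom shoulder -> tip -> top shoulder (the polygon closes
  # back to the first ellipse vertex). Interior wall vertices keep the
  # vertex density comparable to the ellipse part.
  wall_x <- seq(x_sh, tip_x, length.out = 12L)[-1L]
  tip_y <- seq(-needle_r, needle_r, length.out = 12L)[-c(1L, 12L)]
  notch <- rbind(
    cbind(x = wall_x, y = -needle_r),
    cbind(x = tip_x, y = tip_y),
    cbind(x = rev(wall_x), y = needle_r)
  )
  rbind(ell, notch)
}

#' Exact deformation metrics of a synthetic contour
#'
#' Computes the contour's axis-aligned X extent and the invaginate value by
#' exhaustive min/max scans over the polygon vertices. The invaginate value
#' is the X distance from the contour's rightmost shoulder to the deepest
#' point of the notch between the shoulders: the upper and lower
#' half-contours each have a rightmost vertex, and the dip is measured over
#' the vertices strictly between those two shoulder heights. For a convex
#' contour the shoulders coincide on the +X axis and the value is exactly 0.
#' This is the same geometric definition the vision module applies to
#' detected contours ([compute_metrics()]).
#'
#' @param poly Two-column (x, y) polygon matrix in um, cell-centered
#'   coordinates.
#' @return A list with `x_extent` and `invaginate` (both um).
#' @export
contour_metrics <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x_extent <- max(x) - min(x)
  top <- y >= 0; bot <- y <= 0
  i_t <- which(top)[which.max(x[top])]
  i_b <- which(bot)[which.max(x[bot])]
  lo <- min(y[i_t], y[i_b]); hi <- max(y[i_t], y[i_b])
  inner <- y > lo & y < hi & x > 0
  invaginate <- if (any(inner)) {
    max(max(x[i_t], x[i_b]) - min(x[inner]), 0)
  } else 0
  list(x_extent = x_extent, invaginate = invaginate)
}

# Ground truth record for one depth: metrics are vertex scans over the
# generated polygons, referenced to the undeformed depth-0 contour.
ground_truth <- function(cell, dp, depth, n_vertices = 3600) {
  poly0 <- generate_contour(cell, dp, 0, n_vertices)
  polyd <- generate_contour(cell, dp, depth, n_vertices)
  m0 <- contour_metrics(poly0)
  md <- contour_metrics(polyd)
  list(depth = depth, contour = polyd,
       width_reduction_true = m0$x_extent - md$x_extent,
       invaginate_true = md$invaginate)
}

# Even-odd scanline fill of a polygon over a h x w pixel grid. Pixel centers
# sit at integer coordinates (x = column, y = row). Returns a logical matrix
# [y, x].
fill_polygon_mask <- function(height, width, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  x2 <- x[j]; y2 <- y[j]
  keep <- y != y2                       # horizontal edges never cross a row
  x1 <- x[keep]; y1 <- y[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  mask <- matrix(FALSE, height, width)
  for (row in seq_len(height)) {
    cross <- (y1 <= row & y2 > row) | (y2 <= row & y1 > row)
    if (!any(cross)) next
    t <- (row - y1[cross]) / (y2[cross] - y1[cross])
    xs <- sort(x1[cross] + t * (x2[cross] - x1[cross]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1L])
      lo <- max(lo, 1L); hi <- min(hi, width)
      if (lo <= hi) mask[row, lo:hi] <- TRUE
    }
  }
  mask
}

#' Render one synthetic penetration frame
#'
#' Rasterizes a deformed contour into an 8-bit grayscale image: ZP ring at
#' `zp_gray`, cytoplasm interior at `cell_gray`, background at
#' `background_gray`, plus optional additive Gaussian noise clipped to
#' [0, 255]. The cytoplasm region is the contour's `inner` attribute (set by
#' [generate_contour()]); a radially scaled copy of the outer polygon is used
#' as a fallback for plain convex contours.
#'
#' @param poly Contour polygon from [generate_contour()], um coordinates.
#' @param cell A [cell_spec()].
#' @param img An [imaging_spec()].
#' @return A list with `image` (integer matrix `[y, x]`, 0-255) and
#'   `contour_px` (the outer polygon mapped to pixel coordinates).
#' @export
render_frame <- function(poly, cell, img) {
  stopifnot(inherits(cell, "cell_spec"), inherits(img, "imaging_spec"))
  s <- img$px_per_um
  cx <- (img$image_width + 1) / 2
  cy <- (img$image_height + 1) / 2
  to_px <- function(p) cbind(x = cx + p[, 1] * s, y = cy + p[, 2] * s)

  outer_px <- to_px(poly)
  if (min(outer_px[, 1]) < 2 || max(outer_px[, 1]) > img$image_width - 1 ||
      min(outer_px[, 2]) < 2 || max(outer_px[, 2]) > img$image_height - 1) {
    pm_stop("contour does not fit in the raster", "pm_render_error")
  }
  inner <- attr(poly, "inner")
  if (is.null(inner)) inner <- poly * (cell$cytoplasm_radius / cell$outer_radius)
  inner_px <- to_px(inner)

  frame <- matrix(img$background_gray, img$image_height, img$image_width)
  frame[fill_polygon_mask(img$image_height, img$image_width, outer_px)] <-
    img$zp_gray
  frame[fill_polygon_mask(img$image_height, img$image_width, inner_px)] <-
    img$cell_gray

  if (img$noise_sigma > 0) {
    frame <- with_seed(img$seed, {
      frame + matrix(stats::rnorm(length(frame), 0, img$noise_sigma),
                     nrow(frame), ncol(frame))
    })
    frame <- pmin(pmax(frame, 0), 255)
  }
  list(image = matrix(as.integer(round(frame)), nrow(frame), ncol(frame)),
       contour_px = outer_px)
}

#' Generate a full synthetic penetration sequence on disk
#'
#' Writes one 8-bit grayscale PNG per penetration depth, a manifest CSV
#' (`frame,depth_um`) and a ground-truth CSV
#' (`depth_um,width_reduction_um,invaginate_um`). Per-frame noise seeds are
#' derived deterministically from `img$seed` (seed + frame index), so a fixed
#' seed yields byte-identical output.
#'
#' @param cell A [cell_spec()].
#' @param dp A [deformation_params()].
#' @param img An [imaging_spec()].
#' @param dir Output directory (created if needed).
#' @param depths Depth schedule in um; defaults to [depth_schedule()].
#' @param include_precontact Prepend an explicit depth-0 frame.
#' @return Invisibly, a list with `manifest` (data.frame `frame`, `depth_um`),
#'   `truth` (data.frame of ground-truth metrics) and the two CSV paths.
#' @export
generate_sequence <- function(cell, dp, img, dir,
                              depths = depth_schedule(dp),
                              include_precontact = FALSE) {
  if (include_precontact) depths <- c(0, depths)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base_seed <- img$seed
  rows <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    d <- depths[i]
    gt <- ground_truth(cell, dp, d)
    fi <- img
    if (!is.null(base_seed)) fi$seed <- base_seed + i
    fr <- render_frame(gt$contour, cell, fi)
    fn <- sprintf("frame_%03d.png", i - 1L)
    write_frame(fr$image, file.path(dir, fn))
    rows[[i]] <- data.frame(frame = fn, depth_um = d,
                            width_reduction_um = gt$width_reduction_true,
                            invaginate_um = gt$invaginate_true)
  }
  all <- do.call(rbind, rows)
  manifest <- all[, c("frame", "depth_um")]
  truth <- all[, c("depth_um", "width_reduction_um", "invaginate_um")]
  manifest_path <- file.path(dir, "manifest.csv")
  truth_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, truth = truth,
                 manifest_path = manifest_path, truth_path = truth_path))
}

#' Synthetic stress-depth curves from the empirical model
#'
#' Draws force curves `F(d) = alpha1 * r^beta * d^3 * (1 + eps)` with
#' multiplicative Gaussian noise `eps ~ N(0, noise_cv^2)`, one curve per
#' needle radius. With `noise_cv = 0` the curves equal the model exactly.
#'
#' @param alpha1,beta Model coefficients (force in uN for d, r in um).
#' @param radii Needle radii in um.
#' @param depths Penetration depths in um.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param cell_radius Cell radius tag carried on each curve, um.
#' @return A list of [stress_curve()] objects, one per radius.
#' @examples
#' curves <- generate_stress_curves(5.613e-6, 0.4997, radii = c(5, 10),
#'                                  depths = c(25, 50, 75), noise_cv = 0)
#' curves[[2]]$forces
#' @export
generate_stress_curves <- function(alpha1, beta, radii, depths,
                                   noise_cv = 0, seed = NULL,
                                   cell_radius = 75) {
  stopifnot_scalar_num(alpha1, "alpha1", positive = TRUE)
  stopifnot_scalar_num(beta, "beta")
  stopifnot_scalar_num(noise_cv, "noise_cv", nonneg = TRUE)
  if (length(radii) == 0 || length(depths) == 0 ||
      any(radii <= 0) || any(depths < 0)) {
    pm_stop("radii and depths must be non-empty and positive",
            "pm_parameter_error")
  }
  depths <- sort(depths)
  with_seed(seed, {
    lapply(radii, function(r) {
      f <- alpha1 * r^beta * depths^3
      if (noise_cv > 0) {
        f <- f * (1 + stats::rnorm(length(depths), 0, noise_cv))
      }
      stress_curve(depths = depths, forces = pmax(f, 0), needle_radius = r,
                   cell_radius = cell_radius)
    })
  })
}
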