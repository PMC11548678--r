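#' Detection parameters of the vision pipeline
#'
#' @param canny_low,canny_high Hysteresis thresholds on the Sobel gradient
#'   magnitude (weak / strong edge).
#' @param canny_sigma Gaussian pre-smoothing sigma in px.
#' @param close_window Side of the square structuring element of the
#'   morphological close that bridges broken contours, px.
#' @param min_area Connected components smaller than this (px^2) are
#'   discarded before contour extraction.
#' @param roi_margin Fractional enlargement of the circle's bounding square
#'   when cropping the region of interest.
#' @param hough_radius_frac Radius search range of the circle detector, as
#'   fractions of the smaller image dimension.
#' @param hough_radius_step Radius step of the search, px.
#' @param hough_bin Accumulator bin size, px.
#' @param hough_min_votes Minimum accumulator peak to accept a circle.
#' @param notch_halfwidth_px Optional fixed half-width of the notch band used
#'   by [compute_metrics()]; `NULL` auto-detects it from the contour.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(canny_low = 100, canny_high = 200,
                             canny_sigma = 1.4, close_window = 20,
                             min_area = 100, roi_margin = 0.3,
                             hough_radius_frac = c(0.15, 0.45),
                             hough_radius_step = 2, hough_bin = 2,
                             hough_min_votes = 40,
                             notch_halfwidth_px = NULL) {
  if (canny_low >= canny_high) {
    pm_stop("canny_low must be < canny_high", "pm_parameter_error")
  }
  if (close_window < 1) pm_stop("close_window must be >= 1",
                                "pm_parameter_error")
  if (min_area < 0) pm_stop("min_area must be >= 0", "pm_parameter_error")
  structure(
    list(canny_low = canny_low, canny_high = canny_high,
         canny_sigma = canny_sigma, close_window = as.integer(close_window),
         min_area = min_area, roi_margin = roi_margin,
         hough_radius_frac = hough_radius_frac,
         hough_radius_step = hough_radius_step, hough_bin = hough_bin,
         hough_min_votes = hough_min_votes,
         notch_halfwidth_px = notch_halfwidth_px),
    class = "detection_config"
  )
}

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(-Inf, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding (weak edges are
#' kept only in connected components that contain a strong edge).
#'
#' @param image Numeric matrix `[y, x]`, intensities 0-255.
#' @param low,high Hysteresis thresholds on gradient magnitude.
#' @param sigma Pre-smoothing Gaussian sigma, px.
#' @return List with `edges` (logical matrix), `gx`, `gy` (Sobel gradients)
#'   and `magnitude`.
#' @export
canny_edges <- function(image, low = 100, high = 200, sigma = 1.4) {
  img <- if (sigma > 0) {
    EBImage::filter2(image, gaussian_kernel(sigma))
  } else image
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (x = column)
  gx <- EBImage::filter2(img, kx)
  gy <- EBImage::filter2(img, t(kx))
  mag <- sqrt(gx^2 + gy^2)

  # Non-maximum suppression: compare against the two neighbors along the
  # gradient direction, quantized to 0/45/90/135 degrees.
  sector <- (round(atan2(gy, gx) / (pi / 4)) %% 4)
  nms <- matrix(FALSE, nrow(mag), ncol(mag))
  steps <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    dydx <- steps[[as.character(s)]]
    sel <- sector == s
    n1 <- shift_mat(mag, dydx[1], dydx[2])
    n2 <- shift_mat(mag, -dydx[1], -dydx[2])
    nms[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }

  weak <- nms & mag >= low
  strong <- nms & mag >= high
  edges <- weak
  if (any(weak)) {
    # The component labeller is 4-connected; label a 3x3-dilated copy so the
    # weak-edge chains behave 8-connected, as hysteresis tracking requires.
    lab <- EBImage::bwlabel(EBImage::dilate(weak * 1, matrix(1, 3, 3)) > 0)
    keep <- unique(lab[strong])
    keep <- keep[keep > 0]
    edges <- weak & matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  list(edges = edges, gx = gx, gy = gy, magnitude = mag)
}

# Algebraic (Kasa) least-squares circle fit: solves the linear system for
# x^2 + y^2 = 2 a x + 2 b y + c.
kasa_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  c(cx = sol[1], cy = sol[2], r = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

#' Locate the undeformed cell by Hough circle detection
#'
#' Gradient-direction Hough voting over a radius range, followed by an
#' algebraic least-squares refinement on the edge points near the voted
#' circle. Intended for the first (pre-contact) frame of a sequence, where
#' the cell is circular; the strongest peak corresponds to the cell's outer
#' (ZP) boundary.
#'
#' @param frame Grayscale matrix `[y, x]`, 0-255.
#' @param cfg A [detection_config()].
#' @return An object of class `circle_estimate` with `center` (x, y px),
#'   `radius` (px) and the accumulator `votes`.
#' @export
detect_initial_circle <- function(frame, cfg = detection_config()) {
  ed <- canny_edges(frame, cfg$canny_low, cfg$canny_high, cfg$canny_sigma)
  pts <- which(ed$edges, arr.ind = TRUE)
  if (nrow(pts) == 0) {
    pm_stop("no edges found: cannot locate the cell", "pm_detection_error")
  }
  py <- pts[, 1]; px <- pts[, 2]
  idx <- cbind(py, px)
  mag <- ed$magnitude[idx]
  ux <- ed$gx[idx] / mag; uy <- ed$gy[idx] / mag

  h <- nrow(frame); w <- ncol(frame)
  radii <- seq(cfg$hough_radius_frac[1] * min(h, w),
               cfg$hough_radius_frac[2] * min(h, w),
               by = cfg$hough_radius_step)
  bin <- cfg$hough_bin
  nbx <- ceiling(w / bin); nby <- ceiling(h / bin)

  best <- list(votes = -1)
  for (r in radii) {
    cx <- c(px - r * ux, px + r * ux)
    cy <- c(py - r * uy, py + r * uy)
    ok <- cx >= 1 & cx <= w & cy >= 1 & cy <= h
    if (!any(ok)) next
    bx <- pmin(ceiling(cx[ok] / bin), nbx)
    by <- pmin(ceiling(cy[ok] / bin), nby)
    counts <- tabulate((bx - 1L) * nby + by, nbins = nbx * nby)
    peak <- which.max(counts)
    if (counts[peak] > best$votes) {
      best <- list(votes = counts[peak], r = r,
                   cx = (ceiling(peak / nby) - 0.5) * bin,
                   cy = ((peak - 1L) %% nby + 0.5) * bin)
    }
  }
  if (best$votes < cfg$hough_min_votes) {
    pm_stop(sprintf(
      "no circle found (best accumulator peak %d < %d required)",
      max(best$votes, 0), cfg$hough_min_votes), "pm_detection_error")
  }

  # Sub-pixel refinement on edge points near the voted circle.
  dist <- sqrt((px - best$cx)^2 + (py - best$cy)^2)
  near <- abs(dist - best$r) <= max(4, cfg$hough_radius_step * 2)
  est <- if (sum(near) >= 3) kasa_circle(px[near], py[near]) else
    c(cx = best$cx, cy = best$cy, r = best$r)
  structure(
    list(center = c(x = unname(est["cx"]), y = unname(est["cy"])),
         radius = unname(est["r"]), votes = best$votes),
    class = "circle_estimate"
  )
}

#' @export
print.circle_estimate <- function(x, ...) {
  cat(sprintf("Circle: center (%.1f, %.1f) px, radius %.2f px, %d votes\n",
              x$center["x"], x$center["y"], x$radius, x$votes))
  invisible(x)
}

#' Crop the region of interest around the detected cell
#'
#' Crops the circle's bounding square enlarged by `roi_margin` in both axes
#' (to leave room for the Y elongation of the deforming cell), clipped to the
#' frame. The recorded offset maps ROI coordinates back to frame space:
#' `frame_xy = roi_xy + offset`.
#'
#' @param frame Grayscale matrix `[y, x]`.
#' @param circle A `circle_estimate`.
#' @param cfg A [detection_config()].
#' @return List with `image` (the crop) and `offset` (x, y).
#' @export
extract_roi <- function(frame, circle, cfg = detection_config()) {
  half <- circle$radius * (1 + cfg$roi_margin)
  x0 <- max(1L, floor(circle$center["x"] - half))
  x1 <- min(ncol(frame), ceiling(circle$center["x"] + half))
  y0 <- max(1L, floor(circle$center["y"] - half))
  y1 <- min(nrow(frame), ceiling(circle$center["y"] + half))
  list(image = frame[y0:y1, x0:x1, drop = FALSE],
       offset = c(x = x0 - 1L, y = y0 - 1L))
}

#' Extract the cell contour from a region of interest
#'
#' The contour pipeline: Canny edge detection, morphological close with a
#' square structuring element to bridge broken edges, removal of connected
#' components below the area threshold, then the outer boundary of the
#' largest surviving component (holes filled) traced as a closed polygon.
#'
#' @param roi Grayscale matrix `[y, x]` (a crop from [extract_roi()]).
#' @param cfg A [detection_config()].
#' @return Two-column matrix (`x`, `y`, px, 1-based ROI coordinates) tracing
#'   the contour.
#' @export
detect_contour <- function(roi, cfg = detection_config()) {
  ed <- canny_edges(roi, cfg$canny_low, cfg$canny_high, cfg$canny_sigma)
  if (!any(ed$edges)) {
    pm_stop("no edges found in ROI", "pm_detection_error")
  }
  kern <- matrix(1, cfg$close_window, cfg$close_window)
  closed <- EBImage::erode(EBImage::dilate(ed$edges * 1, kern), kern) > 0
  # The component labeller is 4-connected; a 3x3 dilation bridges diagonal
  # steps of the thin edge curve so each contour labels as one component.
  b3 <- matrix(1, 3, 3)
  thick <- EBImage::dilate(closed * 1, b3)
  lab <- EBImage::bwlabel(thick > 0)
  n <- max(lab)
  if (n == 0) pm_stop("no contour found in ROI", "pm_detection_error")
  # Component areas are measured on the closed edge map itself.
  areas <- tabulate(lab[closed], nbins = n)
  keep <- which(areas >= cfg$min_area)
  if (length(keep) == 0) {
    pm_stop("no contour survives the area filter", "pm_detection_error")
  }
  # Union of surviving components. Canny drops a few pixels at sharp corners,
  # so the boundary curve can arrive in pieces; a second dilate/fill/erode
  # round trip (kernel matched, so boundary position cancels to ~1 px) closes
  # those gaps and turns the curve into a filled region. Concavities wider
  # than the closing window -- such as the needle slot -- survive.
  union <- closed & matrix(lab %in% keep, nrow(lab), ncol(lab))
  half <- max(3L, floor(cfg$close_window / 2) * 2L + 1L)
  bridge <- matrix(1, half, half)
  filled <- EBImage::fillHull(EBImage::dilate(union * 1, bridge))
  region <- EBImage::erode(filled, bridge)
  if (!any(region > 0)) pm_stop("contour region vanished", "pm_detection_error")
  rlab <- EBImage::bwlabel(region > 0)
  rmax <- which.max(tabulate(rlab[rlab > 0], nbins = max(rlab)))
  oc <- EBImage::ocontour((rlab == rmax) * 1)
  poly <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # ocontour reports 0-based (dim1, dim2) indices; dim1 is the image row (y).
  cbind(x = poly[, 2] + 1, y = poly[, 1] + 1)
}

#' Unit conversion ratio from the detected cell size
#'
#' @param actual_radius_um Known cell radius, um.
#' @param detected_radius_px Detected circle radius, px.
#' @return um per px.
#' @examples
#' calibrate(75, 150)
#' @export
calibrate <- function(actual_radius_um, detected_radius_px) {
  stopifnot_scalar_num(actual_radius_um, "actual_radius_um", positive = TRUE)
  stopifnot_scalar_num(detected_radius_px, "detected_radius_px",
                       positive = TRUE)
  actual_radius_um / detected_radius_px
}

# Rightmost-boundary profile of a contour: the maximum x per image row.
right_profile <- function(contour) {
  ys <- round(contour[, 2])
  prof <- tapply(contour[, 1], ys, max)
  list(y = as.numeric(names(prof)), x = as.numeric(prof))
}

#' Deformation metrics of one frame relative to the reference contour
#'
#' Width reduction is the decrease of the contour's axis-aligned bounding-box
#' extent along the penetration (X) axis relative to the reference
#' (pre-contact) contour. The invaginate value is the X distance from the
#' contour's rightmost shoulder to the deepest point of the needle-induced
#' notch: the rightmost-boundary profile (max x per row) has two shoulder
#' maxima flanking the contour centerline, and the notch is the dip between
#' them (restricted to `|y - y_center| <= notch_halfwidth_px` when that is
#' set). Both metrics are reported in um.
#'
#' @param contour_0 Reference (pre-contact) contour polygon, px.
#' @param contour_d Contour at penetration depth `depth`, px.
#' @param um_per_px Unit conversion from [calibrate()].
#' @param depth Penetration depth of this frame, um (carried through).
#' @param notch_halfwidth_px Optional fixed notch band half-width, px.
#' @return One-row data frame: `depth_um`, `width_reduction_um`,
#'   `invaginate_um`, `um_per_px`, `contour_area_px`.
#' @export
compute_metrics <- function(contour_0, contour_d, um_per_px, depth,
                            notch_halfwidth_px = NULL) {
  if (nrow(contour_0) == 0 || nrow(contour_d) == 0) {
    pm_stop("empty contour", "pm_parameter_error")
  }
  stopifnot_scalar_num(um_per_px, "um_per_px", positive = TRUE)
  w0 <- max(contour_0[, 1]) - min(contour_0[, 1])
  wd <- max(contour_d[, 1]) - min(contour_d[, 1])
  width_reduction <- (w0 - wd) * um_per_px

  rp <- right_profile(contour_d)
  yc <- mean(range(contour_d[, 2]))
  top <- which(rp$y >= yc)
  bot <- which(rp$y <= yc)
  invaginate <- 0
  if (length(top) && length(bot)) {
    i_top <- top[which.max(rp$x[top])]
    i_bot <- bot[which.max(rp$x[bot])]
    shoulder <- max(rp$x[i_top], rp$x[i_bot])
    band <- seq(min(i_bot, i_top), max(i_bot, i_top))
    if (!is.null(notch_halfwidth_px)) {
      band <- band[abs(rp$y[band] - yc) <= notch_halfwidth_px]
    }
    if (length(band) > 2) {
      invaginate <- max(shoulder - min(rp$x[band]), 0) * um_per_px
    } else if (depth > 2) {
      pm_warn(sprintf("no notch band found at depth %g um; invaginate set to 0",
                      depth), "pm_no_notch_warning")
    }
  }
  data.frame(depth_um = depth, width_reduction_um = width_reduction,
             invaginate_um = invaginate, um_per_px = um_per_px,
             contour_area_px = polygon_area(contour_d))
}

#' Analyze a penetration image sequence
#'
#' Runs the full deformation-parameter detection: Hough circle localization
#' on the first (pre-contact) frame only, calibration of the um/px ratio
#' against the known cell radius, contour detection on every frame within
#' the shared region of interest, and per-frame deformation metrics against
#' the first frame's contour. Frames whose contour detection fails are
#' reported with a warning and skipped; a failure on the first frame aborts
#' the sequence. Records are returned sorted by penetration depth.
#'
#' @param manifest Manifest CSV path or a data frame with columns `frame`
#'   (file paths) and `depth_um`; the first row must be the pre-contact
#'   frame.
#' @param cfg A [detection_config()].
#' @param cell_radius_um Known cell (outer) radius used for calibration, um.
#' @param overlay_dir Optional directory for annotated overlay PNGs
#'   (contour in red, bounding box in green).
#' @return Data frame with one row per analyzed frame: `depth_um`,
#'   `width_reduction_um`, `invaginate_um`, `um_per_px`, `contour_area_px`.
#' @export
analyze_sequence <- function(manifest, cfg = detection_config(),
                             cell_radius_um = 75, overlay_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) pm_stop("empty manifest", "pm_parameter_error")

  f0 <- read_frame(manifest$frame[1])
  circle <- detect_initial_circle(f0, cfg)
  um_per_px <- calibrate(cell_radius_um, circle$radius)
  roi0 <- extract_roi(f0, circle, cfg)

  contour_0 <- detect_contour(roi0$image, cfg)  # abort if reference fails
  if (!is.null(overlay_dir)) {
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
  }

  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch({
      frame <- read_frame(manifest$frame[i])
      roi <- extract_roi(frame, circle, cfg)
      contour <- if (i == 1) contour_0 else detect_contour(roi$image, cfg)
      m <- compute_metrics(contour_0, contour, um_per_px,
                           manifest$depth_um[i], cfg$notch_halfwidth_px)
      if (!is.null(overlay_dir)) {
        write_overlay(frame, sweep(contour, 2, roi$offset, `+`),
                      file.path(overlay_dir,
                                sprintf("overlay_%03d.png", i - 1L)))
      }
      m
    }, error = function(e) {
      pm_warn(sprintf("frame %s (depth %g um) skipped: %s",
                      basename(manifest$frame[i]), manifest$depth_um[i],
                      conditionMessage(e)), "pm_frame_skipped_warning")
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  out <- do.call(rbind, rows)
  out[order(out$depth_um), , drop = FALSE]
}

# Annotated overlay: contour in red, axis-aligned bounding box in green.
write_overlay <- function(frame, contour_frame_px, path) {
  h <- nrow(frame); w <- ncol(frame)
  rgb <- array(rep(frame / 255, 3), dim = c(h, w, 3))
  xs <- round(contour_frame_px[, 1]); ys <- round(contour_frame_px[, 2])
  ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  paint <- function(yy, xx, channel, value) {
    for (ch in 1:3) {
      rgb[cbind(yy, xx, ch)] <<- if (ch == channel) value else 0
    }
  }
  paint(ys[ok], xs[ok], 1, 1)
  bx <- range(xs); by <- range(ys)
  bxs <- bx[1]:bx[2]; bys <- by[1]:by[2]
  paint(rep(by, each = length(bxs)), rep(bxs, 2), 2, 1)
  paint(rep(bys, 2), rep(bx, each = length(bys)), 2, 1)
  png::writePNG(rgb, path)
  invisible(path)
}
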