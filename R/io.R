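#' Read a grayscale frame from PNG or TIFF
#'
#' Color inputs are converted to grayscale by Rec. 601 luminance.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix `[y, x]` of intensities 0-255.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) {
    pm_stop(sprintf("frame not found: %s", path), "pm_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pm_stop(sprintf("unsupported frame format: .%s", ext), "pm_io_error")
  )
  if (length(dim(arr)) == 3L) {
    # luminance conversion; an alpha channel, if present, is ignored
    arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Write a grayscale frame as 8-bit PNG
#'
#' @param image Numeric matrix `[y, x]` of intensities 0-255.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_frame <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Read a penetration-sequence manifest
#'
#' A manifest is a CSV with header `frame,depth_um` mapping frame filenames
#' (relative to the manifest's directory) to penetration depths.
#'
#' @param path Manifest CSV path.
#' @return Data frame with columns `frame` (absolute paths) and `depth_um`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame", "depth_um") %in% names(m))) {
    pm_stop("manifest must have columns `frame` and `depth_um`",
            "pm_io_error")
  }
  m$frame <- file.path(dirname(normalizePath(path)), m$frame)
  m
}

#' Write deformation records to CSV
#'
#' Writes the vision module's interchange format with header
#' `depth_um,width_reduction_um,invaginate_um,um_per_px`.
#'
#' @param records Data frame as returned by [analyze_sequence()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_deformation_csv <- function(records, path) {
  cols <- c("depth_um", "width_reduction_um", "invaginate_um", "um_per_px")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_deformation_csv
#' @export
read_deformation_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read stress curves from long-format CSV
#'
#' Expects columns `radius_um,depth_um,force_uN`; one [stress_curve()] is
#' built per distinct radius.
#'
#' @param path CSV path.
#' @param cell_radius Cell radius tag for the curves, um.
#' @return List of [stress_curve()] objects.
#' @export
read_stress_curves <- function(path, cell_radius = 75) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("radius_um", "depth_um", "force_uN") %in% names(df))) {
    pm_stop("stress CSV must have columns radius_um, depth_um, force_uN",
            "pm_io_error")
  }
  lapply(split(df, df$radius_um), function(g) {
    g <- g[order(g$depth_um), ]
    stress_curve(depths = g$depth_um, forces = g$force_uN,
                 needle_radius = g$radius_um[1], cell_radius = cell_radius)
  })
}

#' @rdname read_stress_curves
#' @param curves List of [stress_curve()] objects.
#' @export
write_stress_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(radius_um = cv$needle_radius, depth_um = cv$depths,
               force_uN = cv$forces)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
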