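#' Configuration of an end-to-end run
#'
#' Bundles every parameter of the generate - detect - fit pipeline. All
#' stochastic stages derive their seeds from the single run `seed`
#' (frame noise uses `seed + 1`, stress-curve noise `seed + 2`), so a fixed
#' configuration is fully reproducible.
#'
#' @param cell A [cell_spec()].
#' @param deformation A [deformation_params()].
#' @param imaging An [imaging_spec()].
#' @param detection A [detection_config()].
#' @param fit List of fitting options: `radii` (needle radii of the
#'   generated stress curves, um) and `noise_cv` (their noise level).
#' @param seed Integer run seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cell = cell_spec(),
                       deformation = deformation_params(),
                       imaging = imaging_spec(),
                       detection = detection_config(),
                       fit = list(radii = c(5, 7.5, 9, 10, 12.5, 15),
                                  noise_cv = 0.02),
                       seed = 1L) {
  stopifnot(inherits(cell, "cell_spec"),
            inherits(deformation, "deformation_params"),
            inherits(imaging, "imaging_spec"),
            inherits(detection, "detection_config"))
  structure(
    list(cell = cell, deformation = deformation, imaging = imaging,
         detection = detection, fit = fit, seed = as.integer(seed)),
    class = "run_config"
  )
}

strip_class <- function(x) {
  x <- unclass(x)
  x[!vapply(x, is.null, logical(1))]
}

#' Save / load a run configuration
#'
#' Configurations round-trip through YAML or JSON (chosen by file
#' extension): `load_run_config(save_run_config(cfg, path))` reproduces
#' `cfg`.
#'
#' @param cfg A [run_config()].
#' @param path Destination (`.yaml`, `.yml` or `.json`).
#' @return `save_run_config()` the path, invisibly; `load_run_config()` the
#'   restored `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- list(cell = strip_class(cfg$cell),
                deformation = strip_class(cfg$deformation),
                imaging = strip_class(cfg$imaging),
                detection = strip_class(cfg$detection),
                fit = cfg$fit, seed = cfg$seed)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else {
    pm_stop("config path must end in .yaml, .yml or .json", "pm_io_error")
  }
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  plain <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    pm_stop("config path must end in .yaml, .yml or .json", "pm_io_error")
  }
  run_config(
    cell = do.call(cell_spec, plain$cell),
    deformation = do.call(deformation_params, plain$deformation),
    imaging = do.call(imaging_spec, plain$imaging),
    detection = do.call(detection_config, plain$detection),
    fit = plain$fit,
    seed = plain$seed
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    pm_stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            "pm_stage_error")
  })
}

#' Run the full generate - detect - fit pipeline
#'
#' Generates a synthetic penetration sequence, detects deformation
#' parameters from the frames, validates detection against the generator's
#' ground truth, generates stress-depth curves from the empirical stress
#' model, fits the cubic / power-law / joint models, and writes every stage
#' artifact plus a run log into `out_dir`. Identical configuration and seed
#' produce byte-identical CSV outputs.
#'
#' @param cfg A [run_config()].
#' @param out_dir Writable output directory.
#' @return Invisibly, a list with the deformation records, the
#'   truth-vs-detected comparison, the per-radius cubic table and the
#'   power-law and joint fits.
#' @export
run_end_to_end <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, error = function(e) FALSE)
  if (!isTRUE(ok)) {
    pm_stop(sprintf("output directory `%s` is not writable", out_dir),
            "pm_io_error")
  }
  unlink(probe)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("penetromech %s run", as.character(utils::packageVersion("penetromech")))
  logf("R %s", R.version.string)
  logf("--- configuration ---")
  cat(yaml::as.yaml(list(cell = strip_class(cfg$cell),
                         deformation = strip_class(cfg$deformation),
                         imaging = strip_class(cfg$imaging),
                         detection = strip_class(cfg$detection),
                         fit = cfg$fit, seed = cfg$seed)),
      file = log_path, append = TRUE)

  img <- cfg$imaging
  img$seed <- cfg$seed + 1L
  frames_dir <- file.path(out_dir, "frames")
  seq_out <- run_stage("synth",
    generate_sequence(cfg$cell, cfg$deformation, img, frames_dir))
  logf("synth: %d frames in %s", nrow(seq_out$manifest), frames_dir)

  records <- run_stage("detect",
    analyze_sequence(seq_out$manifest_path, cfg$detection,
                     cell_radius_um = cfg$cell$outer_radius))
  write_deformation_csv(records, file.path(out_dir, "deformation.csv"))
  logf("detect: %d records, um/px = %.5f", nrow(records),
       records$um_per_px[1])

  comparison <- run_stage("compare",
    compare_deformation(seq_out$truth, records))
  jsonlite::write_json(unclass(comparison),
                       file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("compare: width r = %.4f, invaginate r = %.4f",
       comparison$width_reduction, comparison$invaginate)

  model <- default_stress_model(cfg$cell$outer_radius)
  curves <- run_stage("stress",
    generate_stress_curves(model$alpha1, model$beta, cfg$fit$radii,
                           depth_schedule(cfg$deformation),
                           noise_cv = cfg$fit$noise_cv,
                           seed = cfg$seed + 2L,
                           cell_radius = cfg$cell$outer_radius))
  write_stress_curves(curves, file.path(out_dir, "stress_curves.csv"))

  fits <- run_stage("fit", {
    alpha_tab <- data.frame(
      radius_um = vapply(curves, function(cv) cv$needle_radius, numeric(1)),
      alpha = vapply(curves, function(cv) unname(coef(fit_cubic(cv))),
                     numeric(1)),
      r_squared = vapply(curves, function(cv) fit_cubic(cv)$r_squared,
                         numeric(1)))
    power <- fit_power_law(alpha_tab$radius_um, alpha_tab$alpha)
    joint <- fit_joint(curves)
    list(alpha_table = alpha_tab, power = power, joint = joint)
  })
  utils::write.csv(fits$alpha_table, file.path(out_dir, "alpha_table.csv"),
                   row.names = FALSE, quote = FALSE)
  report <- list(
    power_law = list(kind = "power_law", params = as.list(coef(fits$power)),
                     r_squared = fits$power$r_squared,
                     n_points = fits$power$n_points),
    joint = list(kind = "joint", params = as.list(coef(fits$joint)),
                 r_squared = fits$joint$r_squared,
                 n_points = fits$joint$n_points))
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("fit: alpha1 = %.6g, beta = %.6g, joint R2 = %.6f",
       coef(fits$joint)["alpha1"], coef(fits$joint)["beta"],
       fits$joint$r_squared)

  invisible(list(records = records, comparison = comparison,
                 alpha_table = fits$alpha_table, power = fits$power,
                 joint = fits$joint))
}

#' Re-fit the packaged reference stress coefficients
#'
#' Runs the radius power-law fit on the packaged per-radius cubic
#' coefficients ([fem_alpha_coefficients()]) and the joint fit on
#' stress-depth curves reconstructed from them over the standard depth
#' schedule (1, 5, 10, ..., 130 um), and prints the fitted `alpha1`, `beta`
#' and pooled R-squared next to the packaged reference values.
#'
#' @return Invisibly, a list with the `power_law_fit`, the `joint_fit` and
#'   the reference [stress_model()].
#' @examples
#' reproduce_reference_fit()
#' @export
reproduce_reference_fit <- function() {
  tab <- fem_alpha_coefficients()
  power <- fit_power_law(tab$radius_um, tab$alpha)
  depths <- c(1, seq(5, 130, by = 5))
  curves <- lapply(seq_len(nrow(tab)), function(i) {
    stress_curve(depths, tab$alpha[i] * depths^3,
                 needle_radius = tab$radius_um[i])
  })
  joint <- fit_joint(curves)
  ref <- default_stress_model(75)

  cat("Reference stress-model fit (75 um cell, six needle radii):\n")
  cat(sprintf("  %-22s %12s %12s\n", "", "packaged", "computed"))
  cat(sprintf("  %-22s %12.4g %12.4g\n", "alpha1 (power law)", ref$alpha1,
              coef(power)["alpha1"]))
  cat(sprintf("  %-22s %12.4f %12.4f\n", "beta (power law)", ref$beta,
              coef(power)["beta"]))
  cat(sprintf("  %-22s %12.4g %12.4g\n", "alpha1 (joint)", ref$alpha1,
              coef(joint)["alpha1"]))
  cat(sprintf("  %-22s %12.4f %12.4f\n", "beta (joint)", ref$beta,
              coef(joint)["beta"]))
  cat(sprintf("  %-22s %12s %12.4f\n", "pooled R-squared", ">= 0.99",
              joint$r_squared))
  invisible(list(power = power, joint = joint, reference = ref))
}
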