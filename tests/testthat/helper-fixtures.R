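# Shared fixtures. Image sequences are generated once per test run and
# cached in tempdir(); everything is built in code, nothing is stored.

.fixture_env <- new.env(parent = emptyenv())

fixture_cell <- function() cell_spec()
fixture_dp <- function() deformation_params()

# A short penetration sequence (7 depths + pre-contact frame) for unit
# tests; the full 27-depth schedule is exercised in the acceptance tests.
fixture_sequence <- function(noise_sigma = 0, seed = 101) {
  key <- sprintf("seq_%g_%d", noise_sigma, seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), paste0("pm_", key))
  out <- generate_sequence(
    fixture_cell(), fixture_dp(),
    imaging_spec(noise_sigma = noise_sigma, seed = seed),
    dir, depths = c(1, 25, 50, 75, 100, 125, 130),
    include_precontact = TRUE)
  out$dir <- dir
  .fixture_env[[key]] <- out
  out
}

fixture_frame0 <- function() {
  seq_out <- fixture_sequence()
  read_frame(file.path(seq_out$dir, "frame_000.png"))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Independent brute-force oracle for polygon extents: plain loops, no reuse
# of package internals.
brute_x_extent <- function(poly) {
  mx <- -Inf; mn <- Inf
  for (i in seq_len(nrow(poly))) {
    xi <- as.numeric(poly[i, 1])
    if (xi > mx) mx <- xi
    if (xi < mn) mn <- xi
  }
  mx - mn
}

# Shoulder-to-notch-tip dip, re-derived with plain loops: rightmost vertex
# of each half-contour, then the minimum x strictly between their heights.
brute_invaginate <- function(poly) {
  xt <- -Inf; yt <- NA; xb <- -Inf; yb <- NA
  for (i in seq_len(nrow(poly))) {
    xi <- as.numeric(poly[i, 1]); yi <- as.numeric(poly[i, 2])
    if (yi >= 0 && xi > xt) { xt <- xi; yt <- yi }
    if (yi <= 0 && xi > xb) { xb <- xi; yb <- yi }
  }
  lo <- min(yt, yb); hi <- max(yt, yb)
  mn <- Inf
  for (i in seq_len(nrow(poly))) {
    xi <- as.numeric(poly[i, 1]); yi <- as.numeric(poly[i, 2])
    if (yi > lo && yi < hi && xi > 0 && xi < mn) mn <- xi
  }
  if (is.finite(mn)) max(max(xt, xb) - mn, 0) else 0
}
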