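# Internal helpers shared across modules.

# Raise a classed condition so callers/tests can distinguish failure modes.
pm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "penetromech_error")))
}

pm_warn <- function(msg, class = "penetromech_warning") {
  warning(warningCondition(msg, class = class))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps all stochastic stages reproducible without touching the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pm_stop(sprintf("`%s` must be a finite numeric scalar", name),
            "pm_parameter_error")
  }
  if (positive && x <= 0) {
    pm_stop(sprintf("`%s` must be > 0", name), "pm_parameter_error")
  }
  if (nonneg && x < 0) {
    pm_stop(sprintf("`%s` must be >= 0", name), "pm_parameter_error")
  }
  invisible(x)
}

# Shoelace area of a polygon given as a two-column (x, y) matrix.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
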