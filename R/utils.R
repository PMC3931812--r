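`%||%` <- function(x, y) if (is.null(x)) y else x

fb_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fretbind_error")))
}

fb_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "fretbind_warning")))
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Clamp values to [0, 1]; excursions within `tol` clamp with a warning,
# larger ones abort. `what` names the quantity in messages.
clamp_unit <- function(x, tol, what = "fraction") {
  lo <- x < 0
  hi <- x > 1
  bad <- (x < -tol) | (x > 1 + tol)
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    fb_stop(
      sprintf("%s outside [0, 1] by more than the clamp tolerance %g (worst: %.4g)",
              what, tol, x[bad][which.max(abs(x[bad] - 0.5))]),
      "fretbind_range_error"
    )
  }
  if (any(lo | hi, na.rm = TRUE)) {
    fb_warn(
      sprintf("%d %s value(s) outside [0, 1] by <= %g were clamped",
              sum(lo | hi, na.rm = TRUE), what, tol),
      "fretbind_clamp"
    )
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fb_stop(sprintf("`%s` must be a single finite number", name),
            "fretbind_parameter_error")
  if (positive && x <= 0)
    fb_stop(sprintf("`%s` must be > 0 (got %g)", name, x),
            "fretbind_parameter_error")
  if (nonneg && x < 0)
    fb_stop(sprintf("`%s` must be >= 0 (got %g)", name, x),
            "fretbind_parameter_error")
  invisible(x)
}
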