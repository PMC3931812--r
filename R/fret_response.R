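#' Fractional biosensor response from an emission ratio
#'
#' Maps a donor/acceptor emission ratio R = F475/F535 onto the fractional
#' response `(R - R_min) / (R_max - R_min)`, where `r_min` and `r_max` are the
#' ratios with the biosensor in the unbound and maximally bound states.
#' Calmodulin binding to the linker disrupts FRET, raising donor (475 nm) and
#' lowering acceptor (535 nm) emission, so the ratio increases monotonically
#' with the bound fraction.
#'
#' @param r Observed emission ratio(s), unitless.
#' @param r_min,r_max Endpoint ratios (unbound / maximally bound). Must
#'   satisfy `r_max > r_min`.
#' @param clamp_tol Values outside `[0, 1]` by at most this amount (noise at
#'   the endpoints) are clamped with a warning; larger excursions are errors.
#' @return Fractional response(s) in `[0, 1]`.
#' @seealso [fractional_from_intensity()], [dynamic_range()]
#' @export
#' @examples
#' fractional_from_ratio(1.5, r_min = 1, r_max = 2)
fractional_from_ratio <- function(r, r_min, r_max, clamp_tol = 0.05) {
  check_number(r_min, "r_min")
  check_number(r_max, "r_max")
  if (r_max <= r_min)
    fb_stop("degenerate endpoints: r_max must exceed r_min",
            "fretbind_degenerate_endpoints")
  clamp_unit((r - r_min) / (r_max - r_min), clamp_tol, "fractional response")
}

#' Fractional biosensor response from a single emission channel
#'
#' Single-channel alternative to the ratiometric form: the donor (475 nm)
#' intensity rises on binding, so its fractional response is
#' `(F - F_min) / (F_max - F_min)`; the acceptor (535 nm) intensity falls, so
#' its response is `(F_max - F) / (F_max - F_min)`. Intensities must already
#' be dilution-corrected (see [apply_dilution_correction()]); the ratiometric
#' form needs no such correction.
#'
#' @param f Observed intensity (a.u.), dilution-corrected.
#' @param f_min,f_max Minimal and maximal observed intensities for the
#'   channel; `f_max > f_min`.
#' @param channel `"donor"` (475 nm) or `"acceptor"` (535 nm).
#' @inheritParams fractional_from_ratio
#' @return Fractional response(s) in `[0, 1]`.
#' @export
fractional_from_intensity <- function(f, f_min, f_max,
                                      channel = c("donor", "acceptor"),
                                      clamp_tol = 0.05) {
  channel <- match.arg(channel)
  check_number(f_min, "f_min")
  check_number(f_max, "f_max")
  if (f_max <= f_min)
    fb_stop("degenerate endpoints: f_max must exceed f_min",
            "fretbind_degenerate_endpoints")
  fract <- if (channel == "donor") (f - f_min) / (f_max - f_min)
           else                    (f_max - f) / (f_max - f_min)
  clamp_unit(fract, clamp_tol, "fractional response")
}

#' Dynamic range of a biosensor
#'
#' Fold difference between the maximally bound and unbound emission ratios,
#' `r_max / r_min`. This proxies the size of the conformational change upon
#' calmodulin binding and is used, alongside the apparent K_d, to judge how
#' well a linker sequence captures the binding domain.
#'
#' @param r_min,r_max Endpoint emission ratios; `r_min > 0`,
#'   `r_max >= r_min`.
#' @return The fold difference (>= 1).
#' @export
#' @examples
#' dynamic_range(1.0, 2.65)
dynamic_range <- function(r_min, r_max) {
  check_number(r_min, "r_min")
  check_number(r_max, "r_max")
  if (r_min <= 0)
    fb_stop("invalid endpoint: r_min must be > 0", "fretbind_invalid_endpoint")
  if (r_max < r_min)
    fb_stop("invalid endpoints: r_max must be >= r_min",
            "fretbind_invalid_endpoint")
  r_max / r_min
}

#' Construct a titration series
#'
#' Container for one cuvette titration: ordered per-addition records of added
#' titrant volume, stock concentration and emission intensities. Step 0 is
#' the baseline before any addition (`added_volume = 0`).
#'
#' @param points Data frame with columns `step`, `added_volume` (µL),
#'   `stock_conc` (µM), `f_donor` (a.u., 475 nm), `f_acceptor` (a.u., 535
#'   nm) and optionally `f_indicator` (a.u., 600 nm).
#' @param initial_volume Starting cuvette volume, µL.
#' @param biosensor_total Total biosensor concentration at step 0, µM.
#' @param titrant_name Label for the titrant (default `"CaM"`).
#' @param temperature Assay temperature, °C (metadata; default 22).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(points, initial_volume, biosensor_total,
                             titrant_name = "CaM", temperature = 22) {
  stopifnot(is.data.frame(points))
  need <- c("step", "added_volume", "stock_conc", "f_donor", "f_acceptor")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols))
    fb_stop(paste0("titration points lack column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "fretbind_schema_error")
  check_number(initial_volume, "initial_volume", positive = TRUE)
  check_number(biosensor_total, "biosensor_total", positive = TRUE)
  if (nrow(points) < 1L)
    fb_stop("titration series needs at least one point", "fretbind_schema_error")
  if (any(points$added_volume < 0))
    fb_stop("added volumes must be >= 0", "fretbind_schedule_error")
  if (points$added_volume[1] != 0)
    fb_stop("step 0 must have added_volume = 0 (baseline)",
            "fretbind_schedule_error")
  if (any(diff(points$step) <= 0))
    fb_stop("step indices must be strictly increasing", "fretbind_schema_error")
  if (any(points$f_donor <= 0) || any(points$f_acceptor <= 0))
    fb_stop("donor and acceptor intensities must be > 0",
            "fretbind_schema_error")
  structure(
    list(points = points, initial_volume = initial_volume,
         biosensor_total = biosensor_total, titrant_name = titrant_name,
         temperature = temperature),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s titration: %d points, V0 = %g uL, [BS] = %g uM\n",
              x$titrant_name, nrow(x$points), x$initial_volume,
              x$biosensor_total))
  invisible(x)
}

#' Dilution-correct a titration series
#'
#' Converts the raw per-addition records into analysis-ready quantities:
#' the cumulative, dilution-corrected titrant concentration at each point,
#' the emission ratio (which needs no dilution correction because both
#' channels are scaled identically), dilution-corrected channel intensities,
#' and the per-point diluted biosensor total. Mass conservation gives, after
#' step k with cumulative added volume W_k,
#' `titrant_total_k = sum(stock_i * v_i) / (V0 + W_k)` and the intensity
#' correction factor `(V0 + W_k) / V0`.
#'
#' Fractional responses are pre-computed from the observed endpoint ratios
#' (min/max) for convenience; model fitting re-estimates the endpoints
#' jointly (see [fit_binding()]) because the final point may be
#' sub-saturating.
#'
#' @param series A [titration_series()].
#' @param clamp_tol Clamp tolerance forwarded to [fractional_from_ratio()].
#' @return A data frame of class `response_series` with columns
#'   `titrant_total` (µM), `ratio`, `bs_fract`, `f_donor_corr`,
#'   `f_acceptor_corr`, `dilution_factor`, `bs_total` (µM, diluted), and
#'   attributes `r_min`, `r_max`, `channel_used`.
#' @export
apply_dilution_correction <- function(series, clamp_tol = 0.05) {
  stopifnot(inherits(series, "titration_series"))
  p <- series$points
  v0 <- series$initial_volume
  w <- cumsum(p$added_volume)
  if (any(w < 0)) fb_stop("negative cumulative volume", "fretbind_schedule_error")
  moles <- cumsum(p$added_volume * p$stock_conc)  # nmol if uL * uM
  vol <- v0 + w
  titrant_total <- moles / vol
  factor <- vol / v0
  ratio <- p$f_donor / p$f_acceptor
  r_min <- min(ratio)
  r_max <- max(ratio)
  bs_fract <- if (r_max > r_min * (1 + 1e-9)) {
    fractional_from_ratio(ratio, r_min, r_max, clamp_tol = clamp_tol)
  } else rep(NA_real_, length(ratio))
  out <- data.frame(
    titrant_total = titrant_total,
    ratio = ratio,
    bs_fract = bs_fract,
    f_donor_corr = p$f_donor * factor,
    f_acceptor_corr = p$f_acceptor * factor,
    dilution_factor = factor,
    bs_total = series$biosensor_total * v0 / vol
  )
  attr(out, "r_min") <- r_min
  attr(out, "r_max") <- r_max
  attr(out, "channel_used") <- "ratio"
  attr(out, "titrant_name") <- series$titrant_name
  class(out) <- c("response_series", "data.frame")
  out
}
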