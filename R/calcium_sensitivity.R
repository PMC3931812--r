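#' Free Ca2+ from indicator fluorescence
#'
#' Calibrates the single-wavelength Ca2+ indicator (X-Rhod-5F, emission 600
#' nm) via `[Ca2+]_free = Kd_ind * (F - F_min) / (F_max - F)`, where `F_min`
#' and `F_max` are the indicator intensities under nominally Ca2+-free and
#' Ca2+-saturating conditions and `Kd_ind` is its in-vitro dissociation
#' constant (1.6 µM by default). At `F = (F_min + F_max) / 2` this returns
#' exactly `Kd_ind`.
#'
#' Readings below `F_min` by at most `clamp_tol` of the span are clamped
#' with a warning; readings at or above `F_max` are a saturation error (the
#' calibration map diverges there), so free Ca2+ is not computable.
#'
#' @param f Indicator intensity (a.u.); may be a vector.
#' @param f_min,f_max Calibration endpoint intensities, `f_min < f_max`.
#' @param kd_ind Indicator dissociation constant for Ca2+, µM (default 1.6).
#' @param clamp_tol Allowed relative excursion below `f_min` (default 0.02).
#' @return Free Ca2+ concentration(s), µM.
#' @export
#' @examples
#' free_calcium(200, f_min = 100, f_max = 300)  # 1.6 uM at half-saturation
free_calcium <- function(f, f_min, f_max, kd_ind = 1.6, clamp_tol = 0.02) {
  check_number(f_min, "f_min")
  check_number(f_max, "f_max")
  check_number(kd_ind, "kd_ind", positive = TRUE)
  if (f_min >= f_max)
    fb_stop("degenerate indicator endpoints: f_max must exceed f_min",
            "fretbind_degenerate_endpoints")
  span <- f_max - f_min
  if (any(f >= f_max))
    fb_stop("indicator reading at or above F_max: saturated, free Ca2+ not computable",
            "fretbind_saturation_error")
  low <- f < f_min
  if (any(f < f_min - clamp_tol * span))
    fb_stop(sprintf(
      "indicator reading below F_min by more than %g of the span", clamp_tol),
      "fretbind_range_error")
  if (any(low)) {
    fb_warn(sprintf("%d indicator reading(s) slightly below F_min were clamped",
                    sum(low)), "fretbind_clamp")
    f <- pmax(f, f_min)
  }
  kd_ind * (f - f_min) / (f_max - f)
}

#' Hill Ca2+-dependence curve
#'
#' Bound fraction as a function of free Ca2+:
#' `f = Ca^n / (EC50^n + Ca^n)`, with `n` the Hill coefficient. At `n = 1`
#' this is the hyperbola [predict_hyperbolic()].
#'
#' @param ca Free Ca2+ concentration(s), µM (>= 0).
#' @param ec50 Half-maximal free Ca2+, µM (> 0).
#' @param n Hill coefficient (> 0).
#' @return Fraction(s) in `[0, 1)`.
#' @export
predict_hill <- function(ca, ec50, n) {
  check_number(ec50, "ec50", positive = TRUE)
  check_number(n, "n", positive = TRUE)
  if (any(ca < 0)) fb_stop("ca must be >= 0", "fretbind_parameter_error")
  # work on the log scale to avoid overflow at extreme ca/ec50 ratios
  t <- (ca / ec50)^n
  t / (1 + t)
}

#' Fit a Hill curve to fractional responses vs free Ca2+
#'
#' Least-squares estimate of (EC50, n) — and optionally a free amplitude,
#' used for the species-1 segment of biphasic curves — by bounded
#' Levenberg–Marquardt, multi-started over log-spaced EC50 seeds crossed
#' with n in {0.8, 1.5, 2.5}. Bounds: `n` in [0.3, 6], `ec50` in
#' [1e-3, 1e3] µM, amplitude in (0, 1].
#'
#' @param free_ca Free Ca2+ values, µM; strictly positive.
#' @param bs_fract Fractional biosensor responses.
#' @param fit_amplitude If `TRUE` the plateau amplitude is a free parameter;
#'   otherwise it is fixed at 1.
#' @param min_points Minimum number of points required (default 5).
#' @return An object of class `hill_fit`: list with `ec50`, `hill_n`,
#'   `amplitude`, `rss`, `converged`, `ec50_se`, `hill_n_se`, `n_points`.
#' @export
fit_hill <- function(free_ca, bs_fract, fit_amplitude = FALSE,
                     min_points = 5L) {
  if (length(free_ca) != length(bs_fract))
    fb_stop("free_ca and bs_fract lengths differ", "fretbind_parameter_error")
  if (length(free_ca) < min_points)
    fb_stop(sprintf("at least %d points are required for a Hill fit",
                    min_points), "fretbind_fit_error")
  if (any(free_ca <= 0) || any(!is.finite(free_ca)))
    fb_stop("free_ca must be strictly positive and finite",
            "fretbind_fit_error")
  if (diff(range(bs_fract)) < 0.02)
    fb_stop("no signal: fractional responses are flat", "fretbind_fit_failure")

  y <- bs_fract
  ec50_seeds <- 10^seq(log10(max(min(free_ca), 1e-3)),
                       log10(min(max(free_ca), 1e3)), length.out = 5)
  n_seeds <- c(0.8, 1.5, 2.5)
  if (fit_amplitude) {
    resid <- function(p) p[["amp"]] * predict_hill(free_ca, p[["ec50"]],
                                                   p[["n"]]) - y
    starts <- do.call(c, lapply(ec50_seeds, function(e)
      lapply(n_seeds, function(nn)
        c(ec50 = e, n = nn, amp = min(max(max(y), 0.05), 1)))))
    lower <- c(ec50 = 1e-3, n = 0.3, amp = 1e-6)
    upper <- c(ec50 = 1e3, n = 6, amp = 1)
  } else {
    resid <- function(p) predict_hill(free_ca, p[["ec50"]], p[["n"]]) - y
    starts <- do.call(c, lapply(ec50_seeds, function(e)
      lapply(n_seeds, function(nn) c(ec50 = e, n = nn))))
    lower <- c(ec50 = 1e-3, n = 0.3)
    upper <- c(ec50 = 1e3, n = 6)
  }
  fit <- multistart_lm(resid, starts, lower, upper, key = "ec50")
  if (is.null(fit))
    fb_stop("Hill fit failed to converge from any start",
            "fretbind_fit_failure")
  p <- fit$par
  structure(
    list(ec50 = unname(p[["ec50"]]), hill_n = unname(p[["n"]]),
         amplitude = if (fit_amplitude) unname(p[["amp"]]) else 1,
         rss = fit$deviance, converged = TRUE,
         ec50_se = param_se(fit, "ec50"), hill_n_se = param_se(fit, "n"),
         n_points = length(free_ca)),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> EC50 = %.4g uM, n = %.3f, amplitude = %.3f, RSS = %.3g, n_points = %d\n",
    x$ec50, x$hill_n, x$amplitude, x$rss, x$n_points))
  invisible(x)
}

#' Segmented biphasic decomposition of a Ca2+-response curve
#'
#' Some complexes (notably those of the first submembrane domain) form in
#' two distinct species with drastically different Ca2+ sensitivities. This
#' reproduces the published procedure: species 1 is a Hill fit (with free
#' amplitude) restricted to points with free Ca2+ at or below the breakpoint
#' (1 µM by default); "species 2" is the Hill fit of the entire population,
#' which the more abundant high-Ca2+ species dominates. The curve is flagged
#' biphasic when the species-1 fit converges with amplitude >= 0.05, its
#' EC50 falls below the breakpoint while the global EC50 does not, and the
#' segmented model improves on the single global fit by an F-ratio test at
#' `alpha` (default 0.05) — a formalization of the published visual
#' judgement.
#'
#' @param free_ca Free Ca2+ values, µM; strictly positive.
#' @param bs_fract Fractional biosensor responses.
#' @param breakpoint Free Ca2+ boundary between species, µM (default 1.0).
#' @param amplitude_min Minimum species-1 amplitude to count as real signal.
#' @param alpha F-test level for the segmented-vs-global comparison.
#' @return An object of class `ca_sensitivity`: list with `species1`
#'   (a `hill_fit` or `NULL`), `species2_or_global` (`hill_fit`), `biphasic`,
#'   `breakpoint`, `f_pvalue`, `free_ca`, `bs_fract`.
#' @export
decompose_biphasic <- function(free_ca, bs_fract, breakpoint = 1.0,
                               amplitude_min = 0.05, alpha = 0.05) {
  check_number(breakpoint, "breakpoint", positive = TRUE)
  global <- fit_hill(free_ca, bs_fract, fit_amplitude = FALSE)
  low <- free_ca <= breakpoint
  species1 <- NULL
  p_val <- NA_real_
  if (sum(low) >= 4L) {
    species1 <- tryCatch(
      fit_hill(free_ca[low], bs_fract[low], fit_amplitude = TRUE,
               min_points = 4L),
      error = function(e) NULL)
  }
  biphasic <- FALSE
  if (!is.null(species1) && species1$converged) {
    # F-ratio on the low-Ca2+ segment, where the segmented and global models
    # differ: null = the global Hill curve evaluated there (no local
    # parameters), alternative = the 3-parameter species-1 fit
    resid_global_low <- predict_hill(free_ca[low], global$ec50,
                                     global$hill_n) - bs_fract[low]
    rss_null <- sum(resid_global_low^2)
    rss_alt <- species1$rss
    df2 <- sum(low) - 3L
    if (df2 > 0 && rss_null > 1e-16 && rss_alt < rss_null) {
      f_stat <- ((rss_null - rss_alt) / 3) / (rss_alt / df2)
      p_val <- stats::pf(f_stat, 3, df2, lower.tail = FALSE)
    } else {
      p_val <- 1
    }
    biphasic <- species1$amplitude >= amplitude_min &&
      species1$ec50 < breakpoint &&
      global$ec50 >= breakpoint &&
      is.finite(p_val) && p_val < alpha
  }
  structure(
    list(species1 = species1, species2_or_global = global,
         biphasic = biphasic, breakpoint = breakpoint, f_pvalue = p_val,
         free_ca = free_ca, bs_fract = bs_fract),
    class = "ca_sensitivity")
}

#' @export
print.ca_sensitivity <- function(x, ...) {
  cat(sprintf("<ca_sensitivity> %s (breakpoint %.3g uM)\n",
              if (x$biphasic) "biphasic" else "monophasic", x$breakpoint))
  if (!is.null(x$species1)) {
    cat("  species 1 (low Ca2+): "); print(x$species1)
  }
  if (!is.null(x$species2_or_global)) {
    cat("  global / species 2:   "); print(x$species2_or_global)
  }
  invisible(x)
}

#' Construct a Ca2+-titration assay series
#'
#' Container for a dual-channel Ca2+ titration in which biosensor FRET
#' ratio and a Ca2+ indicator are monitored simultaneously at saturating
#' calmodulin. Indicator calibration endpoints must come from calibration
#' records (the nominally Ca2+-free start and the Ca2+-saturating end of
#' the assay); they are never guessed from the data.
#'
#' @param points Data frame with columns `step`, `added_volume` (µL),
#'   `stock_conc` (µM, of the Ca2+ stock), `f_donor`, `f_acceptor` and
#'   `f_indicator` (a.u., 600 nm).
#' @param initial_volume Starting cuvette volume, µL.
#' @param indicator_f_min,indicator_f_max Calibrated indicator endpoint
#'   intensities (Ca2+-free / Ca2+-saturated).
#' @param indicator_kd Indicator Ca2+ dissociation constant, µM (default
#'   1.6).
#' @param cam_total Saturating calmodulin concentration in the mix, µM.
#' @param biosensor_total Total biosensor concentration, µM (default 0.5).
#' @param chelator Chelator label + concentration (metadata), e.g.
#'   `"Br2BAPTA 0.25 mM"`.
#' @return An object of class `ca_assay_series`.
#' @export
ca_assay_series <- function(points, initial_volume, indicator_f_min,
                            indicator_f_max, indicator_kd = 1.6,
                            cam_total = NA_real_, biosensor_total = 0.5,
                            chelator = "") {
  stopifnot(is.data.frame(points))
  need <- c("step", "added_volume", "stock_conc", "f_donor", "f_acceptor",
            "f_indicator")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols))
    fb_stop(paste0("Ca2+ assay points lack column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "fretbind_config_error")
  if (all(is.na(points$f_indicator)))
    fb_stop("Ca2+ assay requires a populated indicator channel (F600)",
            "fretbind_config_error")
  check_number(initial_volume, "initial_volume", positive = TRUE)
  check_number(indicator_f_min, "indicator_f_min")
  check_number(indicator_f_max, "indicator_f_max")
  if (indicator_f_max <= indicator_f_min)
    fb_stop("indicator_f_max must exceed indicator_f_min",
            "fretbind_degenerate_endpoints")
  structure(
    list(points = points, initial_volume = initial_volume,
         indicator_f_min = indicator_f_min, indicator_f_max = indicator_f_max,
         indicator_kd = indicator_kd, cam_total = cam_total,
         biosensor_total = biosensor_total, chelator = chelator),
    class = "ca_assay_series")
}

#' @export
print.ca_assay_series <- function(x, ...) {
  cat(sprintf(
    "<ca_assay_series> %d points, indicator Kd %.3g uM, [CaM] %.3g uM, %s\n",
    nrow(x$points), x$indicator_kd, x$cam_total, x$chelator))
  invisible(x)
}

#' Run the Ca2+-sensitivity pipeline on an assay
#'
#' Full analysis of a dual-channel Ca2+ titration: per-point free Ca2+ from
#' the indicator calibration ([free_calcium()]), fractional biosensor
#' responses from the emission ratio with endpoints taken from the nominally
#' Ca2+-free first point and the saturating maximum, then the segmented
#' biphasic decomposition ([decompose_biphasic()]). Points whose indicator
#' reading is saturated (at or above `indicator_f_max`) are excluded from
#' fitting with a warning; the baseline (free Ca2+ = 0) anchors the ratio
#' endpoint but does not enter the Hill fit.
#'
#' @param assay A [ca_assay_series()].
#' @param breakpoint,amplitude_min,alpha Passed to [decompose_biphasic()].
#' @param clamp_tol Clamp tolerance for the fractional-response map.
#' @param saturation_margin Indicator readings within this fraction of the
#'   calibration span below `indicator_f_max` are treated as saturated: the
#'   calibration inverse has a vanishing denominator there, so measurement
#'   noise is amplified without bound. Default 0.02 (i.e. the usable range
#'   ends near 50x the indicator Kd).
#' @return A `ca_sensitivity` object carrying, additionally, the per-point
#'   traces `free_ca` and `bs_fract` for all non-excluded points. If no
#'   point shows free Ca2+ above zero, no fit is attempted and the result
#'   has `species1 = NULL`, `species2_or_global = NULL`, `biphasic = FALSE`.
#' @export
run_ca_assay <- function(assay, breakpoint = 1.0, amplitude_min = 0.05,
                         alpha = 0.05, clamp_tol = 0.05,
                         saturation_margin = 0.02) {
  stopifnot(inherits(assay, "ca_assay_series"))
  p <- assay$points
  ratio <- p$f_donor / p$f_acceptor
  fi <- p$f_indicator
  span <- assay$indicator_f_max - assay$indicator_f_min
  saturated <- fi >= assay$indicator_f_max - saturation_margin * span
  if (any(saturated))
    fb_warn(sprintf(
      "%d point(s) with saturated indicator readings excluded from fitting",
      sum(saturated)), "fretbind_saturation")
  free_ca <- rep(NA_real_, length(fi))
  free_ca[!saturated] <- free_calcium(
    fi[!saturated], assay$indicator_f_min, assay$indicator_f_max,
    kd_ind = assay$indicator_kd)
  use <- !saturated & is.finite(free_ca) & free_ca > 0
  if (!any(use)) {
    # e.g. the indicator never left F_min: free Ca2+ stayed at zero, there
    # is nothing to fit
    return(structure(
      list(species1 = NULL, species2_or_global = NULL, biphasic = FALSE,
           breakpoint = breakpoint, f_pvalue = NA_real_,
           free_ca = free_ca, bs_fract = rep(NA_real_, length(fi))),
      class = "ca_sensitivity"))
  }
  r_min <- min(ratio) # nominally Ca2+-free state (noise-robust estimate)
  r_max <- max(ratio) # Ca2+-saturating end of the assay
  if (r_max <= r_min)
    fb_stop("assay shows no ratio increase between the Ca2+-free and saturating states",
            "fretbind_degenerate_endpoints")
  bs_fract <- fractional_from_ratio(ratio, r_min, r_max,
                                    clamp_tol = clamp_tol)
  res <- decompose_biphasic(free_ca[use], bs_fract[use],
                            breakpoint = breakpoint,
                            amplitude_min = amplitude_min, alpha = alpha)
  res$free_ca <- free_ca
  res$bs_fract <- bs_fract
  res
}
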