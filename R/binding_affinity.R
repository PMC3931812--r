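#' Hyperbolic single-site binding isotherm
#'
#' Fraction of biosensor bound at a free-ligand approximation:
#' `f = [CaM] / (Kd + [CaM])`. Valid when the biosensor concentration is
#' negligible relative to Kd (no ligand depletion).
#'
#' @param cam Total calmodulin concentration(s), µM (treated as free).
#' @param kd Dissociation constant, µM (> 0).
#' @return Bound fraction(s) in `[0, 1)`.
#' @export
predict_hyperbolic <- function(cam, kd) {
  check_number(kd, "kd", positive = TRUE)
  if (any(cam < 0)) fb_stop("cam must be >= 0", "fretbind_parameter_error")
  cam / (kd + cam)
}

#' Quadratic (ligand-depletion) single-site binding isotherm
#'
#' Exact mass-action bound fraction when bound ligand is a non-negligible
#' share of total ligand. With totals `[BS]` and `[CaM]` and
#' `S = Kd + [BS] + [CaM]`, the physical root is
#' `f = (S - sqrt(S^2 - 4 [BS] [CaM])) / (2 [BS])`, evaluated here in the
#' numerically stable form `f = 2 [CaM] / (S + sqrt(S^2 - 4 [BS] [CaM]))`.
#' Reduces to [predict_hyperbolic()] when `[BS] << Kd`.
#'
#' @param cam_total Total calmodulin concentration(s), µM.
#' @param bs_total Total biosensor concentration(s), µM (> 0); recycled
#'   against `cam_total`.
#' @param kd Dissociation constant, µM (> 0).
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
predict_quadratic <- function(cam_total, bs_total, kd) {
  check_number(kd, "kd", positive = TRUE)
  if (any(cam_total < 0)) fb_stop("cam_total must be >= 0",
                                  "fretbind_parameter_error")
  if (any(bs_total <= 0)) fb_stop("bs_total must be > 0",
                                  "fretbind_parameter_error")
  s <- kd + bs_total + cam_total
  disc <- s^2 - 4 * bs_total * cam_total
  if (any(disc < -1e-8 * s^2))
    fb_stop("negative discriminant in quadratic isotherm",
            "fretbind_numerical_error")
  2 * cam_total / (s + sqrt(pmax(disc, 0)))
}

#' Fit an apparent dissociation constant to a titration
#'
#' Least-squares estimation of the apparent Kd of the biosensor–calmodulin
#' interaction from a [response_series][apply_dilution_correction]. By
#' default the fit operates in measured-ratio space,
#' `R(c) = r_min + (r_max - r_min) f(c; Kd)`, with the endpoint ratios free
#' parameters estimated jointly with Kd (the final titration point may be
#' sub-saturating, so endpoints are not taken from the data). Levenberg–
#' Marquardt optimization is multi-started over 7 log-spaced Kd seeds
#' spanning 0.01–1000 µM; the lowest-RSS convergent fit wins and RSS ties
#' (< 1e-12) break toward the smaller Kd.
#'
#' @param response A `response_series` (or data frame with columns
#'   `titrant_total`, `ratio` and, for `response_model = "fraction"`,
#'   `bs_fract`).
#' @param bs_total Total biosensor concentration, µM: a scalar or per-point
#'   vector. Defaults to the diluted per-point totals carried on the
#'   response series.
#' @param model `"auto"`, `"hyperbolic"` or `"quadratic"`. `"auto"` fits the
#'   quadratic depletion isotherm and keeps it when the fitted Kd is below
#'   `10 * bs_total` (where depletion error of the hyperbola matters),
#'   otherwise refits hyperbolically; the choice is recorded.
#' @param response_model `"affine_ratio"` (default; ratio affine in bound
#'   fraction), `"fraction"` (data already normalized to bound fraction) or
#'   `"spectral_ratio"` (ratio of two affine channels,
#'   `R = (a + b f) / (1 + d f)`, for data whose acceptor channel changes on
#'   binding).
#' @param dr_threshold Observed dynamic range below which the series is
#'   declared non-binding (default 1.02).
#' @param kd_seeds Multi-start Kd seeds, µM.
#' @return An object of class `binding_fit`: a list with `kd_app`, `kd_se`,
#'   `r_min_fit`, `r_max_fit`, `dynamic_range`, `model`, `response_model`,
#'   `rss`, `n_points`, `converged`, `binding_detected`.
#' @export
fit_binding <- function(response, bs_total = NULL,
                        model = c("auto", "hyperbolic", "quadratic"),
                        response_model = c("affine_ratio", "fraction",
                                           "spectral_ratio"),
                        dr_threshold = 1.02,
                        kd_seeds = 10^seq(-2, 3, length.out = 7)) {
  model <- match.arg(model)
  response_model <- match.arg(response_model)
  stopifnot(is.data.frame(response))
  if (!all(c("titrant_total", "ratio") %in% names(response)))
    fb_stop("response must carry titrant_total and ratio columns",
            "fretbind_schema_error")
  cam <- response$titrant_total
  n <- length(cam)
  if (n < 4L)
    fb_stop("at least 4 titration points are required for a fit",
            "fretbind_fit_error")
  if (is.null(bs_total)) bs_total <- response$bs_total
  if (is.null(bs_total) && model != "hyperbolic")
    fb_stop("bs_total is required for the quadratic/depletion model",
            "fretbind_parameter_error")
  if (!is.null(bs_total)) bs_total <- rep_len(bs_total, n)

  obs_dr <- max(response$ratio) / min(response$ratio)
  if (obs_dr < dr_threshold) {
    out <- structure(
      list(kd_app = NA_real_, kd_se = NA_real_,
           r_min_fit = min(response$ratio), r_max_fit = max(response$ratio),
           dynamic_range = obs_dr, model = "none",
           response_model = response_model, rss = NA_real_, n_points = n,
           converged = FALSE, binding_detected = FALSE),
      class = "binding_fit")
    fb_warn(sprintf(
      "flat response (observed dynamic range %.4f < %.3f): no binding detected",
      obs_dr, dr_threshold), "fretbind_no_binding")
    return(out)
  }

  fit_one_model <- function(mod) {
    ffun <- if (mod == "quadratic") {
      function(kd) predict_quadratic(cam, bs_total, kd)
    } else {
      function(kd) predict_hyperbolic(cam, kd)
    }
    y <- if (response_model == "fraction") response$bs_fract else response$ratio
    if (anyNA(y))
      fb_stop("response values contain NA", "fretbind_fit_error")
    spec <- switch(response_model,
      fraction = list(
        resid = function(p) ffun(p[["kd"]]) - y,
        start = function(kd0) c(kd = kd0),
        lower = c(kd = 1e-9), upper = c(kd = 1e9)),
      affine_ratio = list(
        resid = function(p) p[["r_min"]] +
          (p[["r_max"]] - p[["r_min"]]) * ffun(p[["kd"]]) - y,
        start = function(kd0) c(r_min = min(y), r_max = max(y), kd = kd0),
        lower = c(r_min = 1e-8, r_max = 1e-8, kd = 1e-9),
        upper = c(r_min = Inf, r_max = Inf, kd = 1e9)),
      spectral_ratio = list(
        resid = function(p) (p[["a"]] + p[["b"]] * ffun(p[["kd"]])) /
          (1 + p[["d"]] * ffun(p[["kd"]])) - y,
        start = function(kd0) c(a = min(y), b = max(y) - min(y), d = -0.1,
                                kd = kd0),
        lower = c(a = 1e-8, b = -Inf, d = -0.999, kd = 1e-9),
        upper = c(a = Inf, b = Inf, d = 10, kd = 1e9)))
    multistart_lm(spec$resid, lapply(kd_seeds, spec$start),
                  spec$lower, spec$upper, key = "kd")
  }

  chosen <- if (model == "auto") "quadratic" else model
  fit <- fit_one_model(chosen)
  if (model == "auto" && !is.null(fit) &&
      fit$par[["kd"]] >= 10 * mean(bs_total)) {
    chosen <- "hyperbolic"
    fit <- fit_one_model(chosen)
  }
  if (is.null(fit))
    fb_stop(sprintf(
      "binding fit failed to converge from any of %d Kd starts (model %s)",
      length(kd_seeds), chosen), "fretbind_fit_failure")

  p <- fit$par
  endpoints <- switch(response_model,
    fraction = c(attr(response, "r_min") %||% NA_real_,
                 attr(response, "r_max") %||% NA_real_),
    affine_ratio = c(p[["r_min"]], p[["r_max"]]),
    spectral_ratio = c(p[["a"]], (p[["a"]] + p[["b"]]) / (1 + p[["d"]])))
  dr <- if (anyNA(endpoints)) obs_dr else endpoints[2] / endpoints[1]
  structure(
    list(kd_app = unname(p[["kd"]]), kd_se = param_se(fit, "kd"),
         r_min_fit = unname(endpoints[1]), r_max_fit = unname(endpoints[2]),
         dynamic_range = unname(dr), model = chosen,
         response_model = response_model, rss = fit$deviance, n_points = n,
         converged = TRUE, binding_detected = TRUE),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$binding_detected) {
    cat(sprintf("<binding_fit> no binding detected (DR %.3f)\n",
                x$dynamic_range))
    return(invisible(x))
  }
  cat(sprintf(
    "<binding_fit> Kd_app = %.4g uM (SE %.3g), DR = %.3f, model = %s/%s, RSS = %.3g, n = %d\n",
    x$kd_app, x$kd_se, x$dynamic_range, x$model, x$response_model, x$rss,
    x$n_points))
  invisible(x)
}

#' Titrant concentration needed for a target saturation
#'
#' Smallest total titrant concentration at which the predicted bound
#' fraction reaches `coverage`. For the hyperbola this is
#' `kd * coverage / (1 - coverage)`; for the depletion (quadratic) model the
#' bound biosensor must be supplied too, giving
#' `kd * coverage / (1 - coverage) + coverage * bs_total`. Used to pick
#' saturating calmodulin concentrations for downstream Ca2+-sensitivity
#' assays.
#'
#' @param kd Dissociation constant, µM.
#' @param bs_total Total biosensor concentration, µM (quadratic model only).
#' @param coverage Target bound fraction in (0, 1); default 0.95.
#' @param model `"hyperbolic"` or `"quadratic"`.
#' @return Total titrant concentration, µM.
#' @export
saturating_concentration <- function(kd, bs_total = 0, coverage = 0.95,
                                     model = c("hyperbolic", "quadratic")) {
  model <- match.arg(model)
  check_number(kd, "kd", positive = TRUE)
  check_number(coverage, "coverage", positive = TRUE)
  if (coverage >= 1)
    fb_stop("coverage must be < 1", "fretbind_parameter_error")
  free_needed <- kd * coverage / (1 - coverage)
  if (model == "hyperbolic") free_needed
  else {
    check_number(bs_total, "bs_total", nonneg = TRUE)
    free_needed + coverage * bs_total
  }
}

#' Fold difference between two dissociation constants
#'
#' @param kd_a,kd_b Dissociation constants, µM (> 0).
#' @return List with `fold = kd_a / kd_b` and `nearest` (rounded to the
#'   nearest integer fold).
#' @export
#' @examples
#' fold_difference(3.41, 0.44)  # ~8-fold weaker affinity
fold_difference <- function(kd_a, kd_b) {
  check_number(kd_a, "kd_a", positive = TRUE)
  check_number(kd_b, "kd_b", positive = TRUE)
  fold <- kd_a / kd_b
  list(fold = fold, nearest = round(fold))
}

# --- internal optimization helpers -----------------------------------------

# Multi-start Levenberg-Marquardt over a list of start vectors. Returns the
# converged nls.lm fit with lowest RSS; ties (< 1e-12) break toward the
# smaller value of par[[key]]. NULL if nothing converges.
multistart_lm <- function(resid_fn, starts, lower, upper, key) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4) ||
        !all(is.finite(unlist(fit$par)))) next
    if (is.null(best) ||
        fit$deviance < best$deviance - 1e-12 ||
        (abs(fit$deviance - best$deviance) <= 1e-12 &&
         fit$par[[key]] < best$par[[key]])) {
      best <- fit
    }
  }
  best
}

# 1-sigma standard error of one parameter from the fit Jacobian; NA when the
# covariance is not estimable (e.g. zero-residual fits or boundary solutions).
param_se <- function(fit, name) {
  se <- tryCatch({
    s <- summary(fit)
    unname(s$coefficients[name, "Std. Error"])
  }, error = function(e) NA_real_)
  if (length(se) != 1L || !is.finite(se)) NA_real_ else se
}
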