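#' Define a Ca2+-buffering species
#'
#' A 1:1 (per site) Ca2+ ligand used by the free-Ca2+ equilibrium solver:
#' a chelator (BAPTA, Br2BAPTA), the indicator dye, or calmodulin modelled
#' as `n_sites` identical independent sites.
#'
#' @param name Label.
#' @param total Total concentration, µM (>= 0).
#' @param kd_ca Per-site Ca2+ dissociation constant, µM (> 0).
#' @param n_sites Number of identical sites per molecule (default 1).
#' @return A list of class `buffer_species`.
#' @export
#' @examples
#' buffer_species("Br2BAPTA", total = 250, kd_ca = 1.6)
#' buffer_species("CaM", total = 10, kd_ca = 2, n_sites = 4)
buffer_species <- function(name, total, kd_ca, n_sites = 1L) {
  check_number(total, "total", nonneg = TRUE)
  check_number(kd_ca, "kd_ca", positive = TRUE)
  if (n_sites < 1) fb_stop("n_sites must be >= 1", "fretbind_parameter_error")
  structure(list(name = name, total = total, kd_ca = kd_ca,
                 n_sites = n_sites),
            class = "buffer_species")
}

#' Solve the competitive Ca2+-buffer equilibrium for free Ca2+
#'
#' Finds the unique `x >= 0` satisfying the conservation equation
#' `ca_total = x + sum_j n_j T_j x / (kd_j + x)` over all buffer species j,
#' by safeguarded bracketing (the left side is strictly increasing in x)
#' followed by Newton polishing to a conservation residual below 1e-9
#' relative.
#'
#' @param ca_total Total Ca2+ concentration(s), µM (>= 0); vectorized.
#' @param buffers List of [buffer_species()] (may be empty).
#' @return Free Ca2+ concentration(s), µM.
#' @export
solve_free_ca <- function(ca_total, buffers = list()) {
  if (inherits(buffers, "buffer_species")) buffers <- list(buffers)
  if (any(ca_total < 0))
    fb_stop("ca_total must be >= 0", "fretbind_parameter_error")
  nt <- vapply(buffers, function(b) b$n_sites * b$total, numeric(1))
  kd <- vapply(buffers, function(b) b$kd_ca, numeric(1))
  bound <- function(x) if (length(nt)) sum(nt * x / (kd + x)) else 0
  dbound <- function(x) if (length(nt)) sum(nt * kd / (kd + x)^2) else 0
  vapply(ca_total, function(ct) {
    if (ct == 0) return(0)
    if (!length(nt)) return(ct)
    g <- function(x) x + bound(x) - ct
    x <- stats::uniroot(g, lower = 0, upper = ct,
                        tol = .Machine$double.eps^0.75)$root
    for (i in 1:3) {  # Newton polish for a tight conservation residual
      step <- g(x) / (1 + dbound(x))
      x <- max(x - step, 0)
    }
    if (abs(g(x)) > 1e-9 * max(ct, 1))
      fb_stop(sprintf(
        "free-Ca2+ solver did not meet tolerance (residual %.3g at total %.3g)",
        g(x), ct), "fretbind_solver_error")
    x
  }, numeric(1))
}

#' Total Ca2+ required for a target free Ca2+ level
#'
#' Closed-form inverse of the buffer equilibrium: for a desired free level
#' `x`, `ca_total = x + sum_j n_j T_j x / (kd_j + x)`. Used to design Ca2+
#' addition schedules that stage free Ca2+ at chosen values.
#'
#' @param free_ca Desired free Ca2+ value(s), µM.
#' @param buffers List of [buffer_species()].
#' @return Total Ca2+ concentration(s), µM.
#' @export
total_ca_for_free <- function(free_ca, buffers = list()) {
  if (inherits(buffers, "buffer_species")) buffers <- list(buffers)
  if (any(free_ca < 0))
    fb_stop("free_ca must be >= 0", "fretbind_parameter_error")
  nt <- vapply(buffers, function(b) b$n_sites * b$total, numeric(1))
  kd <- vapply(buffers, function(b) b$kd_ca, numeric(1))
  vapply(free_ca, function(x)
    x + (if (length(nt)) sum(nt * x / (kd + x)) else 0), numeric(1))
}

#' Build an addition schedule hitting target cumulative concentrations
#'
#' Given desired cumulative titrant totals (already dilution-corrected) and
#' a single stock concentration, computes the per-step volumes to add to an
#' initial volume `v0`: after step k with cumulative volume `W_k`, the total
#' is `stock * W_k / (v0 + W_k)`, so `W_k = C_k v0 / (stock - C_k)`.
#'
#' @param targets Strictly increasing cumulative concentrations, µM.
#' @param initial_volume Initial cuvette volume, µL.
#' @param stock_conc Stock concentration, µM; must exceed `max(targets)`.
#' @return Data frame with columns `added_volume` (µL) and `stock_conc`
#'   (µM), one row per addition (baseline step excluded).
#' @export
titration_schedule <- function(targets, initial_volume, stock_conc) {
  check_number(initial_volume, "initial_volume", positive = TRUE)
  check_number(stock_conc, "stock_conc", positive = TRUE)
  if (any(diff(targets) <= 0) || any(targets <= 0))
    fb_stop("targets must be strictly increasing and positive",
            "fretbind_schedule_error")
  if (max(targets) >= stock_conc)
    fb_stop("stock concentration must exceed the largest target",
            "fretbind_schedule_error")
  w <- targets * initial_volume / (stock_conc - targets)
  data.frame(added_volume = diff(c(0, w)), stock_conc = stock_conc)
}

#' Generator configuration for synthetic titrations
#'
#' Bundles the ground-truth parameters and experiment design used by
#' [simulate_cam_titration()] and [simulate_ca_assay()]. Defaults mirror
#' the published assay conditions: 0.5 µM biosensor in a 2000 µL cuvette,
#' unbound ratio 1.0.
#'
#' @param true_kd True dissociation constant for calmodulin titrations, µM.
#' @param true_hill Data frame with columns `ec50` (µM), `n` and `weight`
#'   (one row per complex species, weights summing to 1) for Ca2+ assays.
#' @param bs_total Total biosensor concentration, µM.
#' @param r_min,r_max Unbound and maximally bound emission ratios.
#' @param binding_model `"quadratic"` (depletion; default) or
#'   `"hyperbolic"` for the calmodulin-binding forward model.
#' @param mode `"ideal_ratio"` (acceptor channel constant, ratio affine in
#'   bound fraction) or `"spectral"` (both channels affine in bound
#'   fraction, as for real emission spectra).
#' @param noise_sigma Relative standard deviation of multiplicative
#'   Gaussian measurement noise per channel (0 = noiseless).
#' @param seed Integer RNG seed; generation is a pure function of
#'   (config, seed).
#' @param schedule Data frame of additions (`added_volume` µL,
#'   `stock_conc` µM), e.g. from [titration_schedule()].
#' @param initial_volume Initial cuvette volume, µL.
#' @param max_volume Cuvette capacity, µL; schedules exceeding it error.
#' @param base_intensity Unbound acceptor intensity scale, a.u.
#' @param acceptor_bound_frac Spectral mode only: bound/unbound acceptor
#'   intensity ratio (< 1; the acceptor falls on binding).
#' @param spectrum Spectral endpoint shape parameters for
#'   [synthesize_spectrum()]: list with `peak_donor`, `peak_acceptor` (nm),
#'   `width` (nm), `grid` (nm).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(true_kd = NULL, true_hill = NULL,
                             bs_total = 0.5, r_min = 1.0, r_max = 2.0,
                             binding_model = c("quadratic", "hyperbolic"),
                             mode = c("ideal_ratio", "spectral"),
                             noise_sigma = 0, seed = NULL,
                             schedule = NULL, initial_volume = 2000,
                             max_volume = 3000, base_intensity = 1000,
                             acceptor_bound_frac = 0.7,
                             spectrum = list(peak_donor = 475,
                                             peak_acceptor = 535,
                                             width = 10,
                                             grid = 450:600)) {
  binding_model <- match.arg(binding_model)
  mode <- match.arg(mode)
  check_number(bs_total, "bs_total", positive = TRUE)
  check_number(r_min, "r_min", positive = TRUE)
  check_number(r_max, "r_max", positive = TRUE)
  if (r_max < r_min)
    fb_stop("r_max must be >= r_min", "fretbind_parameter_error")
  check_number(noise_sigma, "noise_sigma", nonneg = TRUE)
  check_number(initial_volume, "initial_volume", positive = TRUE)
  if (!is.null(schedule)) {
    if (!all(c("added_volume", "stock_conc") %in% names(schedule)))
      fb_stop("schedule needs added_volume and stock_conc columns",
              "fretbind_schedule_error")
    if (any(schedule$added_volume < 0))
      fb_stop("schedule volumes must be >= 0", "fretbind_schedule_error")
  }
  if (!is.null(true_hill)) {
    stopifnot(is.data.frame(true_hill),
              all(c("ec50", "n", "weight") %in% names(true_hill)))
    if (abs(sum(true_hill$weight) - 1) > 1e-9)
      fb_stop("species weights must sum to 1", "fretbind_parameter_error")
  }
  structure(
    list(true_kd = true_kd, true_hill = true_hill, bs_total = bs_total,
         r_min = r_min, r_max = r_max, binding_model = binding_model,
         mode = mode, noise_sigma = noise_sigma, seed = seed,
         schedule = schedule, initial_volume = initial_volume,
         max_volume = max_volume, base_intensity = base_intensity,
         acceptor_bound_frac = acceptor_bound_frac, spectrum = spectrum),
    class = "generator_config")
}

# Channel intensities (undiluted scale) for a vector of bound fractions.
channel_intensities <- function(f, config) {
  if (config$mode == "ideal_ratio") {
    f535 <- rep(config$base_intensity, length(f))
    f475 <- f535 * (config$r_min + (config$r_max - config$r_min) * f)
  } else {
    a0 <- config$base_intensity
    a1 <- a0 * config$acceptor_bound_frac
    d0 <- config$r_min * a0
    d1 <- config$r_max * a1
    f475 <- d0 + (d1 - d0) * f
    f535 <- a0 + (a1 - a0) * f
  }
  list(f475 = f475, f535 = f535)
}

apply_noise <- function(channels, sigma, seed) {
  if (sigma <= 0) return(channels)
  with_seed(seed, {
    lapply(channels, function(x) x * (1 + stats::rnorm(length(x), 0, sigma)))
  })
}

#' Simulate a calmodulin titration of a FRET biosensor
#'
#' Forward model of the binding assay: for each scheduled addition the
#' cumulative, dilution-corrected calmodulin and biosensor totals are
#' computed, the bound fraction follows the configured isotherm
#' ([predict_quadratic()] by default), channel intensities follow the
#' configured response mode scaled by the dilution factor, and seeded
#' multiplicative Gaussian noise is applied. Deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()] with `true_kd` and a `schedule` set.
#' @return A [titration_series()].
#' @export
simulate_cam_titration <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$true_kd))
    fb_stop("config$true_kd is required", "fretbind_parameter_error")
  if (is.null(config$schedule))
    fb_stop("config$schedule is required", "fretbind_schedule_error")
  sch <- rbind(data.frame(added_volume = 0, stock_conc = 0), config$schedule)
  v0 <- config$initial_volume
  w <- cumsum(sch$added_volume)
  if (max(v0 + w) > config$max_volume)
    fb_stop(sprintf("schedule exceeds cuvette capacity (%g > %g uL)",
                    max(v0 + w), config$max_volume),
            "fretbind_schedule_error")
  vol <- v0 + w
  cam_total <- cumsum(sch$added_volume * sch$stock_conc) / vol
  bs_total <- config$bs_total * v0 / vol
  f <- if (config$binding_model == "quadratic") {
    predict_quadratic(cam_total, bs_total, config$true_kd)
  } else {
    predict_hyperbolic(cam_total, config$true_kd)
  }
  ch <- channel_intensities(f, config)
  dil <- v0 / vol
  ch$f475 <- ch$f475 * dil
  ch$f535 <- ch$f535 * dil
  ch <- apply_noise(ch, config$noise_sigma, config$seed)
  titration_series(
    data.frame(step = seq_len(nrow(sch)) - 1L,
               added_volume = sch$added_volume,
               stock_conc = sch$stock_conc,
               f_donor = ch$f475, f_acceptor = ch$f535),
    initial_volume = v0, biosensor_total = config$bs_total)
}

#' Simulate a dual-channel Ca2+-sensitivity assay
#'
#' Forward model of the Ca2+ titration at saturating calmodulin: for each
#' Ca2+ addition the diluted buffer totals are computed, free Ca2+ is
#' obtained from the competitive buffer equilibrium ([solve_free_ca()]),
#' the indicator fluoresces as
#' `F = F_min + (F_max - F_min) x / (Kd_ind + x)`, the biosensor bound
#' fraction is the weight-summed Hill response of the configured species,
#' and channel intensities follow the response mode with seeded noise.
#'
#' @param config A [generator_config()] with `true_hill` and a `schedule`
#'   (of Ca2+ additions) set.
#' @param buffers List of [buffer_species()] competing for Ca2+ (chelator,
#'   calmodulin, ...). The indicator is added automatically.
#' @param indicator List with `kd` (µM, default 1.6), `total` (µM, default
#'   2), `f_min`, `f_max` (a.u. calibration endpoints).
#' @return A [ca_assay_series()] whose calibration endpoints are the
#'   indicator's asymptotic intensities.
#' @export
simulate_ca_assay <- function(config, buffers = list(),
                              indicator = list(kd = 1.6, total = 2,
                                               f_min = 100, f_max = 1100)) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$true_hill))
    fb_stop("config$true_hill is required", "fretbind_parameter_error")
  if (is.null(config$schedule))
    fb_stop("config$schedule is required", "fretbind_schedule_error")
  if (inherits(buffers, "buffer_species")) buffers <- list(buffers)
  ind_kd <- indicator$kd %||% 1.6
  ind_total <- indicator$total %||% 2
  sch <- rbind(data.frame(added_volume = 0, stock_conc = 0), config$schedule)
  v0 <- config$initial_volume
  w <- cumsum(sch$added_volume)
  if (max(v0 + w) > config$max_volume)
    fb_stop(sprintf("schedule exceeds cuvette capacity (%g > %g uL)",
                    max(v0 + w), config$max_volume),
            "fretbind_schedule_error")
  vol <- v0 + w
  dil <- v0 / vol
  ca_total <- cumsum(sch$added_volume * sch$stock_conc) / vol
  ind_buf <- buffer_species("indicator", ind_total, ind_kd)
  all_buf <- c(buffers, list(ind_buf))
  free_ca <- vapply(seq_along(ca_total), function(k) {
    dil_buf <- lapply(all_buf, function(b)
      buffer_species(b$name, b$total * dil[k], b$kd_ca, b$n_sites))
    solve_free_ca(ca_total[k], dil_buf)
  }, numeric(1))
  f_ind <- indicator$f_min + (indicator$f_max - indicator$f_min) *
    free_ca / (ind_kd + free_ca)
  th <- config$true_hill
  bound <- Reduce(`+`, lapply(seq_len(nrow(th)), function(i)
    th$weight[i] * predict_hill(free_ca, th$ec50[i], th$n[i])))
  ch <- channel_intensities(bound, config)
  ch$f475 <- ch$f475 * dil
  ch$f535 <- ch$f535 * dil
  ch$f_ind <- f_ind
  ch <- apply_noise(ch, config$noise_sigma, config$seed)
  cam_idx <- which(vapply(buffers, function(b) identical(b$name, "CaM"),
                          logical(1)))
  ca_assay_series(
    data.frame(step = seq_len(nrow(sch)) - 1L,
               added_volume = sch$added_volume,
               stock_conc = sch$stock_conc,
               f_donor = ch$f475, f_acceptor = ch$f535,
               f_indicator = ch$f_ind),
    initial_volume = v0,
    indicator_f_min = indicator$f_min, indicator_f_max = indicator$f_max,
    indicator_kd = ind_kd,
    cam_total = if (length(cam_idx)) buffers[[cam_idx[1]]]$total else NA_real_,
    biosensor_total = config$bs_total,
    chelator = paste(vapply(buffers, `[[`, character(1), "name"),
                     collapse = "+"))
}

#' Synthesize an emission spectrum for a given bound fraction
#'
#' Builds a 450–600 nm (1 nm grid) emission spectrum as the affine
#' interpolation between unbound and bound endpoint spectra, each composed
#' of two Gaussian peaks at the donor (475 nm) and acceptor (535 nm)
#' emission maxima. Peak shapes are normalized so that integrating the
#' spectrum over the 470–480 and 530–540 nm bands returns the configured
#' channel intensities, and the 475/535 peak-height ratio equals `r_min` at
#' `f = 0` and `r_max` at `f = 1`.
#'
#' @param bound_fraction Bound fraction in `[0, 1]`.
#' @param config A [generator_config()].
#' @return Data frame with columns `wavelength_nm` and `intensity_au`.
#' @export
synthesize_spectrum <- function(bound_fraction, config) {
  stopifnot(inherits(config, "generator_config"))
  if (length(bound_fraction) != 1L || !is.finite(bound_fraction) ||
      bound_fraction < 0 || bound_fraction > 1)
    fb_stop("bound_fraction must be a single value in [0, 1]",
            "fretbind_parameter_error")
  sp <- config$spectrum
  lambda <- sp$grid
  shape <- function(center) exp(-(lambda - center)^2 / (2 * sp$width^2))
  band <- function(center, lo, hi) {
    l <- lambda >= lo & lambda <= hi
    sum(exp(-(lambda[l] - center)^2 / (2 * sp$width^2)))
  }
  ch <- channel_intensities(bound_fraction, config)
  g_d <- shape(sp$peak_donor) / band(sp$peak_donor, 470, 480)
  g_a <- shape(sp$peak_acceptor) / band(sp$peak_acceptor, 530, 540)
  data.frame(wavelength_nm = lambda,
             intensity_au = ch$f475 * g_d + ch$f535 * g_a)
}
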