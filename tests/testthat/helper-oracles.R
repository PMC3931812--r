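# Independent oracles (brute-force bisection on the conservation laws) and
# shared scenario builders. The oracles deliberately avoid the closed forms
# and solvers used by the package.

# Bound fraction from single-site mass action, by bisection on free ligand:
# free + bs_total * free / (kd + free) = cam_total.
oracle_quadratic_fraction <- function(cam_total, bs_total, kd) {
  vapply(cam_total, function(ct) {
    if (ct == 0) return(0)
    lo <- 0; hi <- ct
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      g <- mid + bs_total * mid / (kd + mid) - ct
      if (g > 0) hi <- mid else lo <- mid
    }
    mid <- (lo + hi) / 2
    mid / (kd + mid)
  }, numeric(1))
}

# Free Ca2+ by fine bisection on the multi-buffer conservation equation.
oracle_free_ca <- function(ca_total, buffers) {
  nt <- vapply(buffers, function(b) b$n_sites * b$total, numeric(1))
  kd <- vapply(buffers, function(b) b$kd_ca, numeric(1))
  vapply(ca_total, function(ct) {
    if (ct == 0) return(0)
    lo <- 0; hi <- ct
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      g <- mid + sum(nt * mid / (kd + mid)) - ct
      if (g > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# Standard CaM-titration round trip: 30 log-spaced totals spanning
# 0.01x-100x the true Kd, 0.5 uM biosensor, stock at 50x the top target.
kd_roundtrip_config <- function(kd, dynamic_range = 1.61, bs_total = 0.5,
                                binding_model = "quadratic", n_points = 30,
                                noise_sigma = 0, seed = NULL,
                                mode = "ideal_ratio") {
  targets <- 10^seq(log10(0.01 * kd), log10(100 * kd), length.out = n_points)
  sch <- titration_schedule(targets, initial_volume = 2000,
                            stock_conc = 50 * max(targets))
  generator_config(true_kd = kd, bs_total = bs_total, r_min = 1,
                   r_max = dynamic_range, binding_model = binding_model,
                   mode = mode, noise_sigma = noise_sigma, seed = seed,
                   schedule = sch)
}

# Standard Ca2+-sensitivity assay: 0.5 uM biosensor, 2 uM indicator
# (Kd 1.6 uM), 250 uM Br2BAPTA, saturating CaM modelled as a 4-site Ca2+
# buffer; 32 additions staging free Ca2+ at log-spaced values 0.02-3000 uM.
ca_assay_parts <- function(true_hill, dynamic_range = 1.61,
                           cam_total = 10, noise_sigma = 0, seed = NULL) {
  buffers <- list(buffer_species("Br2BAPTA", 250, 1.6),
                  buffer_species("CaM", cam_total, 2, n_sites = 4))
  indicator <- list(kd = 1.6, total = 2, f_min = 100, f_max = 1100)
  free_targets <- 10^seq(log10(0.02), log10(3000), length.out = 32)
  totals <- total_ca_for_free(
    free_targets,
    c(buffers, list(buffer_species("indicator", indicator$total,
                                   indicator$kd))))
  sch <- titration_schedule(totals, initial_volume = 2000, stock_conc = 1e5)
  cfg <- generator_config(true_hill = true_hill, bs_total = 0.5, r_min = 1,
                          r_max = dynamic_range, noise_sigma = noise_sigma,
                          seed = seed, schedule = sch)
  list(config = cfg, buffers = buffers, indicator = indicator)
}

simulate_standard_ca_assay <- function(true_hill, ...) {
  parts <- ca_assay_parts(true_hill, ...)
  simulate_ca_assay(parts$config, buffers = parts$buffers,
                    indicator = parts$indicator)
}
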