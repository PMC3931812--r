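#!/usr/bin/env Rscript
# Generate the synthetic study data: one calmodulin titration per published
# biosensor construct (at its published Kd and dynamic range) and one
# dual-channel Ca2+ assay per complex, all at the study conditions (0.5 uM
# biosensor, 2000 uL cuvette, 250 uM Br2BAPTA + 2 uM indicator for the Ca2+
# assays). Writes titration tables under results/simulated/.

suppressPackageStartupMessages(library(fretbind))

out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20140221L

binding <- gper_binding_params()
for (i in seq_len(nrow(binding))) {
  kd <- binding$kd_um[i]
  targets <- 10^seq(log10(0.01 * kd), log10(100 * kd), length.out = 30)
  sch <- titration_schedule(targets, initial_volume = 2000,
                            stock_conc = 50 * max(targets))
  cfg <- generator_config(
    true_kd = kd, bs_total = 0.5, r_min = 1,
    r_max = binding$dynamic_range[i],
    binding_model = if (kd > 50) "hyperbolic" else "quadratic",
    noise_sigma = 0.01, seed = seed + i, schedule = sch)
  path <- file.path(out_dir, paste0(binding$construct[i], "_cam.csv"))
  write_titration_table(simulate_cam_titration(cfg), path)
  cat("wrote", path, "\n")
}

ca_tab <- gper_ca_params()
mono <- ca_tab[is.na(ca_tab$species), ]
for (i in seq_len(nrow(mono))) {
  kd <- binding$kd_um[match(mono$smd[i], binding$smd)]
  cam_sat <- saturating_concentration(kd, 0.5, model = "quadratic")
  buffers <- list(buffer_species("Br2BAPTA", 250, 1.6),
                  buffer_species("CaM", cam_sat, 2, n_sites = 4))
  indicator <- list(kd = 1.6, total = 2, f_min = 100, f_max = 1100)
  totals <- total_ca_for_free(
    10^seq(log10(0.02), log10(3000), length.out = 32),
    c(buffers, list(buffer_species("indicator", 2, 1.6))))
  sch <- titration_schedule(totals, initial_volume = 2000, stock_conc = 1e5)
  cfg <- generator_config(
    true_hill = data.frame(ec50 = mono$ec50_um[i], n = mono$hill_n[i],
                           weight = 1),
    bs_total = 0.5, r_min = 1,
    r_max = binding$dynamic_range[match(mono$smd[i], binding$smd)],
    noise_sigma = 0.01, seed = seed + 100L + i, schedule = sch)
  path <- file.path(out_dir, paste0(gsub("[ ]", "_", mono$complex[i]),
                                    "_ca.csv"))
  write_titration_table(simulate_ca_assay(cfg, buffers = buffers,
                                          indicator = indicator), path)
  cat("wrote", path, "\n")
}

# the SMD1 complex: a two-species mixture (weights 0.25/0.75) at 700 uM CaM
sp <- ca_tab[!is.na(ca_tab$species), ]
buffers <- list(buffer_species("Br2BAPTA", 250, 1.6),
                buffer_species("CaM", 700, 2, n_sites = 4))
totals <- total_ca_for_free(
  10^seq(log10(0.02), log10(3000), length.out = 32),
  c(buffers, list(buffer_species("indicator", 2, 1.6))))
sch <- titration_schedule(totals, initial_volume = 2000, stock_conc = 1e5)
cfg <- generator_config(
  true_hill = data.frame(ec50 = sp$ec50_um, n = sp$hill_n,
                         weight = c(0.25, 0.75)),
  bs_total = 0.5, r_min = 1, r_max = 1.31, noise_sigma = 0.01,
  seed = seed + 200L, schedule = sch)
path <- file.path(out_dir, "CaM-GPER_83-93_mixture_ca.csv")
write_titration_table(simulate_ca_assay(cfg, buffers = buffers,
                                        indicator = list(kd = 1.6, total = 2,
                                                         f_min = 100,
                                                         f_max = 1100)),
                      path)
cat("wrote", path, "\n")
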