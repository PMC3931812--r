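#!/usr/bin/env Rscript
# Fit apparent Kd and dynamic range for every simulated calmodulin titration
# written by 01_simulate_titrations.R, and compare the recovered values with
# the generating (published) parameters. Also reports the SMD2 fold
# difference that pins the basic patch (a.a. 170-175) as an affinity
# determinant. Writes results/affinities.csv.

suppressPackageStartupMessages(library(fretbind))

binding <- gper_binding_params()
rows <- lapply(seq_len(nrow(binding)), function(i) {
  path <- file.path("results/simulated",
                    paste0(binding$construct[i], "_cam.csv"))
  rep <- run_pipeline("fit-kd",
                      config = list(initial_volume = 2000,
                                    biosensor_total = 0.5, model = "auto"),
                      input = path, construct = binding$construct[i])
  fit <- rep$results$binding
  data.frame(construct = binding$construct[i], smd = binding$smd[i],
             kd_true = binding$kd_um[i], kd_fit = fit$kd_app,
             kd_rel_err = abs(fit$kd_app - binding$kd_um[i]) /
               binding$kd_um[i],
             dr_true = binding$dynamic_range[i], dr_fit = fit$dynamic_range,
             model = fit$model)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/affinities.csv", row.names = FALSE)
print(tab, digits = 4)

fd <- fold_difference(tab$kd_fit[tab$construct == "BSGPER_150-170"],
                      tab$kd_fit[tab$construct == "BSGPER_150-175"])
cat(sprintf(
  "\nSMD2 truncation: removing the 170-175 basic patch weakens affinity %.2f-fold (~%d-fold)\n",
  fd$fold, fd$nearest))
cat(sprintf("median |Kd error| at 1%% channel noise: %.2f%%\n",
            100 * median(tab$kd_rel_err)))
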