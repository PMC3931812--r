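# fretbind

Quantitation of calmodulin (CaM) binding from ratiometric FRET biosensor
titrations.

Biosensors built as a donor–acceptor fluorescent-protein pair flanking a
candidate CaM-binding peptide lose FRET when Ca²⁺-loaded CaM binds the
linker: donor emission (475 nm) rises, acceptor emission (535 nm) falls,
and the ratio `R = F475/F535` tracks the bound fraction. Scanning the
submembrane domains of a G protein-coupled receptor with such biosensors
locates its CaM-binding domains and quantifies them — this package
implements the full downstream analysis for anyone running (or simulating)
those spectrofluorometric assays:

- **Fractional response & dynamic range** —
  `BS_fract = (R − R_min)/(R_max − R_min)`, `DR = R_max/R_min`, with exact
  per-addition dilution correction for intensity-based readouts.
- **Apparent K_d** — least-squares fits of the response isotherm, either
  the hyperbola `f = [CaM]/(K_d + [CaM])` or the ligand-depletion
  (quadratic) mass-action form
  `f = (S − sqrt(S² − 4[BS][CaM]))/(2[BS])`, `S = K_d + [BS] + [CaM]`,
  with endpoint ratios fit jointly and automatic model selection in the
  depletion regime.
- **Free Ca²⁺ calibration** — `[Ca²⁺] = K_d_ind (F − F_min)/(F_max − F)`
  for a co-measured indicator dye (K_d 1.6 µM).
- **Ca²⁺ sensitivity** — Hill fits
  `BS_fract = [Ca²⁺]ⁿ/(EC₅₀ⁿ + [Ca²⁺]ⁿ)` of complex formation against
  free Ca²⁺, plus a segmented decomposition of biphasic curves into a
  low-Ca²⁺ species (below a 1 µM breakpoint) and the dominant global
  species, with an F-ratio decision rule.
- **A synthetic titration generator** — dilution schedules,
  chelator-buffered free Ca²⁺ (competitive multi-buffer equilibrium
  solver), indicator response, mono-/biphasic biosensor response, endpoint
  emission spectra, and seeded measurement noise, standing in for the
  spectrofluorometer in all tests.

## Worked example

Simulate a 30-point CaM titration of a 0.5 µM biosensor whose linker binds
CaM at K_d = 0.44 µM with dynamic range 1.61, then refit it:

```r
library(fretbind)

kd_true <- 0.44
targets <- 10^seq(log10(0.01 * kd_true), log10(100 * kd_true), length.out = 30)
sch <- titration_schedule(targets, initial_volume = 2000, stock_conc = 50 * max(targets))
cfg <- generator_config(true_kd = kd_true, bs_total = 0.5, r_min = 1, r_max = 1.61,
                        schedule = sch)
fit_binding(apply_dilution_correction(simulate_cam_titration(cfg)), model = "quadratic")
#> <binding_fit> Kd_app = 0.44 uM (SE 2.44e-16), DR = 1.610, model = quadratic/affine_ratio, RSS = 3.94e-31, n = 31
```

The fit recovers the generating affinity (`Kd_app`, µM) and dynamic range
exactly on noiseless data; `model = quadratic` records that the
ligand-depletion isotherm was used (at 0.5 µM biosensor, a 0.44 µM K_d is
deep in the depletion regime). Affinities of truncation variants are
compared as fold differences:

```r
fold_difference(3.41, 0.44)
#> $fold 7.75   $nearest 8
```

i.e. dropping a construct's basic C-terminal patch costs ~8-fold in
affinity. A full dual-channel Ca²⁺ assay runs end to end with
`simulate_ca_assay()` + `run_ca_assay()`, which calibrates free Ca²⁺ from
the indicator channel, normalizes the biosensor ratio, and reports Hill
fits (and a biphasic decomposition when the data support one):

```r
#> <ca_sensitivity> monophasic (breakpoint 1 uM)
#>   global / species 2:   <hill_fit> EC50 = 2.379 uM, n = 1.210, ...
```

The numbered scripts under `analysis/` run the whole study at the standard
conditions — `01_simulate_titrations.R` generates noisy titrations for
every published construct, `02_fit_affinities.R` recovers their K_d values
and dynamic ranges, `03_ca_sensitivity.R` their Ca²⁺ sensitivities, and
`04_biphasic_smd1.R` decomposes the biphasic SMD1 mixture — writing tables
under `results/`.

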