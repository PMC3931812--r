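---
title: "Quantifying calmodulin binding with ratiometric FRET biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calmodulin binding with ratiometric FRET biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretbind)
```

## The measurement

A FRET biosensor for calmodulin (CaM) binding is a fusion of a cyan donor
and a yellow acceptor fluorescent protein flanking a candidate CaM-binding
peptide. With the linker unoccupied, donor excitation (430 nm) transfers
energy to the acceptor and emission is dominated by the acceptor band
(535 nm). Ca²⁺-loaded CaM binding to the linker forces a conformational
change that disrupts the transfer: donor emission (475 nm) rises while
acceptor emission falls. The donor/acceptor emission ratio
$R = F_{475}/F_{535}$ therefore increases monotonically with the bound
fraction, and because both channels are scaled identically by dilution, $R$
needs no dilution correction.

`fretbind` analyzes two assay formats:

1. **CaM titrations at saturating Ca²⁺** — small aliquots of purified CaM
   are added to a cuvette of biosensor; the apparent dissociation constant
   $K_d$ of the linker–CaM interaction is fit from the response isotherm.
2. **Ca²⁺ titrations at saturating CaM** — Ca²⁺ is titrated into a
   chelator-buffered mix of biosensor, CaM and a red-emitting Ca²⁺
   indicator, and the Ca²⁺ sensitivity ($\mathrm{EC}_{50}$, Hill $n$) of
   complex formation is fit against free Ca²⁺ read from the indicator.

## Fractional response and dynamic range

The fractional response maps the ratio onto $[0, 1]$:

$$\mathrm{BS_{fract}} = \frac{R - R_{min}}{R_{max} - R_{min}},$$

where $R_{min}$ and $R_{max}$ are the ratios in the unbound and maximally
bound states. Single-channel alternatives exist for dilution-corrected
intensities — $(F - F_{min})/(F_{max} - F_{min})$ for the rising donor and
$(F_{max} - F)/(F_{max} - F_{min})$ for the falling acceptor — and agree
with the ratiometric form exactly when the ratio is affine in the bound
fraction. The dynamic range $DR = R_{max}/R_{min}$ proxies the size of the
conformational change and is reported alongside $K_d$.

**Endpoints are fit, not read.** The final titration point may be
sub-saturating, so treating the last observed ratio as $R_{max}$ biases
every downstream quantity. `fit_binding()` therefore fits in measured-ratio
space, $R(c) = R_{min} + (R_{max} - R_{min})\,f(c; K_d)$, with the
endpoints free parameters seeded by the observed extremes. A
pre-normalized `"fraction"` mode is available for data already expressed as
$\mathrm{BS_{fract}}$.

**Clamp policy.** Noise at the endpoints can push computed fractions
slightly outside $[0, 1]$. Excursions of at most 0.05 are clamped with a
warning (aborting a fit over endpoint noise would be worse); anything
larger is an error, because it indicates wrong endpoints rather than noise.
The indicator channel uses a 2% clamp on its low side.

## Binding isotherms and ligand depletion

With biosensor total $[BS]$ and CaM total $[CaM]$, single-site mass action
gives the bound fraction as the physical root of a quadratic:

$$f = \frac{(K_d + [BS] + [CaM]) - \sqrt{(K_d + [BS] + [CaM])^2 - 4 [BS][CaM]}}{2[BS]},$$

evaluated internally in the cancellation-free form
$f = 2[CaM]/(S + \sqrt{S^2 - 4[BS][CaM]})$. When $[BS] \ll K_d$ this
reduces to the hyperbola $f = [CaM]/(K_d + [CaM])$. At 0.5 µM biosensor the
published affinities span 0.44–136.62 µM, i.e. both regimes occur, so
`model = "auto"` fits the depletion form first and keeps it when the fitted
$K_d < 10\,[BS]$ (where the hyperbola's depletion error exceeds a few
percent), otherwise refits hyperbolically; the choice is recorded in the
result. The published tables do not state which constructs were fit with
which form — the auto rule is this package's policy. Dilution is handled
exactly: the response series carries the per-addition diluted biosensor
total, and the quadratic fit consumes it point-wise.

Two further response models address how the ratio relates to the bound
fraction. In `"affine_ratio"` (the default, matching the ideal ratiometric
readout) $R$ is affine in $f$. Real spectra have an acceptor channel that
*falls* on binding, making $R$ a ratio of two affine functions; the
`"spectral_ratio"` model fits $R = (a + b f)/(1 + d f)$ and recovers the
generator's $K_d$ exactly on such data, while the affine approximation
shows a small but finite bias — kept visible in the fit RSS rather than
silently absorbed.

## Free Ca²⁺ calibration and the Hill fit

Free Ca²⁺ is read from the single-wavelength indicator (X-Rhod-5F-like,
$K_d = 1.6$ µM, emission 600 nm):

$$[\mathrm{Ca}^{2+}]_{free} = K_d^{ind}\,\frac{F - F_{min}}{F_{max} - F},$$

with $F_{min}$ and $F_{max}$ measured under nominally Ca²⁺-free and
Ca²⁺-saturating conditions. At the half-saturation intensity this returns
exactly $K_d^{ind}$. The map diverges as $F \to F_{max}$: readings within
2% of the span below $F_{max}$ are treated as saturated and excluded from
fitting (`saturation_margin`), because measurement noise there is amplified
without bound — in practice the indicator is informative up to roughly
50× its $K_d$. Endpoints must come from calibration records; they are never
guessed from the data.

Ca²⁺ sensitivity is the Hill fit

$$\mathrm{BS_{fract}} = \frac{[\mathrm{Ca}^{2+}]^n}{\mathrm{EC}_{50}^n + [\mathrm{Ca}^{2+}]^n},$$

bounded to $n \in [0.3, 6]$ and $\mathrm{EC}_{50} \in [10^{-3}, 10^3]$ µM
and multi-started over log-spaced $\mathrm{EC}_{50}$ seeds crossed with
$n \in \{0.8, 1.5, 2.5\}$.

## Biphasic decomposition

The SMD1-type complexes form in two species with Ca²⁺ sensitivities almost
30-fold apart. The package reproduces the published segmented procedure
rather than a statistically purer mixture model: species 1 is a
free-amplitude Hill fit restricted to free Ca²⁺ ≤ 1 µM (the breakpoint,
configurable), and "species 2" is the Hill fit of the entire population,
which the abundant high-Ca²⁺ species dominates. The biphasic *call* — the
published analysis judged this visually — is formalized as: the species-1
fit converges with amplitude ≥ 0.05, its $\mathrm{EC}_{50}$ lies below the
breakpoint while the global one does not, and an F-ratio test at
$p < 0.05$ on the low-Ca²⁺ segment (null: the global curve, no local
parameters; alternative: the 3-parameter species-1 fit) shows the segment
is genuinely better described locally. Restricting the test to the segment
where the models differ matters: including the high-Ca²⁺ points dilutes
the contrast with shared misfit and costs most of the detection power. At
1% channel noise the rule detects the 0.25/0.75 two-species mixture in
about two-thirds of replicates while flagging monophasic curves in ≤ 2–4%
(the F-test's nominal level bounds the false-positive rate at 5%).

## The synthetic generator

No public datasets exist for these assays, so the generator is a
first-class module that emulates the spectrofluorometer record by record:

- **Schedules.** Additions are (volume, stock) pairs;
  `titration_schedule()` inverts conservation of mass to hit chosen
  cumulative concentrations. Defaults chosen once as study conditions:
  2000 µL initial volume, 0.5 µM biosensor, 30 log-spaced CaM totals
  spanning 0.01–100× the true $K_d$ (stock at 50× the top target keeps
  cumulative dilution below ~2%), and 32 Ca²⁺ additions staging free Ca²⁺
  at 0.02–3000 µM.
- **Binding.** The bound fraction follows the quadratic depletion isotherm
  (or the hyperbola when configured) on the *diluted* per-point totals.
- **Channels.** `ideal_ratio` mode holds the acceptor constant (1000 a.u.)
  so the ratio is affine in the bound fraction; `spectral` mode moves both
  channels affinely (acceptor falling to 0.7× its unbound intensity),
  which is what full emission spectra do. `synthesize_spectrum()` renders
  450–600 nm endpoint spectra as two 10 nm-wide Gaussian bands whose
  470–480/530–540 nm integrals reproduce the channel intensities.
- **Ca²⁺ chemistry.** Free Ca²⁺ solves the competitive buffer equilibrium
  $\mathrm{Ca}_{tot} = x + \sum_j n_j T_j x/(K_j + x)$ (bracketed root plus
  Newton polish, conservation residual < 10⁻⁹ relative). Chelator
  affinities are configuration with documented defaults — BAPTA 0.16 µM,
  Br₂BAPTA 1.6 µM at the assay's ionic conditions; the published work never
  states the values it assumed. CaM's own Ca²⁺ buffering is modelled as
  4 identical independent sites with a 2 µM per-site $K_d$ — a deliberate
  simplification of EF-hand cooperativity that only affects the mapping
  from *total* to *free* Ca²⁺, never the analysis, which always reads free
  Ca²⁺ from the indicator exactly as the assay does.
- **Noise.** Multiplicative Gaussian noise per channel, i.i.d. across
  points (photomultiplier shot noise scales with signal), seeded:
  generators are pure functions of (config, seed).
- **Mixtures.** Two-species Ca²⁺ responses are weight-summed Hill curves;
  the species-1/species-2 abundances were never quantified beyond "the
  majority", so the 0.25/0.75 default weighting is an assumption of this
  package.

What the generator does *not* emulate — photobleaching, baseline drift,
spectral cross-talk between indicator and acceptor, pipetting error in the
schedule, Ca²⁺ contamination of protein stocks — bounds what passing
round-trip tests show: they demonstrate the estimators invert the assumed
forward model at realistic designs and noise, not that real cuvette data
are free of those artifacts.

## Numerical choices

- All fits are bounded Levenberg–Marquardt (`minpack.lm`), multi-started:
  7 log-spaced $K_d$ seeds over 0.01–1000 µM (the 300-fold published
  affinity span defeats single starts), 15 seed pairs for Hill fits. The
  lowest-RSS convergent fit wins; RSS ties (< 10⁻¹²) break toward the
  smaller $K_d$/EC₅₀.
- Parameter uncertainties are 1-σ from the fit Jacobian. Published ±
  values are spreads across independent experiments, so comparisons are on
  point estimates.
- A series whose observed dynamic range is below 1.02 is declared
  non-binding (the negative-control construct responds to neither CaM nor
  Ca²⁺); $K_d$ is undefined rather than forced.
- Degenerate inputs error early with typed conditions
  (`fretbind_degenerate_endpoints`, `fretbind_saturation_error`,
  `fretbind_schedule_error`, ...), and every clamp or model-selection
  decision surfaces as a classed warning that `run_pipeline()` collects
  into the report.

## Problem sizes

The test-suite and driver-script simulations use 30-point CaM titrations,
32-point Ca²⁺ assays, and 100-seed noise ensembles — sizes at which each
fit takes milliseconds and every published parameter is recovered to well
inside its comparison tolerance, chosen as representative of real titration
records.

## Known limitations

- In `run_ca_assay()` the ratio endpoints are plugged in from the observed
  extremes; under noise the extreme-value bias (≈ 2σ of the channel noise)
  propagates into a percent-level upward bias of EC₅₀ at 1% noise. The
  $K_d$ pipeline avoids this by fitting endpoints freely; a ratio-space
  Ca²⁺ fit would too, at the cost of diverging from the published
  normalize-then-fit procedure this package reproduces.
- The global "species 2" fit is knowingly contaminated by species 1 —
  that is the published procedure. A sum-of-two-Hill-components fit would
  separate the species more cleanly and could be layered on top of
  `decompose_biphasic()`; it is deliberately not the default.
- The quadratic isotherm assumes one CaM per linker; cooperative or
  multi-site binding along the linker is out of scope.
- Linker amino-acid sequences are not bundled: constructs carry residue
  ranges only, and no sequence-based CaM-motif prediction is attempted
  (CaM-binding sequences famously share no common motif).

## Worked example

```{r example}
# Simulate the strongest-affinity construct's titration and refit it
kd_true <- 0.44
targets <- 10^seq(log10(0.01 * kd_true), log10(100 * kd_true),
                  length.out = 30)
sch <- titration_schedule(targets, initial_volume = 2000,
                          stock_conc = 50 * max(targets))
cfg <- generator_config(true_kd = kd_true, bs_total = 0.5,
                        r_min = 1, r_max = 1.61, schedule = sch)
fit <- fit_binding(apply_dilution_correction(simulate_cam_titration(cfg)),
                   model = "quadratic")
fit
```
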