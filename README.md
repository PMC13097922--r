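# slipfit

Bi-component modeling of cerebrospinal fluid (CSF) outflow from
Time-SLIP MRI signal increase ratio (SIR) curves.

## The problem

Time-Spatial Labeling Inversion Pulse (Time-SLIP) MRI tags CSF with
paired selective/non-selective inversion pulses and follows the tagged
fluid as a function of inversion time (TI). The dimensionless tracer
signal is the signal increase ratio

```
SIR(TI) = (Tag − Control) / M0
```

with M0 approximated by the control image at the longest acquired TI.
CSF clearance is not a single process: rapid bulk outflow along
meningeal and perivascular routes coexists with a slower, perfusion-like
exchange of CSF and interstitial fluid. A single Γ-variate curve cannot
represent both phases, so `slipfit` models an SIR curve as the sum of
two components:

```
SIR(TI) = f · (TI − Δt_Γ) · exp(−(TI − Δt_Γ) / T1app)                    (perfusion-like)
        + A · [exp(−((TI − Δt_G) − 2τ)² / (2τ²)) − e⁻²] · 1[Δt_G, Δt_G+4τ](TI)   (bulk flow)
```

The Γ-variate term (scale `f` in ms⁻¹, arrival `Δt_Γ`, apparent
relaxation time `T1app`) captures the slow tail; the windowed offset
Gaussian (amplitude `A`, arrival `Δt_G`, spread `τ`) captures the
compact, symmetric bolus of bulk displacement, and is exactly zero
outside its passage window `[Δt_G, Δt_G + 4τ]`. In the composite model
`T1app` is fixed at 2000 ms, the bulk bolus must arrive first
(`Δt_G < Δt_Γ`), and a built-in selection rule suppresses the Γ-variate
term (sets `f = 0`) whenever a Gaussian-only fit, computed in parallel,
is not substantially worse — so purely bulk-flow data (e.g. a flow
phantom) automatically collapse to a single-component fit.

The package provides:

* the three models as pure functions plus curve descriptors
  (time-to-peak, FWHM, peak height, area under the curve),
* bounded nonlinear least-squares fitting (multi-start
  Levenberg–Marquardt with box constraints and variable projection of
  the linear amplitudes) with the physiological parameter boxes and the
  automatic Γ-suppression rule,
* ROI-level SIR extraction from paired Tag/Control NIfTI series
  (3×3 median filter, voxelwise subtraction, M0 normalization, ROI
  averaging),
* a synthetic-data generator (noisy SIR curves and a miniature flow
  phantom image series with known ground truth) and the
  inversion-recovery / T2-preparation relaxation arithmetic used for
  validation,
* a command-line front end (`simulate | extract | fit | report`).

## Worked example

Simulate a noisy in-vivo-style curve at the 9-TI protocol
(TI = 500…3000 ms) and fit the bi-component model:

```r
library(slipfit)
sim <- simulate_curve("bicomponent", truth_defaults("invivo"),
                      ti_grid("invivo"), noise_sigma = 0.02, seed = 42)
fit <- fit_bicomponent(sim$curve)
print(fit)
#> bicomponent fit
#>   params: f=0.0003725, delta_t_gamma=750, t1_app=2000, amplitude=0.6055, delta_t_g=478, tau=309.2, gamma_suppressed=0
#>   gamma term: retained
#>   R2 = 0.9957 | SSE = 0.001519 | RMSE = 0.01299 (n = 9)
#>   TTP 1136 ms | FWHM 757 ms | PH 0.6371 | AUC 1836.4 ms
```

The ground truth behind this curve is `A = 0.60`, `Δt_G = 500 ms`,
`τ = 300 ms`, `f = 3.4·10⁻⁴ ms⁻¹`, `Δt_Γ = 700 ms`: both components are
correctly retained and the bulk-flow arrival is recovered to ~20 ms at
this noise level. `fit$selection` records the AICc and SSE comparison
behind the retain/suppress decision, `fit_results_table(fit)` flattens
everything to one CSV-ready row (PH in %, AUC in %·s), and
`plot(fit, curve = sim$curve)` draws the data with both components.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/slipfit", package = "slipfit"))')
Rscript $CLI simulate --config cfg.json --out-dir out/   # curves + truth
Rscript $CLI fit      --config fit.json --out-dir out/   # fits.csv / fits.json
```

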