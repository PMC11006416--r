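# apemu — neural-network emulation of paced ventricular action potentials

`apemu` is an R package for surrogate modelling in cardiac
electrophysiology and quantitative systems pharmacology.  Mechanistic
cardiomyocyte models map ion-channel maximum conductances to the action
potential (AP) by integrating a stiff ODE system to its pacing limit
cycle — accurate, but far too slow for workflows that need thousands to
millions of APs (population calibration, uncertainty quantification, and
especially the *inverse problem* of estimating per-channel drug effects
from recorded APs by iterative optimization).

The package provides the full workflow at desk scale:

* **Simulator** — a reduced paced ventricular cardiomyocyte model
  (Rush–Larsen/forward-Euler, compiled) with nine scalable current
  magnitudes (`gNa, gNaL, pCa, gto, gKr, gKs, gK1, gNCX, pNaK`), tuned so
  its baseline biomarkers sit inside experimental calibration ranges and
  so strong hERG block with L-type calcium enhancement produces early
  afterdepolarizations (EADs).
* **Emulator** — a two-stage neural network.  An encoder
  (4 × 256, ELU) maps normalized conductances
  `x = g/(2 g_ref) − 0.5 ∈ [−0.5, 0.5]^9` to a 256-dimensional latent
  code plus three depolarization parameters; a time-conditioned decoder
  (4 × 64, ELU/tanh; time encoded as polynomials of degree ≤ 8) realizes

      Vm(t) = f_θ(t) + (d₃/2) · tanh((d₁/2)(t − d₂)),

  a continuous function that can be evaluated (and differentiated) at any
  time resolution.
* **Training** — mean-squared-error loss
  `L = 1/(2|T|) Σ_x Σ_t (Vm(x,t) − V̂m(t))²` over random time subsets,
  optimized with Adam under batch-size and time-subset schedules.
* **Inverse fitting** — projected Adam on

      1/(2|T|) Σ_t (Vm(x, t−t₀) − V̂m(t))² + (λ/2)‖x − x_prior‖²,
      x ∈ [−0.5, 0.5]^9,

  with a jointly optimized stimulus-timing offset `t₀`; pharmacological
  scaling factors are the element-wise ratios
  `s_i = G_drug,i / G_control,i`.
* **Pharmacology** — Sobol'-sequence population-of-models calibration
  against experimental biomarker ranges, synthetic multi-target drugs,
  the pore-block model `s = 1/(1 + (C/IC50)^h)`, and success
  classification of estimates against reference distributions
  (`μ ± (0.15 + σ)`).
* **Preprocessing** — stimulus-artifact blanking, zero-phase Butterworth
  filtering, beat averaging and non-uniform resampling of noisy
  multi-beat recordings, plus a synthetic-recording generator for testing
  the pipeline end to end.

## Worked example

```r
library(apemu)

## simulate a baseline AP and check its biomarkers
ap <- simulate_ap(conductance_set())
round(compute_biomarkers(ap), 1)
#>      RMP   dVmMax     Peak    APD40    APD50    APD90 Tri90_40
#>    -88.0    313.6     46.0    214.1    251.9    309.0     94.8

## a strong hERG blocker with calcium enhancement triggers an EAD
drug <- synthetic_drug(c(gKr = 0.05, pCa = 1.20))
detect_ead(simulate_ap(apply_drug(conductance_set(), drug)))
#> [1] TRUE

## build the training corpus and train the emulator (about 15 min on 1 CPU)
ds <- build_training_set(4000, seed = 1)
ds <- train_val_split(ds, 0.2, seed = 1)
w  <- train_emulator(ds, desk_training_config(seed = 1))
min(attr(w, "log")$val_rmse, na.rm = TRUE)   # held-out mean trace RMSE, mV
#> [1] 0.976

## inverse problem: estimate conductances and drug scaling factors
ctrl <- emulate_ap(rep(0, 9), canonical_grid(), w)
fit  <- estimate_control(ctrl, w, desk_fit_config())
round(fit$x_hat, 3)                           # close to the truth x = 0
```

The biomarker row is what the baseline model prints: resting potential
−88 mV, upstroke 314 mV/ms, peak 46 mV, APD90 309 ms — all inside the
experimental calibration ranges used for population building
(`biomarker_ranges()`).

A command-line wrapper over the same functions is installed with the
package (`system.file("cli", "ap-emu.R", package = "apemu")`) with verbs
`generate`, `train`, `emulate`, `fit`, `population`, and `preprocess`.

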