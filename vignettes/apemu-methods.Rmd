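---
title: "Emulating the paced ventricular action potential: models, training, and the inverse problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating the paced ventricular action potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`apemu` couples three components:

1. a **reduced ionic simulator** of the paced human ventricular
   cardiomyocyte action potential (AP) with nine scalable current
   magnitudes,
2. a **neural-network emulator** that maps the nine conductance scale
   factors to the full transmembrane-potential time course `Vm(t)`, and
3. a **gradient-based inverse fitter** that estimates conductances — and,
   from control/drug pairs, pharmacological scaling factors — from AP
   traces.

The package is built for pharmacological workflows: the *forward problem*
(predict the drugged AP from per-channel scaling factors) and the *inverse
problem* (estimate those scaling factors from a control and a drugged AP).

# The reduced ionic simulator

## Model structure

The simulator is a Hodgkin–Huxley-style membrane model with twelve state
variables (potential, ten gating variables, intracellular calcium) and
exactly nine scalable current magnitudes: fast sodium (`gNa`), late sodium
(`gNaL`), L-type calcium (`pCa`), transient outward potassium (`gto`),
rapid (`gKr`) and slow (`gKs`) delayed rectifier potassium, inward
rectifier (`gK1`), sodium–calcium exchange (`gNCX`) and the
sodium–potassium pump (`pNaK`).  Each scale factor multiplies a fixed
baseline magnitude; 1 is baseline, 0 full block, and all package workflows
operate on factors in `[0, 2]`.

The fast-sodium, L-type calcium, rapid-rectifier and inward-rectifier
formulations follow the classical guarded-gate kinetics of early human/
mammalian ventricular models; the transient-outward, slow-rectifier, pump
and exchanger terms use standard modern formulations with fixed
intracellular ion concentrations (only calcium is dynamic, with a fast
relaxation towards its diastolic level).  This deliberately small model is
**not** a replica of any state-of-the-art human ventricular model: it is a
surrogate data generator whose qualitative pharmacology is correct — AP
prolongation under `gKr`/`gK1` block, early afterdepolarizations (EADs)
under strong `gKr` block with `pCa` enhancement — while being fast enough
to regenerate the full training corpus in minutes on one CPU.  The
simulator sits behind a narrow interface (`simulate_ap`,
`integrate_beat`, `batch_simulate`), so a full ionic model can be swapped
in without touching the rest of the stack.

## Numerics

Gating variables advance with the Rush–Larsen exponential update (the
analytic solution of each gate's linear ODE at frozen voltage); the
potential and calcium use forward Euler.  The default solver step is
0.01 ms with 0.05 ms sampling; halving the solver step changes every AP
biomarker by less than 2 %, which is the package's accuracy criterion for
step-size choices.  Voltage-dependent rate quantities are tabulated on a
0.05 mV grid and linearly interpolated, which makes a 1000 ms beat cost a
few milliseconds.

Pacing uses a 1000 ms cycle length and a 1 ms rectangular stimulus.  The
stimulus amplitude (80 µA/µF) is a model-calibration constant chosen so
that depolarization succeeds across the whole `[0.5, 1.5]^9` sampling box.
Every simulation starts from a frozen baseline limit-cycle state
(`baseline_state()`), and each new parameter set is paced for up to 200
beats with an early stop once the per-beat relative state change falls
below `1e-4`; because the model's slow variables relax quickly, most
parameter sets converge within ten beats.  Each beat's trace uses `t = 0`
at stimulus onset, on the closed interval `[0, 1000]` ms.

## Biomarkers and abnormality rules

`compute_biomarkers` returns the seven standard scalars: resting membrane
potential (RMP), maximum upstroke velocity (dVmMax), peak potential,
APD40/APD50/APD90, and triangulation (APD90 − APD40).  Definitions follow
the standard conventions: RMP is the held pre-stimulus potential, peak the
trace maximum, dVmMax the maximum time derivative (finite differences
refined by a local parabolic fit so the estimate is stable under
resampling), and APDx runs from the activation time (time of dVmMax) to
the first downward crossing of `Peak − x/100·(Peak − RMP)`, linearly
interpolated between samples.

The EAD rule is a documented surrogate for the conventional definition (a
depolarizing deflection during phase 2/3): after the AP peak plus a guard
interval, a local minimum followed by a later local maximum at least
`delta_ead = 1` mV higher, with that maximum above `v_gate = −40` mV, on a
5-point moving-average-smoothed trace.  The guard is 100 ms: the reduced
model has a pronounced spike-notch-dome morphology, and a shorter guard
misreads the physiological phase-1 dome (which peaks ~40–60 ms after the
upstroke) as an EAD.  With the 100 ms guard, none of 30 sampled
population-range APs is flagged while all ten drugs of the
`ead_drug_grid()` regime are.  All four parameters are arguments and can
be recalibrated for a different simulator.

A preparation is *abnormal* when either of its last two beats shows an EAD
or fails the repolarization criterion (potential difference between
`t = 0` and `t = 1000` ms exceeding 10 % of the trace amplitude, strict
inequality, amplitude = max − min).

# The training corpus

`build_training_set` draws Sobol' low-discrepancy samples of the nine
scale factors — by default half over `[0, 2]^9` (the
physiology/pharmacology range, where full block is plausible) and half
over `[0.5, 1.5]^9` (the experimentally calibrated range) — simulates each
to its approximate limit cycle, drops unrepolarized traces, and resamples
the survivors onto a canonical non-uniform grid: 4 kHz on `[−10, −5)` ms,
10 kHz on `[−5, 20)` ms (depolarization emphasis), 4 kHz on `[20, 1000]`
ms — 4191 points, with the pre-stimulus extension held constant at
`vm(0)`.  The Sobol' generator is the standard unscrambled Joe–Kuo
construction (30-bit, Gray-code ordering); an optional seeded digital
shift provides scrambling, but the deterministic sequence is the default
so that corpora are exactly reproducible.

The desk-scale default is 4,000 samples (2,000 per range), which the
simulator generates in roughly two minutes on one CPU; the full-scale
40,000-sample design is a parameter away (`n_total = 40000`).  Of the
4,000 default samples, typically only a handful fail the repolarization
criterion.  A random 20 % of the kept samples form the validation split.

# The emulator

## Architecture

The emulator is a two-stage network.  An encoder (four fully connected
layers of width 256, ELU activations, linear output) maps the normalized
conductances `x ∈ [−0.5, 0.5]^9` (`x = g/(2 g_ref) − 0.5`) to a
256-dimensional latent code plus three depolarization parameters.  A
decoder (four fully connected layers of width 64; ELU on the first three,
tanh on the last, then a linear map to one output) is conditioned on the
latent code and on the time point, encoded as the powers 1…8 of the
normalized time.  The emulated potential is

```
Vm(t) = f_theta(t) + (d3/2) * tanh((d1/2) * (t − d2))
```

where `f_theta` is the decoder output and the explicit tanh term handles
the sharp depolarization that a smooth polynomial-conditioned decoder
learns only slowly.  `d1` (slope, 1/ms) and `d3` (amplitude, mV) pass
through a softplus so they stay positive, matching their roles; `d2`
(offset, ms) is free.  We place the amplitude multiplicatively —
`(d3/2)·tanh(·)` — because `d3` is an amplitude; an additive constant
`d3/2` would shift, not scale, the step.

Two representation choices matter for conditioning: time is normalized
affinely from `[−10, 1000]` ms onto `[−1, 1]` (`t̃ = (t − 495)/505`) so the
degree-8 monomial basis stays well-conditioned, and the decoder works on
`Vm/100` internally (multiplied back to mV at the interface) so targets
are O(1).

Because the latent block of the decoder's first layer depends only on the
sample and the time block only on the time point, the first layer is
evaluated in factored form; the full (batch × time) input matrix is never
materialized.  The compiled evaluation path returns predictions and, on
request, gradients with respect to the weights, the conductances, and a
per-sample time shift; a pure-R reference implementation of the same
forward/backward pass is kept and cross-checked against the compiled path
(and against central differences) in the test suite.

## Training

Training minimizes the mean-squared-error loss
`L = 1/(2|T|) Σ_samples Σ_t (Vm(x,t) − V̂m(t))²` with Adam, where each step
uses a random time subset `T` drawn uniformly without replacement from the
canonical grid.  Time subsampling is unbiased for the gradient (checked
empirically in the tests) and is the main cost lever: a 1/16 subset gives
a 16-fold cheaper step with modest extra gradient noise.

The reference (full-scale) configuration follows the growing batch
(1250 → 1800) and growing time-subset (|T|/16 → |T|) schedules over 5000
epochs.  The desk-scale preset (`desk_training_config()`) is sized for a
single CPU: batch 64, a constant 1/32 time subset, a geometrically
decaying step size (3e-3 → 2e-4) over 320 epochs (~16,000 Adam steps),
and single-precision arithmetic in the fused compiled loop (master
weights and Adam state stay double).  Many cheap, noisy steps beat fewer
expensive ones decisively here: at equal wall time, halving the time
subset and doubling the step count roughly halved the held-out error.
This trains the 4,000-sample corpus to a held-out mean trace RMSE around
1 mV in 12-13 minutes on one CPU.  Validation RMSE is computed every few
epochs and the best-validation checkpoint is returned.  One optimization
quirk is worth knowing: the 2 ms depolarization spike occupies a
~0.016-wide sliver of the normalized time axis, and carving it through
the degree-8 polynomial basis has a long plateau — training error on the
spike breaks through only late in the schedule, which is why tiny-corpus
memorization converges more slowly than held-out accuracy on the full
corpus.  Both schedule
shapes (linear in epoch; geometric for the step size) are package choices:
the endpoints, not the interpolation, are what the reference recipe
specifies.

# The inverse problem

`fit_ap` minimizes

```
1/(2|T|) Σ_t (Vm(x, t − t0) − V̂m(t))²  +  (λ/2) ||x − x_prior||²
```

subject to `x ∈ [−0.5, 0.5]^9`, with Adam and projection onto the box
after every step.  The temporal offset `t0` absorbs stimulus-timing
mismatch; it is optimized jointly but with its own smaller step size
(0.02 versus 0.01), since it lives on a different scale (ms) than the
normalized conductances.  The prior weight defaults to `λ = 10`.  Because
multiple conductance sets produce nearly identical APs (notably `gKs` is
almost non-identifiable from a single paced AP), the prior keeps
non-identifiable coordinates at their initialization instead of letting
them wander.

Control APs are fitted with `x_init = x_prior = 0` (the reference
conductances); drugged APs with `x_init = x_prior = x_control`.  Scaling
factors are the element-wise ratios of the denormalized drugged and
control estimates, `s_i = G_drug,i / G_control,i`, defined only where the
control conductance is positive.  Errors propagate through this chain, so
control estimates are typically more accurate than drug estimates, which
are more accurate than the derived scaling factors.

Convergence is by fixed iteration count.  Shifted evaluation times falling
outside the trained domain `[−10, 1000]` ms are clamped to the boundary
with a warning.  Multiple targets sharing one time grid are fitted jointly
as independent problems in one batch, which is how the package-level
experiments keep 50–100 fits inside a few minutes.

# Pharmacology

`build_population` reproduces the population-of-models calibration: walk
the Sobol' sequence over `[0.5, 1.5]^9` in order and accept members whose
last two beats are abnormality-free and whose biomarkers fall inside the
experimental ranges (RMP −95…−80 mV, dVmMax 100…1000 mV/ms, peak 10…55 mV,
APD40 85…320 ms, APD50 110…350 ms, APD90 180…440 ms, Tri90−40 50…150 ms).
First-n-accepted in sequence order makes the population reproducible
without a separate selection rule.  With the reduced model the acceptance
rate is around 0.2, dominated by APD90 and triangulation.

Synthetic drugs are per-target scaling factors (`s < 1` block, `s > 1`
enhancement).  `random_drug` draws the four-target uniform `[0.5, 1.5]`
design; `ead_drug_grid()` is the fixed ten-drug hERG-block/Cav1.2-
enhancement grid (gKr 0.05…0.14 step 0.01, pCa 1.20…1.38 step 0.02) used
to probe EAD behaviour.  `pore_block` converts concentration-response
parameters to a scaling factor via `s = 1/(1 + (C/IC50)^h)`.

Estimated scaling factors are classified against reference distributions
(samples per drug-target, e.g. from pore-block transforms of sampled
IC50/Hill pairs) as successful when they fall in the closed interval
`μ ± (0.15 + σ)`; the 0.15 margin is a fixed constant of the rule,
configurable.  The package ships no third-party reference samples; a
synthetic fixture generator (log-normal IC50 samples) stands in for
testing and is labelled as such.

# Preprocessing of raw recordings

Experimental-style recordings (ten consecutive beats, stimulus artifact,
noise) are processed as: blank the artifact window `[0, 1.75]` ms with the
end-of-beat resting value; resample to 100 kHz and low-pass filter
(second-order Butterworth, 2.5 kHz cutoff); average across beats; resample
the average at 100 kHz on `[0, 15)` ms and 1 kHz on `[15, 1000]` ms.  Two
filtering choices are deliberate: the filter runs zero-phase
(forward–backward), so no group delay leaks into the depolarization time
that the inverse fitter would absorb into `t0`; and the signal is
baseline-anchored and reflection-padded before filtering to suppress the
zero-state edge transient.  The QC report flags across-beat standard
deviations above 7 mV before the peak or 2 mV after it.  Beats are
aligned by stimulus time, not by upstroke.

`synthesize_recording` generates raw recordings from the simulator
(artifact spike, Gaussian noise, alignment jitter) so the whole pipeline
is testable without experimental data; with 1 mV noise the pipeline
recovers the clean AP to well under 1 mV RMSE.

# What the synthetic data do and do not show

The generator emulates the *structure* of the real workflow: paced
steady-state APs, conductance-driven variability, drug action as
conductance scaling, EADs under repolarization-reserve loss, and noisy
multi-beat recordings.  It does not emulate: channel-kinetics variability
(only magnitudes vary), tissue-level electrotonic effects (experimental
APs from small tissue preparations differ systematically from single-cell
APs — the main source of inaccuracy in real inverse problems),
state/voltage-dependent drug binding, temporally correlated noise, or
non-1000 ms pacing.  Passing tests therefore demonstrate the correctness
and internal consistency of the machinery at desk scale, not
production-level accuracy on experimental recordings.

# Problem sizes and numerical choices

The shipped experiments use: a 4,000-sample corpus (~2 min to generate),
~5,000 Adam training steps (~10 min), 50-target batched inverse studies
(~2–4 min), and populations of up to 100 members.  Degenerate inputs are
handled explicitly: non-finite model states abort integration with the
offending time; traces that never repolarize raise a missing-APD error
distinct from the no-upstroke error; zero control conductances make the
scaling-factor ratio an error naming the coordinate, rather than an Inf.
Ties in the biomarker crossing search resolve to the first crossing after
the peak.  All stochastic components (splits, time subsets, drug draws,
noise, scrambling) are seed-controlled, and training/fitting runs are
bit-reproducible for a fixed seed and thread policy.

# Known limitations

* The reduced simulator's EAD threshold region is sharper than that of
  detailed human models; EAD confusion statistics quantify agreement
  between the emulator and *this* simulator's labels, not any external
  standard.
* Only five coordinates are practically identifiable from a single paced
  AP: `gNa`, `pCa`, `gto`, `gKr`, `gK1` — the currents that individually
  shape the upstroke, plateau, notch and repolarization.  `gNaL` and
  `gKs` have tiny AP signatures at this cycle length, while `gNCX` and
  `pNaK` are sensitive but nearly collinear with each other (both shift
  late repolarization), as the orthogonalized sensitivity of the emulated
  AP shows.  Recovered values of the weakly identifiable four mostly
  reflect the prior, and inverse accuracy is reported per coordinate for
  that reason.
* The emulator is trained for one pacing protocol (1000 ms cycle length)
  and one beat; alternans and rate dependence are out of scope.
* Weights serialize to JSON text; at ~230k parameters this favours
  portability and diffability over compactness.
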