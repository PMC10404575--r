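---
title: "A hierarchical competition model of tactile perceptual rivalry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical competition model of tactile perceptual rivalry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactrivalry)
```

## The phenomenon and the model

Antiphase trains of high- and low-intensity vibrotactile pulses delivered to
the two index fingers evoke a bistable percept: either one simultaneous
vibration on both hands (SIM) or a vibration that appears to jump between
hands (AM). For a fixed intensity difference ΔI (dB) between the high and the
low pulses, perception alternates between these two interpretations every few
seconds.

`tactrivalry` implements a two-stage firing-rate model of this phenomenon.

**Stage 1 — alternation generator.** Two adapting recurrent units ν_R, ν_L
(one per hemisphere) with logistic activation
N(x) = 1/(1+e^{−(x−x₀)}), recurrent excitation w, activity-driven adaptation
α with sigmoid A(ν) = 1/(1+e^{−k_A(ν−ν₀)}) and timescales τ_ν = 0.9 s,
τ_α = 4.5–5 s. Driven by an input of strength D = f(ΔI) plus a shared
Ornstein–Uhlenbeck noise ζ(t), the population hops between a quiescent DOWN
state and an active UP state. Between the two folds of the noise-free unit
(D ∈ [1.58, 2.42] for the reference constants) DOWN and UP coexist; the
adaptation sweep g·α ∈ [0, 1.5] and the noise carry the system across the
folds, producing irregular alternations.

**Stage 2 — percept encoder.** Two fast units u_R, u_L (τ = 1 ms) receive the
pulse trains with strength c, excite each other quickly (a) and inhibit each
other through a delayed, slowly decaying pathway (strength b, decay
τ_i = 0.25 s) realised as a Rubin–Terman-style indirect synapse: a fast gate
y_j charges at rate α_x while u_j is above threshold and decays at β_x; the
inhibition x_j relaxes toward a steep sigmoid of (y_j − θ_s). The gate's
onset delay has the closed form −ln(1−θ_s(α_x+β_x)/α_x)/(α_x+β_x) = 5.08 ms,
consistent with the nominal 5 ms delay. Both stage-2 units are inhibited by
the total first-stage activity with strength d. When the first stage is DOWN,
both units respond to high **and** low pulses (SIM); when it is UP, the extra
inhibition lets each unit respond only to its own high pulses (AM).

The percept therefore follows the first-stage state, and the dominance
durations inherit its switching statistics.

## Reconstruction choices

The auxiliary equations (adaptation, delayed inhibition) and several input
conventions are not fully determined by the published main text; the package
makes the following choices, each exposed as an option so the verbatim
printed forms remain available.

**First-stage drive (`drive_mode`, `drive_offset`).** The printed stage-1
stimulus term, f(ΔI)(i_L−i_R)/ΔI for the right unit, is an antiphase square
wave of amplitude f(ΔI) with zero cycle average. A zero-mean drive cannot
sustain the UP state: the UP branch of ν = N(wν − x₀ + D) exists only for
D ≥ 1.58, while all fitted f values exceed 2.16 — and indeed simulations with
the zero-mean drive never leave the DOWN/SIM state, for any noise reading or
cross-unit pooling we tried. The same source states that, by symmetry, the
two stage-1 units reduce to one adapting recurrent unit with **constant**
input D = f(ΔI); that reduction is exact only if the drive's cycle-symmetric
component equals f(ΔI). The package default (`drive_mode = "collapsed"`)
therefore gives each stage-1 unit the constant drive D = f(ΔI). The
antiphase component can be added back (`drive_mode = "ideal"`,
`"sigmoid_printed"`, `"sigmoid_centered"`, with `drive_offset` scaling the
symmetric component; `drive_offset = 0` with `"ideal"` is the verbatim
printed form). Numerically, antiphase amplitudes ≳1 flatten the
forcing-averaged ν-nullcline, destroy the fold structure and freeze the
alternation at a stable midpoint — which is why the collapsed form is the
default for all statistics.

**Adaptation pooling (`adapt_pool`).** By default adaptation tracks the
population-mean rate A((ν_R+ν_L)/2), which collapses exactly to the one-unit
model's A(ν) under symmetry. Per-unit adaptation (`adapt_pool = FALSE`) is
the more literal reading but, under pulsatile drive, the within-cycle swings
pin the adaptation signal near A ≈ 1/2 and stall the relaxation oscillation.

**Second-stage inputs (`input_smoothing`).** ΔI in dB is substituted
literally, so the low-pulse level 1−ΔI is −1 at ΔI = 2. With raw levels the
low-pulse input c(1−ΔI) = −5.5 overwhelms the maximal cross excitation
a = 3.4 and SIM becomes impossible for ΔI ≳ 1.3; with the printed smoothing
1/(1+e^{−k i}) the gap level becomes c/2 = 2.75 and the units latch
permanently. The default is the centered sigmoid 1/(1+e^{−k(i−1/2)}), which
maps gaps and negative lows to ≈0 and the high level to ≈1; it is the only
dialect under which both SIM and AM attractors exist across the experimental
ΔI grid.

**Simplified-model inhibition (`nu_weight`).** The exact symmetric collapse
of −d(ν_R+ν_L) is −2dν, the package default. The printed one-unit form
(−dν, `nu_weight = 1`) caps downstream inhibition at 2.6, below the ≈3
needed to suppress the partner's low-pulse response at ΔI = 0.5, and no AM
state would exist there.

**Noise convention (`rate_convention`).** The noise equation as printed,
dζ = −τ_n ζ dt + σ√(2 τ_n dt) W_t, uses τ_n as a decay **rate**: for
τ_n = 0.05 the correlation time is 20 s. Read instead as a correlation time
(0.05 s), the σ = 0.3 noise averages to ≈0.07 SD inside τ_ν and the model
never switches; we therefore keep the printed rate convention as the default
(`rate_convention = FALSE` selects the correlation-time reading). For the
simplified-model demonstration profile (τ_n = 0.98) the two readings
coincide. Either way the stationary SD is σ.

**Percept read-out.** The classifier labels each 2·TR stimulus cycle: a side
"responds" to a pulse window when u ≥ `u_resp` (0.5) for at least
`resp_frac` (0.5) of the window; SIM requires both sides to respond in their
low-intensity windows, AM neither; mixed cycles inherit the previous label
and an undetermined first cycle is SIM (the zero-init percept). The
sustained-fraction rule avoids counting the ~20–30 ms onset transient of the
suppressed unit (before the ≈5 ms-delayed inhibition engages and x rises) as
a full response. First and last phases are censored and excluded from
statistics. Durations are therefore quantized at 2·TR = 1.6 s.

## Parameters and profiles

`model_profile()` packages three configurations: `table1` (the reference
constants; σ = 1, τ_α = 4.5 s), `fig5fit` (the optimisation-stage set used
for the duration statistics and the input-strength curve: τ_α = 5 s,
σ = 0.3, τ_n = 0.05) and `fig3_simplified` (noise-driven demonstration of
the simplified model: g = 0, σ = 0.79, τ_n = 0.98). The input nonlinearity
f(ΔI) = f₀ + f₁/(1+e^{−r(ΔI−ΔI₀)}) defaults to the published fit
(2.12, 1.80, 1.57, 2.64) with the five calibration points
(0.5, 2.16) … (6, 3.92) shipped in `inst/extdata/f_points.csv`; table lookups
never interpolate.

## Numerical choices

Integration is explicit Euler–Maruyama (compiled), default dt = 0.01 ms; all
rate-like updates are convex combinations for dt ≤ τ, so [0,1] is exactly
forward-invariant. Statistics runs use dt = 0.05 ms, still 20× below the
fastest timescale; halving dt leaves slow variables within 10⁻³ pointwise,
while the 1 ms threshold units shift their crossing instants by O(dt) and are
checked in L1. Storage is strided (1 ms default). The first 2 s of every run
are excluded as transient from the all-zero initial state. Noise is
piecewise-constant over each step and generated inside the stepper from R's
RNG, so a seed fixes the whole trajectory.

## What the simulations show — and what they do not

With the reconstruction above, the model at ΔI = 2 dB (profile `fig5fit`)
alternates with seconds-scale dominance durations, a coefficient of variation
of the mean-normalized pooled durations near 0.77, and clean generalized
input-strength behaviour over ΔI ∈ {0.5, 1, 2}: mean SIM dominance falls
(≈126 → 55 → 20 s), mean AM dominance rises (≈7 → 16 → 21 s), with
equidominance near ΔI = 2. Known deviations from the published results,
measured rather than tuned away:

* the duration distribution is right-heavier than reported (γ₁/cv ≈ 3.5–4
  vs 2.17), and on large pooled samples the one-sample KS test can reject
  the fitted log-normal as well as the gamma — slow (20 s) noise parks the
  system and stretches occasional phases, and the cycle quantization adds
  ties;
* at ΔI ∈ {4, 6} the fitted drives (3.75, 3.92) place the UP state so far
  from the lower fold that adaptation alone cannot destabilize it and
  σ = 0.3 noise does so too rarely to observe; those conditions report NaN
  means rather than silently dropping;
* the noise-free simplified model's bistable band over constant drive D is
  the single contiguous interval D ∈ [≈1.6, ≈2.4]; D = 1.25 lies below it
  and is SIM-only — the published noise-driven switching there (σ = 0.79)
  is metastable switching, not fold-bounded bistability.

The synthetic stimulus generator emulates ideal antiphase square-wave pulse
trains (400 ms pulses, 800 ms repetition) with an exactly shared noise
process. It does not emulate receptor adaptation, skin-site variability,
response/report latency, or the build-up of the first percept, so passing
tests constrain the model dynamics, not those aspects of real tactile data.

## Problem sizes used by the test suite

Unit tests run sub-minute simulations. The statistics checks pool five
1800-s runs at ΔI = 2 (≈400 uncensored phases); the input-strength check
uses four 1200-s repetitions per ΔI; the regime scan covers D ∈ [0.5, 2.5]
in steps of 0.1 with 40-s settling runs. These sizes were chosen so that
each quantity's sampling error is small against its acceptance band.

## A worked example

```{r, eval = FALSE}
library(tactrivalry)
prof <- model_profile("fig5fit")
traj <- simulate_model("full", stimulus_params(2), prof,
                       t_max = 300, dt = 5e-5, seed = 42)
seqp <- percept_durations(traj)
duration_stats(seqp)
```

## Limitations

The adaptation and delayed-inhibition equations are reconstructions
constrained by the published constants and described behaviour, isolated
behind `first_stage_params()` / `second_stage_params()` so they can be
swapped if the original auxiliary equations become available. Build-up
dynamics and the dependence of dominance on pulse timing (TD, TR) are out of
scope. The evolutionary fitter ships with deliberately small defaults; real
refits should raise `reps`, `t_max` and `budget` substantially.
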