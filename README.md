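# tactrivalry

Simulation and analysis of **tactile perceptual rivalry**: antiphase trains
of high- and low-intensity vibrotactile pulses on the two hands are perceived
either as one simultaneous vibration (SIM) or as a vibration jumping between
hands (apparent movement, AM), and perception alternates between the two
every few seconds. The package implements a hierarchical two-stage
firing-rate competition model of this phenomenon for computational
neuroscientists studying perceptual bistability.

**Stage 1** is a pair of adapting recurrent units (rates ν_R, ν_L) with
logistic activation N(x) = 1/(1+e^{−(x−x₀)}), recurrent excitation w,
adaptation α with slow timescale τ_α, driven by D = f(ΔI) — an offset-scaled
sigmoid of the intensity difference ΔI (dB) — plus shared
Ornstein–Uhlenbeck noise ζ(t). It alternates stochastically between DOWN and
UP population states. **Stage 2** is a pair of fast percept units (u_R, u_L)
with mutual fast excitation a, delayed slowly decaying inhibition b
(an indirect synapse with ~5 ms onset delay and τ_i = 0.25 s decay), stimulus
drive c·i, and inhibition d·(ν_R+ν_L) from stage 1:

    τ_ν ν̇_j = −ν_j + N(w ν_j − g α_j + D + ε_j(t) + ζ)
    τ_α α̇_j = −α_j + A((ν_R+ν_L)/2)
    τ  u̇_j  = −u_j + S(a u_ȷ − b x_ȷ − d(ν_R+ν_L) + c i_j − θ)
    ẏ_j     = α_x (1−y_j) S(u_j−θ) − β_x y_j
    τ_i ẋ_j = −x_j + S(y_j − θ_s)

with S a steep sigmoid (k = 20) replacing the Heaviside gain and ε_j(t) the
optional antiphase pulse component. DOWN states encode SIM, UP states AM, so
dominance durations inherit the first stage's switching statistics.
Everything is integrated with a compiled Euler–Maruyama stepper
(dt = 0.01–0.05 ms).

## Worked example

```r
library(tactrivalry)

prof <- model_profile("fig5fit")        # sigma = 0.3, tau_n = 0.05, tau_a = 5 s
traj <- simulate_model("full", stimulus_params(2), prof,
                       t_max = 300, dt = 5e-5, seed = 42)
seqp <- percept_durations(traj)
duration_stats(seqp)
#> dominance-duration statistics (n = 12 uncensored phases)
#>   mean SIM 17.33 s | mean AM 26.40 s
#>   cv 0.600 | gamma1 0.621 | gamma1/cv 1.034
#>   KS p: lognormal NA, gamma NA
#>   lag 1: r = -0.216 (p = 0.524)
#>   lag 2: r = -0.664 (p = 0.0364)
```

The report gives the mean dominance duration per percept, the coefficient of
variation and skewness ratio of the mean-normalized pooled durations
(scale-free shape descriptors of the duration distribution), one-sample
Kolmogorov–Smirnov p-values against fitted log-normal and gamma families
(`NA` below 20 phases), and Pearson correlations between successive dominance
durations. Longer runs (≥1500 s) and several seeds are needed for stable
shape statistics.

Other entry points:

```r
fit_sigmoid(f_points())                     # least-squares fit of f(dI); ~(2.12, 1.80, 1.57, 2.64)
levelt_curve(c(0.5, 1, 2), reps = 4)        # mean dominance vs intensity difference
bistability_scan(seq(0.5, 2.5, 0.1))        # SIM/AM/bistable regimes over drive D
run_config("config.yaml", out_dir = "out")  # declarative pipeline
```

A thin command-line front end with the same operations ships at
`inst/cli/tactrivalry.R` (subcommands `simulate`, `percepts`, `stats`,
`sweep levelt|bistability`, `fit sigmoid|model`, `run`).

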