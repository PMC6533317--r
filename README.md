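# mindchange

Simulation and analysis of a distributed neural circuit model of decision
uncertainty and change-of-mind in two-choice reaction-time tasks.

Perceptual decisions come with a sense of confidence, and its complement —
decision uncertainty — sometimes drives us to reverse a choice mid-movement.
`mindchange` implements a three-module attractor circuit in which that link
is mechanistic rather than descriptive: a winner-take-all sensorimotor
network (the reduced two-variable mean-field model with NMDA-gating
variables S₁, S₂), an uncertainty-monitoring microcircuit whose
uncertainty-encoding population y_U is released from top-down inhibition
mid-trial, integrates while the decision is still contested, and feeds its
activity back *equally* to both sensorimotor populations (gain J_mc0), and
a pair of mutually inhibitory motor integrators whose difference maps onto
a screen position x = q(y_L − y_R). The feedback transiently replaces the
two choice attractors with a single choice-neutral stable state; noise can
then carry the trajectory across the diagonal, and the motor read-out
reverses sign — a change-of-mind. The same y_U signal yields per-trial
uncertainty read-outs (peak, and trapezoidal area as a post-hoc proxy), a
coupled-trial sequential effect (the first trial's uncertainty area raises
the tonic bias of the second), and the behavioural statistics: Weibull
psychometric fits p = 1 − 0.5·exp(−(ε/α)^β), chronometric curves,
change-of-mind probability curves, and the RT–uncertainty regression.

The package is aimed at computational/cognitive neuroscientists who want a
tested, scriptable re-implementation of this model family: every circuit
constant is configurable, trials are integrated with Euler–Maruyama at
0.5 ms with fully reproducible per-trial RNG streams, and the 2-D
sensorimotor subsystem comes with numerical phase-plane tools (nullclines,
fixed points with stability, bifurcation scan over the feedback current).

## Worked example

```r
library(mindchange)

ts <- run_block(400, params = model_parameters(), master_seed = 2024)
ts
#> <trial_set> 2400 trials; epsilon grid: 0, 3.2, 6.4, 12.8, 25.6, 51.2
#>   indecision 2.0%; change-of-mind 3.1%

psychometric_fit(ts)
#> <psychometric_fit> p = 1 - 0.5 exp(-(eps/alpha)^beta); alpha = 6.629%,
#>   beta = 1.072 (binomial ML)

reg <- rt_uncertainty_regression(ts)
reg$trial$pearson_r        # 0.843  slower trials carry more uncertainty
reg$condition$r_squared    # 1.000  six condition means are collinear

com_probability_curve(ts)[, 1:5]
#>   epsilon   n  p_any p_to_correct p_to_error
#> 1     0.0 378 0.0556       0.0317     0.0238
#> 2     3.2 388 0.0567       0.0335     0.0232
#> 3     6.4 386 0.0311       0.0285     0.0026
#> 4    12.8 399 0.0476       0.0476     0.0000
#> 5    25.6 400 0.0025       0.0025     0.0000
#> 6    51.2 400 0.0000       0.0000     0.0000
```

At 400 trials per level the fit is still noisy; at a few thousand trials
per level the defaults give α ≈ 7.3%, β ≈ 1.3, an indecision rate of
≈ 2.2% and a trial-level RT–uncertainty correlation of ≈ 0.85. A single
change-of-mind trial, with its full trace, looks like this:

```r
rec <- run_trial(trial_config(epsilon = 3.2, correct_side = 2, seed = 17),
                 model_parameters())
rec
#> <trial_record> epsilon = 3.2 ; correct side = 2
#>   rt = 831.5 ms ; initial -> 1 ; final -> 2
#>   change-of-mind: TRUE (error-to-correct)
#>   uncertainty: peak = 3.434, area = 1903.5 Hz*ms
plot(rec$time, rec$x, type = "l")   # motor position reverses sign
```

The initial movement heads toward choice 1 (the error side), the
uncertainty feedback reconfigures the phase plane, and the final target
reached is choice 2 — the correct side. The dynamical-systems view of the
same mechanism:

```r
p <- model_parameters()
find_fixed_points(0, I_fb = 0, p)      # 2 choice attractors + saddle
find_fixed_points(0, I_fb = 0.03, p)   # 1 choice-neutral attractor
critical_feedback_current(p)
#> 0.0186   (nA; the saddle-node where the choice attractors vanish)
plot_phase_plane(0, 0.02, p)
```

A thin command-line interface over the same functions is installed at
`system.file("cli", "mindchange.R", package = "mindchange")`, with
`simulate`, `analyze`, `coupled`, `phaseplane` and `fixtures`
subcommands.

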