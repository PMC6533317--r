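---
title: "Modelling decision uncertainty and change-of-mind with mindchange"
author: "mindchange authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decision uncertainty and change-of-mind with mindchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindchange)
```

## The model

`mindchange` simulates a distributed neural circuit for two-choice
reaction-time decisions in which decision uncertainty is computed *during*
the decision and fed back into it, occasionally reversing the outcome — a
change-of-mind. The circuit has three modules.

**Sensorimotor module.** Two competing excitatory populations, selective
for the two choice options, are described by the reduced two-variable
mean-field model of winner-take-all decision circuits: each population is
summarised by its slow NMDA-mediated synaptic gating variable
$S_i \in [0, 1]$,

$$\dot S_i = -\frac{S_i}{\tau_s} + (1 - S_i)\,\gamma\,H(x_i), \qquad
H(x) = \frac{a x - b}{1 - e^{-d(a x - b)}},$$

with total current
$x_i = J_{N,ii} S_i - J_{N,ij} S_j + I_0 + I_i + J_{mc0}\, y_U + I_{noise,i}$
and stimulus input $I_i = J_{A,ext}\,\mu_0 (1 \pm \varepsilon/100)$.
The evidence quality $\varepsilon$ plays the role of motion coherence in a
random-dot stimulus; the population selective for the correct side receives
the $+$ sign. All sensorimotor constants are the published values of the
reduced model this module is taken from ($a = 270$ Hz/nA, $b = 108$ Hz,
$d = 0.154$ s, $\gamma = 0.641$, $\tau_s = 100$ ms, $J_{N,ii} = 0.2609$ nA,
$J_{N,ij} = 0.0497$ nA, $I_0 = 0.3255$ nA, $J_{A,ext} = 5.2\times10^{-4}$
nA Hz$^{-1}$, $\mu_0 = 30$ Hz). The singularity of $H$ at $a x = b$ is
removable and evaluated by its limit $1/d$ (series expansion within
$|d(ax-b)| < 10^{-4}$).

**Uncertainty-monitoring module.** A cortical-column-like microcircuit of
two threshold-linear populations. An inhibitory population integrates the
summed sensorimotor rates; an uncertainty-encoding population receives a
tonic excitatory bias $\mu$ and is inhibited by the first:

$$\tau_{mc}\,\dot y_{inh} = [J_{V,inh}(H_1 + H_2) - g]_+ - y_{inh}, \qquad
\tau_{mc}\,\dot y_U = [\mu - J_{N,inh}\, y_{inh} - g]_+ - y_U,$$

with $[\cdot]_+ = \max(0, \cdot)$ applied to the full bracketed drive.
While the populations compete (summed rate low), $y_U$ is released from
inhibition and integrates upward; once a clear winner emerges the
inhibitory population shuts the drive down. The peak of this phasic bump
is therefore larger the longer the competition lasts — it *is* the
circuit's uncertainty read-out. $y_U$ is fed back equally to both
sensorimotor populations through $J_{mc0}$.

**Motor module.** Two mutually inhibitory threshold-linear integrators
driven by the sensorimotor rates,

$$\tau_h\,\dot y_{L} = [J H_1 - J_{N,LR}\, y_R - g]_+ - y_L, \qquad
\tau_h\,\dot y_{R} = [J H_2 - J_{N,RL}\, y_L - g]_+ - y_R,$$

mapped to a screen position $x = q\,(y_L - y_R)$ with
$q = |T_{pos}|/M_{th}$, $T_{pos} = 750$ screen units and $M_{th} = 17.4$
Hz, so the position reaches a choice target exactly when the leading motor
rate reaches $M_{th}$ with the other silent. The package's sign convention
maps choice 1 (Left) to positive positions; the read-out is antisymmetric,
so all statistics are invariant to this choice.

## The trial event schedule

A trial proceeds as follows (times in ms, defaults in parentheses):

1. From trial start, a large top-down inhibition $g$ (1000 nA) clamps the
   uncertainty and motor modules; both gating variables start at a
   spontaneous value $S_i = 0.1$.
2. The stimulus switches on at `t_stimulus_onset` (900) and stays on.
3. $g$ is removed from the inhibitory population 400 ms after stimulus
   onset and from the uncertainty-encoding population 500 ms after.
4. When either sensorimotor rate first reaches the decision threshold
   (35.5 Hz) the response time and initial choice are recorded, $g$ is
   reinstated at 3000 nA on the uncertainty module, and the motor module
   is released. Nothing is reset: the network keeps evolving.
5. Integration continues until a motor rate reaches $M_{th}$ (final
   choice, target reached) or until 4000 ms after stimulus onset
   (indecision).

A *change-of-mind* is a reversal of the order of dominance of the motor
populations after movement initiation: the final choice differs from the
initial movement direction (the first non-zero sign of $x$ after the motor
release), provided a choice target is eventually reached. We use this net
reversal rather than "any sign change of $x$" so that every change-of-mind
trial is unambiguously either error-to-correct or correct-to-error and the
two directional curves partition the total exactly; trials that wobble
across zero and return to their initial side are not counted.

A key structural feature: with the published sensorimotor constants the
winner's firing rate at the choice attractor (about 30 Hz with the
stimulus on) lies *below* the 35.5 Hz decision threshold. Crossing the
threshold therefore requires the transient excitatory boost from the
uncertainty feedback (or an unusually large noise excursion). Decisions
are thereby paced by the uncertainty bump itself, which is what couples
response time so tightly to the uncertainty read-out and what makes both
indecisions (bump insufficient before the timeout) and changes-of-mind
(feedback transiently erasing the choice attractors) possible.

## Noise model

The integration scheme is forward Euler–Maruyama with `dt = 0.5` ms
(smaller steps change no conclusion; the test suite verifies 0.1 ms).
Noise enters as independent Ornstein–Uhlenbeck currents
added to each sensorimotor population's input:
$I \leftarrow I(1 - dt/\tau_{noise}) + \sigma\sqrt{dt/\tau_{noise}}\,\xi$,
$\xi \sim \mathcal N(0,1)$, giving a stationary standard deviation of
$\sigma/\sqrt 2$. The defaults are $\sigma = 0.0125$ nA and
$\tau_{noise} = 12$ ms.

These two values were chosen as part of the package's one-time calibration
(below) rather than inherited from the reduced-model tradition
($\sigma = 0.02$ nA, $\tau = 2$ ms), for a structural reason. With
fast 2-ms noise at 0.02 nA the firing-rate fluctuations (SD $\approx$ 3.5
Hz) bridge the 5.4 Hz gap between the attractor rate and the decision
threshold within tens of milliseconds, so every trial is decided by a
noise spike: the indecision rate is structurally zero and the feedback
loop becomes irrelevant to the decision, contradicting the behaviour the
circuit is built to produce. A longer correlation time also makes the
noise act partly as a quasi-static bias present at stimulus onset, which
differentiates the lowest evidence levels (at $\varepsilon = 0$ the
initial tilt is sometimes tiny, producing slow, diagonal, reversal-prone
trials) — the regime in which the change-of-mind probability decreases
monotonically with evidence quality.

## Calibrated default profile

The couplings of the uncertainty and motor modules are not constrained by
published constants; they were calibrated once against the behavioural
target set (psychometric threshold $\alpha \approx 7.32\%$ and slope
$\beta \approx 1.32$; indecision rate $\approx 2.2\%$; trial-level
RT–uncertainty correlation $\approx 0.85$; monotone-decreasing
change-of-mind curve with error-to-correct changes peaking at low
evidence; slower errors; the uncertainty "<" divergence) and then frozen
as the package defaults:

| parameter | value | units | role |
|---|---|---|---|
| `J_mc0` | 0.0072 | nA per unit $y_U$ | uncertainty feedback gain |
| `tau_mc` | 350 | ms | uncertainty-module time constant |
| `J_V_inh` | 0.1 | nA/Hz | sensorimotor → inhibitory drive |
| `J_N_inh` | 1 | — | inhibitory → uncertainty coupling |
| `mu_tonic` | 7 | nA | tonic bias to the uncertainty population |
| `tau_h` | 300 | ms | motor integrator time constant |
| `J_N_LR`, `J_N_RL` | 2 | — | motor mutual inhibition |
| `sigma_noise` | 0.0125 | nA | noise amplitude |
| `tau_noise` | 12 | ms | noise correlation time |

Every constant is overridable through `model_parameters()` or a YAML/JSON
configuration file (`load_config()`), which also accepts seconds-based
time constants via `time_unit: s`.

## Uncertainty read-outs and analyses

Per trial we report the **peak** of $y_U$ (real-time read-out) and the
**area** under $y_U(t)$ over the recorded window, computed with the
trapezoidal rule on the millisecond time grid (units Hz·ms). Both are
feature-scaled to $[0,1]$ across a whole trial set per measure when
summarised. In coupled-trial (multi-stage) simulations the first trial's
area $X_n$ sets a bias $C_{n+1} = \alpha X_n + \beta$ (defaults
$\alpha = 0.008$ nA per Hz·ms, $\beta = 0.5$ nA) added to the tonic input
$\mu$ of the second trial, after which the stored bias resets to zero.
The units of $X_n$ are a convention the area measure fixes; $\alpha$ is
interpreted per the same convention.

The psychometric function is fitted with a Weibull,
$p = 1 - 0.5\,e^{-(\varepsilon/\alpha)^\beta}$, by binomial maximum
likelihood by default (`method = "ls"` gives plain least squares); the
form fixes $p(0) = 0.5$ and gives $p(\alpha) = 1 - 0.5/e \approx 0.816$
(the conventional description of $\alpha$ as the "85% threshold" does not
hold exactly for this parameterisation). The RT–uncertainty regression is
reported at two pairing levels because they answer different questions:
the trial-level Pearson correlation (the headline $r$) and the
six-condition-mean regression whose $R^2$ is near unity; a single pairing
cannot produce both numbers.

Indecision trials are flagged, retained in the trial table, and excluded
by every analysis function. Change-of-mind probabilities are computed over
the analysed (non-indecision) trials of each evidence level, and the total
curve equals the sum of the two directional curves by construction.

## Phase-plane and bifurcation analysis

The stability analysis studies the two-dimensional sensorimotor subsystem
in isolation, replacing the feedback term $J_{mc0} y_U$ with a constant
current $I_{fb}$ (the bifurcation parameter) and setting the noise to
zero. Fixed points are found by multi-start damped Newton iteration (17 ×
17 starts over the unit square, analytic Jacobian, residual tolerance
$10^{-12}$ s$^{-1}$, deduplication at $10^{-6}$), classified by the
Jacobian eigenvalues, and labelled: a stable point with
$|S_1^* - S_2^*| < 0.05$ is the *choice-neutral attractor* (the threshold
is arbitrary but recorded and configurable). Nullclines are located by
sign-change bracketing on a grid followed by root polishing, and a
brute-force residual-grid oracle cross-checks the finder in the test
suite. The bifurcation scan refines every change of the fixed-point count
by bisection to $10^{-4}$ nA; critical currents are reported at the
midpoint. Scanning a range in either direction yields identical branches
(the procedure is stateless).

With the stimulus on at $\varepsilon = 0$, the default profile gives the
winner-take-all structure (two choice attractors and a saddle) at low
feedback, an intermediate window with an additional choice-neutral
attractor, and a collapse to a single choice-neutral stable state once
the feedback current exceeds $\approx 0.019$ nA. At a constant feedback
of 0.03 nA — a level the within-trial bump reaches on high-uncertainty
trials — only the choice-neutral state remains, which is the transient
reconfiguration that permits changes-of-mind. Both $S_1$ and its firing
rate $H_1$ are exported for every branch.

## What the simulations do and do not show

The generator reproduces the study conditions: the evidence-quality grid
{0, 3.2, 6.4, 12.8, 25.6, 51.2}%, counterbalanced correct sides, 900 ms
pre-stimulus period, 4 s response timeout, and per-trial RNG streams
derived reproducibly from one master seed. It emulates stationary
within-trial noise and i.i.d. trials; it does not emulate across-trial
slow drifts, lapses, motor execution noise, or any learning, so passing
tests certify the circuit's internal consistency and its agreement with
the published simulation-level statistics, not fits to any empirical
dataset.

Known limitations of the calibrated profile, measured at large n:

* The error branch of the uncertainty-by-evidence pattern is flat rather
  than increasing: the "<" shape appears as a strongly decreasing correct
  branch with a monotonically growing error-minus-correct divergence
  (normalized gap $\approx 0.31$ at $\varepsilon = 25.6$), while mean
  error uncertainty itself stays roughly constant across evidence levels.
* Mean error RT exceeds mean correct RT clearly at $\varepsilon \ge
  12.8$ and overall, but the two are statistically indistinguishable at
  the two lowest non-zero levels.
* The error-to-correct change-of-mind curve is nearly flat between
  $\varepsilon = 3.2$ and 6.4 (its values there differ by well under one
  percentage point), so the location of its maximum over the non-zero
  grid is resolved only with very large trial counts.

## Problem sizes and numerics in the tests

The test suite simulates 3000 trials per condition for the behavioural
criteria (plus 5000 per non-zero condition for the change-of-mind curve),
500 per condition for the step-size comparison (0.5 vs 0.1 ms; summary
statistics agree within Monte-Carlo error, mirroring the convergence
check of the original study), and 400 per condition for the
feedback-ablation experiment ($J_{mc0} = 0$: change-of-mind vanishes
while the evidence-graded uncertainty signal survives). The acceptance
script uses 2000 trials per condition for the psychometric/uncertainty
targets and 8000 per non-zero condition for the change-of-mind curve.
Deterministic checks (transfer-function limits, exchange symmetry,
fixed-point residuals $\le 10^{-10}$, nullcline-vs-Newton
cross-validation) run at machine-precision tolerances.
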