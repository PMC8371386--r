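---
title: "Neural gate models for ion channel kinetics: methods and design"
author: "iongate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural gate models for ion channel kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(iongate)
```

This vignette is the package's account of its science: the models and
their assumptions, the state-space estimation procedure that makes
training possible, the parameters that matter, and the numerical and
design choices made where the design was genuinely open. It states no
empirical result that the package's tests do not themselves compute.

## 1. The mechanistic models

**Candidate model.** The working model of the hERG/I~Kr~ current is the
two-gate Hodgkin–Huxley form

$$I = g\,a\,r\,(V - E), \qquad
\frac{dx}{dt} = \alpha(V)(1-x) - \beta(V)x, \qquad
\alpha = A_\alpha e^{B_\alpha V},\; \beta = A_\beta e^{B_\beta V},$$

with activation gate $a$ (slow: time constants of order seconds near
0 mV), inactivation gate $r$ (fast: tens of milliseconds), eight kinetic
constants and the maximal conductance $g$. The reversal potential is not
fitted but computed from the Nernst equation; with the package defaults
(4 mM external / 110 mM internal K^+^, 294.55 K) it is $-84.1$ mV. Units
are fixed package-wide — ms, mV, nA, µS, mM, rates in ms^−1^ — which
removes a whole class of silent unit bugs and matches the nA scale of the
observation noise.

Key structural assumption: at constant voltage each gate relaxes as a
*single* exponential, $x(t) = x_\infty + (x_0 - x_\infty)e^{-t/\tau}$ with
$x_\infty = \alpha/(\alpha+\beta)$, $\tau = 1/(\alpha+\beta)$. This is
both the candidate's limitation and the package's main test oracle.

**Ground-truth model.** The data-generating model for the synthetic
studies replaces the activation gate by a linear three-state chain
C1 ⇌ C2 ⇌ O, all four transition rates of the exponential form above,
sharing the candidate's inactivation gate. Its open-state occupancy obeys
a second-order ODE, so constant-voltage relaxation is a sum of **two**
exponentials — dynamics the candidate cannot represent, i.e. built-in
model discrepancy. The main design choices:

* *Chain topology*: the simplest chain with more than one closed state,
  C1 ⇌ C2 ⇌ O. Anything deeper changes quantity, not quality, of the
  discrepancy.
* *Default parameters*: the C1 ⇌ C2 step reuses the candidate's
  literature-plausible activation rates; the C2 ⇌ O step is roughly an
  order of magnitude faster. At a −40 mV tail the two eigen-time-constants
  are ≈ 126 ms and ≈ 4 s (ratio ≈ 32, comfortably above the ≥ 3 design
  floor), so deactivation is unmistakably two-exponential — the signal the
  whole study is about. The defaults live in `ground_truth_params()` and
  can be replaced by any externally identified set via
  `read_params_json()`; they are explicitly *defaults*, not a claim about
  the true channel.
* *Conductance*: 1 µS in both generators, following the synthetic-study
  convention; currents are then tens of nA against 0.1 nA noise.

## 2. Voltage protocols

Step protocols are ordered (duration, voltage) segments with a half-open
$[t_{\text{start}}, t_{\text{end}})$ convention: the voltage at a
discontinuity belongs to the *new* step. The same convention is used by
the simulator (which restarts integration at each boundary), the spline
segmentation and the capacitance masking, so boundary samples are never
double-counted.

The genuine published waveforms of the classical hERG protocol suite are
not redistributable inside this package, so the generators produce
*surrogates*, deliberately named `pr3_like`, `pr5_like`, `pr4_like`:

* `pr3_like` (activation): per sweep 1 s hold at −80 mV, 4 s test step
  sweeping −60…+40 mV, 1.5 s tail at −40 mV. The long test steps let the
  slow activation approach steady state across the sweep, covering the
  activation branch of $(a, V)$ space.
* `pr5_like` (deactivation): 1 s hold, a *strong* 2 s activating step at
  +40 mV (driving $a$ to ≈ 1), then 4 s tails sweeping −120…−40 mV. The
  strong step matters: tails must *enter* at high $a$ so the
  high-$a$/low-$V$ deactivation region is actually visited — this is the
  region an activation protocol alone never reaches, and the region every
  deactivation prediction needs.
* `pr4_like` (inactivation; used as the unseen prediction protocol):
  1 s hold, 0.8 s at +40 mV, then a brief 100 ms test step sweeping
  −120…0 mV. Its dwell at high $a$ and low $V$ is brief, which is exactly
  why a Pr3+Pr4 training pair leaves that region sparse (Section 6).
* `make_sinusoidal_protocol()` / `make_ap_protocol()`: sampled waveforms
  (sum of three sinusoids around −30 mV; a train of action-potential-like
  spikes) emulating condensed protocol designs, used only for prediction.

Archived experimental waveforms can be loaded with `read_protocol_csv()`
and used everywhere a generated protocol can.

## 3. Simulation

The solver is an adaptive Dormand–Prince 5(4) pair with the standard
fourth-order dense output, written in R because no ODE package is
available in the target environment. Tolerances default to
atol = 10^−6^, rtol = 10^−8^; integration is hard-restarted at every step
boundary so the discontinuous driving term is never stepped across, and
the maximum step is capped (50 ms; near the waveform's sample spacing for
sampled protocols) so narrow features are not missed. Two-gate
Hodgkin–Huxley models on step protocols additionally have an *exact*
piecewise-exponential propagator (`method = "analytic"`, selected by
`"auto"`); the solver and the closed form agree to < 10^−5^ and check one
another in the tests. The propagator is what makes candidate-model
fitting cheap. Initial conditions are always the steady state at the
holding voltage (−80 mV), the standard experimental condition.

Observation noise is i.i.d. Gaussian (default SD 0.1 nA), added to
currents only — never to states — with seeds derived from a master seed
(one offset per protocol) so every dataset is reproducible bit for bit.

## 4. State-space estimation

Training data are tuples $(a, V, da/dt)$ recovered from current traces:

1. **Per-step splines.** One cubic smoothing spline per constant-voltage
   segment (never across a discontinuity). By default the smoothing
   parameter is chosen per segment by generalised cross-validation
   (`stats::smooth.spline`), which adapts to the very different noise
   amplification across segments; `smoothing = 0` gives an interpolating
   spline for noise-free data. Segments with fewer than five usable
   samples are skipped with a warning.
2. **Algebraic inversion.** With the trusted inactivation model providing
   $r(t)$ analytically, $a = I_s / (g\,r\,(V - E))$ pointwise from the
   smoothed current $I_s$. The estimate is *not* clipped to $[0,1]$;
   out-of-range values are information, not errors.
3. **Derivative.** On constant-voltage segments ($dV/dt = 0$, and the
   summation over the other gates reducing to the single $r$ term),
   $$\frac{da}{dt} = \frac{1}{r}\left[\frac{dI_s/dt}{g\,(V-E)} - a\,\frac{dr}{dt}\right].$$
4. **Guards.** The denominator vanishes as $V \to E$ or $r \to 0$, so
   samples with $|V - E| <$ `v_min` (1 mV) or $r <$ `r_min` (10^−3^) are
   masked invalid rather than returned; both guards are configurable.
   Capacitance blanking (5 ms after each step, the convention for real
   recordings) is applied before spline fitting; noise-free tests use 0.
5. **Scaling.** Tuples are normalised by fixed divisors
   $(a, V, da/dt) \mapsto (a,\; V/100,\; 1000\,da/dt)$ so each variable is
   O(1) — the only direction of the "(1, 100, 1000)" normalisation
   consistent with mV-scale voltages and ~10^−3^ ms^−1^ derivatives. The
   divisors are stored with the training set and inverted inside every
   neural right-hand side.

On noise-free candidate data this round trip reproduces $(a, da/dt)$ with
interior RMSE far below 10^−3^ (the acceptance suite asserts exactly
this); with noise, accuracy degrades monotonically with the noise SD.

## 5. Neural gate models and training

The network is a fully connected multi-layer perceptron, leaky-ReLU
(slope 0.01) hidden layers, linear output, biases folded into the weight
matrices. The reference architecture is 5 hidden layers × 200 nodes;
depth and width are configuration (`network_spec()`), and the package's
own tests use 3 × 32 — the regression surface is a smooth 2-D function,
and the compact net keeps the CPU-only test budget honest without
changing any qualitative outcome.

Three ways of closing the gate ODE:

* **NN-f** (full): $da/dt = N(a, V)$ — maximally flexible, no mechanistic
  prior.
* **NN-d** (discrepancy): $da/dt = f(a, V) + N(a, V)$ with $f$ the
  *fitted* candidate gate. With a zero network NN-d *is* the candidate
  (exact, to floating point — a test asserts identity), so the network
  starts from a good prior and learns only the correction.
* **NN-r** (rates): $da/dt = N_\alpha(V)(1-a) - N_\beta(V)\,a$ with
  softplus-positive network outputs. This keeps solutions in $[0,1]$ by
  construction but is affine in $a$ at fixed voltage, so it *cannot*
  express the curvature that two-time-constant deactivation induces in
  the $(a, da/dt)$ relation — useful precisely as the structured control.

Training is plain mean-squared-error regression of the scaled derivative
(for NN-d, of the scaled residual) with Adam — deliberately *not*
backpropagation through the solver, which is impractical for hour-long
voltage-clamp series. Defaults: full batch, 450 epochs, learning rate
3 × 10^−3^ decaying geometrically to a tenth over the run (the decay
mainly reduces seed-to-seed endpoint variance), seeded uniform fan-in
initialisation. The seed is a required, recorded argument; weight
initialisation and minibatch shuffling both derive from it, and the
caller's RNG state is never disturbed. Non-finite losses abort with a
diagnostic rather than silently producing a broken model.

Steady states of a trained gate need care: a regression surface has no
algebraic root. `nn_steady_state()` brackets a sign change of the learned
right-hand side on a fine grid in $[0,1]$ and bisects; if no sign change
exists it falls back to a 10 s simulated hold and warns. The fallback is
not cosmetic — trained full-replacement networks frequently have no exact
root at the holding voltage because the data near $V = E$ are the
noisiest in the whole pipeline (the driving force $|V - E| \approx 4$ mV
amplifies 0.1 nA of current noise into ≈ 0.04 of $a$-noise).

## 6. The synthetic study and its diagnostics

`run_synthetic_study()` chains the whole pipeline deterministically:
generate (ground-truth or candidate generator) → fit the candidate
(multi-start L-BFGS-B on log-rates, bounds $A \in [10^{-7}, 10^3]$
ms^−1^, $B \in [-1, 1]$ mV^−1^, soft rate cap of 10^3^ ms^−1^ at
±120 mV) → estimate state space (trusted $r$ gate, known $g$) → train
NN-f and NN-d → tabulate mean absolute errors of every model against the
noisy data on every protocol (all samples; blanking-restricted MAE is a
flag away) → coverage diagnostics.

What the generator emulates: protocol structure, steady-state holding,
slow/fast gate separation, additive Gaussian observation noise, and the
two-time-constant deactivation discrepancy. What it does *not* emulate:
capacitive charging transients, series-resistance and leak artefacts,
temperature drift, run-down, or correlated noise. A green test therefore
establishes that the method recovers *structural kinetic* discrepancy
from idealised recordings — not that it survives every experimental
artefact; flexible models can absorb artefacts as happily as dynamics.

The coverage diagnostics make the extrapolation failure mode measurable:
`coverage_map()` bins the $(a, V)$ training trajectories (default 50 × 50
over $[0,1] \times [-140, 60]$ mV), and `extrapolation_fraction()`
reports the fraction of a prediction trajectory falling in bins with no
training occupancy within a 1-bin neighbourhood. Training on the
activation + *inactivation* pair (Pr3+Pr4) leaves the sustained
high-$a$/low-$V$ region unexplored; predicting the deactivation protocol
then requires extrapolating into that hole, and the prediction error
rises accordingly — whereas the mechanistic candidate, for all its
discrepancy, extrapolates gracefully because its structure restricts it.
The acceptance suite reproduces this ordering.

## 7. Numerical choices and degenerate inputs

* Solver tolerance asymmetry (atol 10^−6^ > rtol 10^−8^) follows the
  reference setting; halving both changes gate solutions by < 10^−5^.
* Step-size underflow or exceeding the step budget raises an error
  carrying the failure time.
* `three_state_steady_state()` solves the rate-matrix null space with the
  conservation constraint replacing one balance equation; an all-zero
  rate matrix is rejected.
* Ties at protocol boundaries resolve to the *new* segment everywhere.
* Checkpoints are single JSON files (architecture, mode, scaling, seeds,
  candidate/inactivation parameters, full-precision weights); round trips
  restore bitwise-identical forward evaluations, and truncated or
  version-mismatched files are rejected at load.
* The candidate fit thins residuals to a 5 ms grid by default: with both
  gates' time constants ≥ 40 ms this loses no identifiable information
  and cuts fitting cost an order of magnitude.

## 8. Known limitations

* Training uses step protocols only; time-varying-voltage segments would
  need the $dV/dt$ term of the product rule and are out of scope.
* One neural state: dynamics needing three or more activation states are
  approximated only as well as a nonlinear $(a, V) \mapsto da/dt$ surface
  allows; the projection of a second-order system onto one state is
  inherently lossy.
* No uncertainty quantification on fits or networks.
* No Q10/temperature scaling; potassium currents only.
* Neural gate predictions outside the trained region are untrustworthy by
  construction; the package measures this (Section 6) rather than
  pretending to fix it.
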