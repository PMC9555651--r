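---
title: "Fractional-order dynamics of socially buffered stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order dynamics of socially buffered stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressdyn)
```

## The model

`stressdyn` analyses a three-variable kinetic model of psychological
stress in which social support buffers the stress response. The state is

* `X(t)` — perceived psychological stress,
* `Y(t)` — symptoms of stress-related ill-health,
* `Z(t)` — received social support currently in use (out of a bounded
  pool `S0`, so `S0 - Z` is support available but unused),

and the dynamics are

$$
\begin{aligned}
D^{q_1} X &= k_1 A + (k_2 B - k_6) X + k_3 Y - k_4 X Z - k_5 X^2,\\
D^{q_2} Y &= k_6 X - k_7 Y,\\
D^{q_3} Z &= k_8 (S_0 - Z) Y - \beta k_4 X Z - k_9 Z,
\end{aligned}
$$

an Oregonator-like activator–inhibitor structure: environmental stress
`A` drives `X`, kindling (`k_2 B X`, stress begetting stress) amplifies
it, buffering (`k_4 X Z`) consumes both stress and support, and support
is recruited by symptoms at rate `k_8` from the unused pool. `A` is
periodically forced, `A(t) = A_0 + \rho \sin(\omega t)`, which is what
makes chaos possible; the unforced system settles on fixed points or
simple oscillations.

`D^{q}` is the Caputo fractional derivative of order `q ∈ (0, 1]`, a
power-law-weighted memory of the integer derivative. Psychologically, the
order acts as a memory strength: at `q = 1` the dynamics are Markovian,
and as `q` decreases the past exerts a longer reach — the stress response
today reflects the accumulated history of stressors and support rather
than the instantaneous state alone. The Caputo form (rather than
Riemann–Liouville) is used so that initial conditions are ordinary state
values and constants have zero derivative.

The `table1` preset (`stress_params()`) fixes
`A0 = 1, S0 = 10, beta = 0.5, k1 = 1, k2 = 1, k3 = 0.01, k4 = 2,
k5 = 0.3, k6 = 0.01, k7 = 0.01, k8 = 0.1, k9 = 0.01`. The interesting
regimes studied throughout are reached with kindling `B` between 1 and 3
and forcing `rho = 11`, `omega` near 1.5.

## Stationary states and fractional stability

With the forcing off (`rho = 0`), stationarity forces
`Y* = (k_6/k_7) X*`, and eliminating `Z*` through the support equation
reduces the problem to a cubic in `X*` (`find_equilibria()`). The three
real roots are polished by damped Newton iteration to residuals below
1e-12 — necessary because the middle root's support coordinate is
ill-conditioned: `Z*` there is a ratio whose denominator nearly cancels,
so a fourth-decimal change in `X*` moves `Z*` by whole units.

```{r equilibria}
eq <- find_equilibria(stress_params(B = 2.2))
eq[c("X", "Y", "Z", "residual_norm", "c2", "c1", "c0")]
```

Stability of a commensurate fractional linearisation is decided by the
Matignon sector condition: asymptotically stable iff every eigenvalue
satisfies `|arg λ| > q π / 2`. Unlike the classical half-plane test, the
stable region widens as `q` decreases, so an equilibrium that is unstable
classically can be stable at low order. That is not hypothetical here: at
`B = 2.2` the positive equilibrium has two positive real eigenvalues and
is unstable at every order, but at `B = 1.0`–`1.1` the unstable pair is
complex with `|arg λ| ≈ 0.87`, and the state is Matignon-stable for
`q` below about 0.55. The package reports what the criterion gives;
classification uses the principal argument with a 1e-9 marginal band
(boundary cases are flagged and reported unstable, keeping the
classification deterministic).

## The fractional integrator

`fode_solve()` (R, any field) and `simulate_stress()` (compiled, the
stress model) implement the predictor–corrector Adams–Bashforth–Moulton
scheme for Caputo initial value problems: the fractional rectangle rule
predicts, the fractional trapezoid corrects once at the predicted point
(PECE; further sweeps via `corrector_iterations`). Orders may differ per
equation. The theoretical convergence order `min(2, 1 + q)` is verified
empirically by `empirical_convergence_order()`, and the `q = 1` limit
reproduces the classical cumulative PECE iterates to machine precision.
Two independent oracles back the scheme in the test suite: a
Mittag–Leffler series solution for linear relaxation, and direct
singularity-aware quadrature of the Caputo integral
(`caputo_derivative()`).

Numerical choices worth knowing:

* **Divergence.** Strongly fractional orders (`q` below about 0.5) can
  send the forced model to infinity in finite time. Any state magnitude
  beyond `blowup` (default 1e8) truncates the trajectory and sets a flag
  rather than raising an error, so parameter sweeps survive divergent
  cells.
* **Short memory.** The per-step history sum makes a full-memory run
  O(N²). `memory_horizon = L` caps the exact sum at the most recent `L`
  steps — but plainly discarding older terms would be disastrous near
  `q = 1`, where the quadrature weights tend to a constant and the tail
  carries most of the underlying Volterra integral. The package instead
  freezes the weight of older terms at its horizon value and accumulates
  them in a running sum: exact at `q = 1`, and for `q` near 1 a mild
  approximation (the true weights drift like `s^{q-1}`). In a chaotic
  regime any such scheme difference is amplified at the rate of the
  leading Lyapunov exponent, so truncated and full-memory trajectories
  agree closely only over a bounded window while their attractor
  statistics remain consistent; the tests check exactly that.
* **Defaults.** `h = 0.01` and initial state `(1, 1, 1)`. The initial
  state is an arbitrary point in the chaotic attractor's basin; because
  the system is multistable, results that depend on attractor identity
  are checked from more than one start.

## Lyapunov spectrum

`lyapunov_spectrum()` runs a Benettin–Wolf procedure on the variational
system: the state and an orthonormal tangent frame are co-integrated
(the tangent rows share the state's fractional orders), Gram–Schmidt is
applied every `renorm_interval` steps, and exponents are accumulated log
norms over elapsed post-transient time. Two design points are specific
to the fractional setting:

* **Tangent memory restart.** After each renormalisation the tangent
  subsystem's fractional history restarts from the orthonormalised frame.
  Without this, the replaced tangent values would be inconsistent with
  their own memory integral and Gram–Schmidt would not commute with the
  update. It is an approximation — the tangent flow loses memory older
  than one renormalisation leg — adopted deliberately; with the default
  leg of 10 steps the effect on a `q ≈ 1` system is small.
* **`mode = "restart"`.** Optionally the *state* memory also restarts
  each leg, making every leg a fresh Caputo initial value problem. This
  reproduces the behaviour of widely used fractional Lyapunov codes that
  re-initialise their solver every renormalisation interval. Both modes
  give consistent spectra for this model.

Validation: a linear diagonal system at `q = 1` recovers its exact
exponents to 0.01; the exponent sum matches the trajectory-average
Jacobian trace within 5%; a stable forced limit cycle shows a leading
exponent at zero within 0.02.

In the chaotic regime (`B = 2.2, rho = 11, omega = 1.5, q = 0.99`) the
converged spectrum is approximately `(0.09, 0.00, -9.4)` (t_total = 3000);
at the desk-scale settings used by the acceptance script
(t_total = 500, transient = 100, memory horizon 1000) the estimates are
still drifting, which the `history` field and `converged` flag expose.
The exponent sum is pinned near the attractor's mean divergence of about
-9, which constrains how negative the third exponent can be.

`kaplan_yorke()` derives attractor dimensions under two conventions:
the standard Kaplan–Yorke interpolation `j + (Σ_{i≤j} LE_i)/|LE_{j+1}|`,
and a variant `3 - LE_1/|LE_3|` found in parts of the fractional-chaos
literature. They disagree strongly whenever `|LE_3|` is large; both are
reported (`glance()`) rather than adjudicated.

## Spectral entropy and C0 complexity

Both metrics summarise the one-sided power spectrum of a zero-mean
window. Spectral entropy is the Shannon entropy of the relative spectral
density normalised by `ln(N/2)` — 0 for a single-bin tone, 1 for a flat
spectrum. C0 complexity thresholds the two-sided spectrum at `r` times
the mean one-sided power, keeps only the bins strictly above it (the
regular part), and reports the energy fraction of what remains. The
normalisation in the spectral-density denominator runs over
`k = 0..N/2-1` as the definitions state; whether a two-sided
normalisation was intended by the metric's originators is noted here but
not second-guessed.

Choices:

* **Control parameter.** `r = 1` is the default everywhere and is
  recorded in every result; the threshold `G_N` then equals the mean
  two-sided bin power. C0 is nondecreasing in `r` (a larger threshold
  removes more bins); a sensitivity sweep over `r ∈ [0.5, 10]` is a
  one-liner with `complexity_metrics()` and is exercised in the tests.
* **Windowing.** `signal_window()` drops the first half of the
  trajectory and resamples the remainder to `N = 4096` evenly spaced
  points. With `h = 0.01` and `t_end = 1000` the window spans 500 time
  units — about 120 forcing periods at `omega = 1.5`. The window length
  matters: halving the horizon to 500 depresses spectral entropy by
  roughly 0.15 across the board (fewer forcing periods per window), which
  is why both the single-run policy and the metric scans integrate to
  1000 time units.
* **Regime rule.** `classify_regime()` labels a point chaotic iff
  SE > 0.4 *and* C0 > 0.12 (conjunctive). Under the default window
  policy the C0 threshold is the stricter of the two: chaotic runs at
  `q = 0.99` score SE ≈ 0.44 but C0 ≈ 0.08–0.10, crossing 0.12 only at
  `q = 1.0` or with longer windows. SE-only exceedance is therefore also
  reported in scans, and the thresholds are arguments, not constants.

## Scans

`bifurcation_scan()` (distinct peak values of `X`) and `metric_scan()`
(SE / C0 / leading exponent) sweep `q`, `B`, `rho`, `omega`, or the
initial conditions `Y0` / `Z0`, with per-point divergence masking.
Sweep policy: `h = 0.01`, `t_end = 1000` with a 50% transient, memory
horizon 1000 steps. The long horizon is not cosmetic: the model's
periodic orbits contract at rates of order 0.01, so a 250-time-unit
transient leaves peak sets smeared (dozens of spurious distinct peaks);
at 500 post-transient time units the periodic/chaotic contrast is crisp
(2–4 distinct peaks vs > 100). Peak deduplication at 1e-4 and the
">50 distinct peaks" chaos signature are package conventions chosen for
robustness at this resolution, not physical constants.

The structure these scans resolve, at coarse desk-scale resolution:
chaos confined to a narrow forcing-frequency window around
`omega ∈ [1.5, 1.7]` at `rho = 11`; alternating periodic and chaotic
bands in `q ∈ [0.8, 1]`; sensitivity to initial conditions (the chaotic
label fires only for small `Y0`), including bistability — two runs
differing only in `Y0` can land on different regimes with identical
parameters.

## What the tests do and do not show

The dynamical pipeline is deterministic; the only seeded randomness is in
the validation fixtures (`fixture_signal()`: exact-bin sinusoid, Gaussian
white noise, logistic-map iterates). These fixtures anchor the metrics'
endpoints (tone → SE ≈ 0; broadband chaos → high SE and C0) but are
synthetic: they say nothing about empirical stress time series, and the
model itself is not fitted to data anywhere in this package. Problem
sizes in the test suite are desk-scale (horizons of 200–1000 time units,
grids of 10–40 points); they resolve the regime structure described
above but not fine bifurcation detail, and Lyapunov estimates at these
horizons carry visible finite-time drift, which is surfaced rather than
hidden.

## Known limitations

* Incommensurate-order stability analysis is out of scope (simulation
  with distinct `q_i` works; the Matignon classification assumes a
  common order).
* No Riemann–Liouville or Grünwald–Letnikov operators, no adaptive
  stepping, no orders above 1.
* The tangent-memory restart in the Lyapunov procedure is an
  approximation without an error bound; agreement with the `restart`
  mode and with classical oracles at `q = 1` is the evidence offered.
* Exponent estimates at sweep-scale horizons are finite-time quantities;
  treat `le1` maps from `metric_scan()` as indicative, and re-run points
  of interest at longer `t_total`.
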