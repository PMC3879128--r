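---
title: "An exact finite Markov model of cargo transport by kinesin ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An exact finite Markov model of cargo transport by kinesin ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorensemble)
```

## The physical model

A cargo is pulled along a microtubule by an ensemble of `m_bar` identical
kinesin motors. The track is a one-dimensional lattice of binding sites with
period `d_s = 8` nm. Each motor is permanently bound to the cargo through an
elastic linkage of stiffness `k_el` and rest length `l0` that resists only
stretch: `F(l) = k_el (l - l0)` for `l >= l0`, zero in the slack region,
and the mirrored law under compression of the coordinate (the linkage never
pushes). Engaged motors occupy lattice sites (several motors may share a
site: a change of coordinates maps all cargo attachment points to one, so
identically stretched motors coincide); each engaged motor can step forward
one site or detach, and each unattached motor can re-attach near the cargo.
The cargo relaxes to mechanical equilibrium between events — the cargo's
relaxation time is far shorter than the waiting times between motor events
— and is subject to a constant opposing load `F_load`. Thermal motion of
the cargo is modeled by a Gaussian of width `sigma_th` truncated at three
standard deviations around the equilibrium position. When the last motor
detaches the cargo is lost and the run ends.

Single-motor kinetics are force dependent:

* **Stepping.** Michaelis–Menten ATP turnover
  `P_step(F) = k_cat [ATP] / ([ATP] + K_m(F)) * eps(F)` with
  `K_m(F) = (k_cat + k0_off e^{F d_l / k_B T}) / k_on` and binding
  efficiency `eps(F) = (1 - F/F_s)^2` between zero and the stall force
  `F_s`, `1` for assisting loads, `0` at or above stall.
* **Detachment.** Tied to the measured processivity
  `L(F) = d_s [ATP] A e / ([ATP] + B (1 + A) e)`, `e = e^{-F delta_l/k_B T}`,
  through `P_step/P_detach = L/d_s`; above stall, a constant `P_back`.
* **Attachment.** Total rate `(m_bar - m) P_att`, split uniformly over the
  lattice sites within `l0` of the cargo (a motor binds without stretching
  its linkage). We read `P_att` as a rate per unattached motor; a per-site
  reading is obtained by scaling `P_att`.

Site rates multiply the single-motor law by the site occupancy and average
it over the truncated-Gaussian cargo position.

## From an infinite lattice to a finite chain

The *absolute configuration* — occupancy of every lattice site — is an
infinite-dimensional description, but the dynamics is translation
invariant: shifting every motor by the same number of sites leaves all
rates unchanged. Grouping absolute configurations by the *relative
configuration* (occupancies read from the rearguard motor, rendered as
strings such as `"M||MM"`) therefore preserves the Markov property, and
the projected rate from class to class is simply the total rate from any
one representative into the target class. The `relative_rates()` /
`transition_table()` functions implement exactly that: events are
enumerated from the canonical representative (rearguard at site 0) and
grouped by the projection of their targets.

The relative space is finite because the stall force bounds the extent a
configuration can reach. While the vanguard motor can still step, the
total elastic stretch is at most `m_bar F_s - F_load`; slack linkages add
up to `2 l0` of unstretched separation, and attachment behind a trailing
cargo can spread the ensemble by up to `F_load/k_el + 2 l0`. Thermal
fluctuation lets a motor step while its mean load is up to
`3 sigma_th k_el` above stall, and every assisting motor's force is
bounded by the vanguard's, so the noise allowance is `3 sigma_th` per
motor. `max_extent()` takes the larger of the stall and attachment
branches, each with the slack and thermal allowances plus one site for
the final step. This is marginally more generous than the minimal bound,
which costs a few extra states but is provably closed under the dynamics;
the Gillespie suite asserts empirically that no trajectory ever leaves
it. With all of `m_bar <= 4` the state count `N = 1 + sum_m C(n+m-2, m-1)`
stays in the hundreds to low tens of thousands.

## Solving the master equation

`build_generator()` assembles the sparse rate matrix in the column
convention `dP/dt = A P`; each diagonal entry balances its column so
columns sum to zero, and the empty (cargo-lost) state is absorbing. The
continuous-time convention is required for the conditional steady state
to exist; a discrete-time-looking diagonal would not conserve
probability under the matrix exponential.

`propagate()` applies the exponential of `A t`: densely for up to 2000
states, and by uniformization (a positive, probability-conserving series
in a dominated jump chain) above that, so large ensembles never require
a dense exponential. The reference initial condition mirrors the standard
protocol: a single engaged motor one second before the observation
window, conditioned on the cargo surviving to time zero
(`initial_distribution()`).

Conditioned on the cargo not being lost, the chain approaches a unique
quasi-stationary distribution supported on the states reachable from
`"M"`. `quasi_stationary()` computes it as the leading eigenvector of the
substochastic restriction `Q` — densely up to 1500 reachable states,
otherwise by sparse inverse iteration, which converges to the eigenvalue
of `Q` closest to zero (the quasi-stationary one for an absorbing
restriction). Long-horizon conditional propagation provides the
cross-check; the two routes agree to ~1e-10 total variation in the
three-motor test case.

## Observables

* **Velocity** sums `rate * displacement * P(state)` over every event,
  including self-transitions of the relative chain (a lone stepping motor
  keeps its relative configuration while moving the cargo a full period).
* **Run length** is the time integral of the velocity, evaluated in
  closed form through the expected occupancy times `tau = -Q^{-1} P0`
  rather than by time quadrature; an eigenmode integration serves as an
  independent check in the tests.
* **Step-size distribution**: each event's weight is `rate * P(state)`;
  weights are grouped by displacement within 1e-6 nm, the zero class
  (slack attachments and unloaded rearguard steps) is excluded, and the
  rest normalized. Every support point carries an attribution over
  `(kind, rearguard, from, to)`, which is how displacements beyond one
  lattice period are traced — exhaustively, not by sampling — to
  detachments of a taut opposing rearguard motor.

## Parameters

Defaults are the published Kinesin-I constants: `k_cat = 105` 1/s,
`k_on = 2e6` 1/(M s), `k0_off = 55` 1/s, `[ATP] = 2` mM, `F_s = 6` pN,
`d_s = 8` nm, `d_l = 1.6` nm, `delta_l = 1.3` nm, `A = 107`,
`B = 0.029` uM, `T = 300` K, `k_el = 0.32` pN/nm, `P_att = 5` 1/s,
`P_back = 2` 1/s. Two constants deserve comment:

* **`A = 107`** is read as one hundred seven (dimensionless). With that
  value the zero-force processivity is `L(0) = 854.7` nm, the
  physiological kinesin run length; reading it as `1e7` would give an
  absurd ~550 um.
* **`l0 = 110` nm** is not printed with the constants above; it is the
  kinesin tether rest length used by the Monte-Carlo study the constants
  come from, and every result that depends on it states it explicitly.
* **`sigma_th`** defaults to the equipartition width
  `sqrt(k_B T / k_el) ≈ 3.6` nm of a single linkage; `sigma_th = 0`
  selects the noiseless model. Both modes are first-class.

### The reference load for step statistics

The two-motor step-size analysis needs a load: the distribution's
support is load dependent and no single value is canonical. The 4-nm
mode arises from configurations in which *two* taut motors share the
load, so that one step moves the equilibrium half a period; with the
slack linkage such states exist at motor spacings of a full site only
when `F_load >= k_el d_s = 2.56` pN. The package's reference condition
is therefore `F_load = 3` pN — the smallest whole-piconewton load above
that threshold, keeping the run deep in the sub-stall regime. At loads
below the threshold the shared-load mode is replaced by near-period
partial steps (about 1.6 and 6.4 nm at 1 pN); the step-distribution
functions accept any load, and this sensitivity should be kept in mind
when comparing against experiments.

## Numerical choices

* **Cargo equilibrium** is solved exactly: the net spring force is
  piecewise linear and monotone, so the active piece is found by
  breakpoint scan and inverted — no iterative tolerance. When the balance
  holds on a whole interval (possible only at zero required spring
  force, e.g. a lone slack motor at `F_load = 0`) the midpoint is
  returned and flagged. Because of that tie-break, formal displacements
  of attach/detach events at exactly zero load reflect midpoint shifts;
  step-statistics reference runs therefore use a strictly positive load,
  where the equilibrium is unique.
* **Thermal averages** use fixed-order Gauss–Legendre quadrature
  (41 nodes, configurable via `options(motorensemble.quad_order = )`)
  applied piecewise between the breakpoints of the force law (slack
  boundaries and the stall switch of the detachment law), which restores
  spectral accuracy in the presence of kinks; the tests validate it
  against adaptive integration to 1e-8 relative.
* **Attachment boundary**: sites satisfying `|a_k - x_eq| <= l0` with a
  1e-9-site tie tolerance; the boundary case has zero probability in
  practice but is fixed for bit-reproducibility.
* **State order** is graded (motor count, then extent, then
  lexicographic occupancy) and the empty state is last, so generators
  are reproducible bit for bit.
* **Transitions into the empty state** carry zero displacement: the run
  ends through absorption, not through a final jump.

## The stochastic oracle

`simulate_ensemble()` is a direct event-driven simulation of the lattice
model, re-enumerating `absolute_transitions()` at every event — slow but
entirely independent of the projection and solver. `simulate_batch()`
exploits translation invariance to advance thousands of trajectories in
lock-step over the same event table the exact solver consumes, so exact
vs. simulated discrepancies isolate solver or projection defects rather
than rate differences. Both are exactly reproducible from an integer
seed (R's default Mersenne-Twister generator).

What the oracle runs do and do not show: agreement of the empirical state
distribution (20,000 two-motor trajectories at `t = 2` s, total variation
~0.01), of run lengths (one and two motors, within three standard
errors), of the velocity (survival-conditioned displacement slope), and
of the step histogram (total variation < 0.03) validates the projection
and the solver *for this model*. It says nothing about phenomena the
model excludes: backward steps, motor-cargo unbinding, cargo inertia or
explicit Brownian dynamics (replaced by the truncated-Gaussian
approximation), or heterogeneous motor species.

## Problem sizes used in the checks

The packaged tests and the acceptance script run: one motor (2 states,
closed-form regime, loads 0–5 pN); two motors at 0 and 3 pN (37–38
states); three motors (862 states with noise, ~640 noiseless); the
near-stall fine sweep on a 0.2 pN grid over 5.4–6.6 pN; and Gillespie
batches of 3,000–20,000 trajectories. Four-motor spaces (~16,000 states)
build with the same code path (sparse inverse iteration replaces the
dense eigensolve) but are not part of the routine checks.

## Known limitations

* The extent bound is intentionally slightly generous; state counts grow
  combinatorially with `m_bar`, so cluster-scale ensembles need the
  `n_cap` truncation, which drops boundary transitions and is flagged in
  every output manifest.
* Quantities that depend on the unprinted linkage rest length — the
  exact positions of rare large steps, the prominence of the shared-load
  step mode, and the single- versus multi-motor velocity ordering at low
  load — are parameter sensitive. With the defaults here, a three-motor
  ensemble at 0.5 pN is slightly *faster* than a single motor (the
  oracle confirms this is a property of the model, not of the solver);
  a two-motor ensemble is slower, as expected.
* At exactly `F_load = 0` the plateau tie-break makes event
  displacements convention dependent (see above); use a small positive
  load for step statistics.
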