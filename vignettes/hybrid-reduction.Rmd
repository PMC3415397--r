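---
title: "Hybrid models and dominant-scale reduction of excitable membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid models and dominant-scale reduction of excitable membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modeling problem

Many biophysical models are smooth dynamical systems whose behavior is
nevertheless *functionally modular in time*: during any one phase of a
periodic behavior only a few state variables actually shape the output, and
the identity of that dominant subset switches as the trajectory proceeds.
`hybridsys` provides two connected toolsets built around this observation:

1. **Hybrid dynamical systems machinery** — containers (intervals, labeled
   point sets, evaluable trajectories), an adaptive ODE integrator with
   dense output, arbitrary-precision zero-crossing event detection, and a
   simulator for regime-graph hybrid models with guards and reset maps.
2. **A dominant-scale reduction toolbox** — for conductance-based neuron
   models, it measures the instantaneous influence of each input term on
   the membrane potential, segments a trajectory into *epochs* of constant
   dominant ("active") input set, and assembles the per-epoch reduced
   (differential-algebraic) sub-models into a hybrid model. The assembled
   hybrid model is a *formal, executable hypothesis* about the mechanism of
   the behavior; simulating it and comparing against the full model tests
   that hypothesis.

The bundled worked systems are the classical space-clamped Hodgkin–Huxley
(HH) membrane and integrate-and-fire neurons.

# Containers

An `interval(lo, hi)` carries an absolute endpoint tolerance
(`tol = 1e-12` by default) and is closed by default: an event-located time
sits exactly on a regime boundary and must test as in-domain for *both*
adjacent segments, so membership at an endpoint is granted when the probe is
within `tol` of it. A `pointset` is an N×d named array with an optional
strictly increasing independent variable and labels mapping a name to a
*set* of row indices — repeated events (several spikes) share one label. A
`trajectory` adds domain checking and interpolation: cubic Hermite whenever
time derivatives are stored (always true for ODE output; Hermite reproduces
cubics exactly), linear otherwise.

# Integration and events

`integrate_ode()` implements the Dormand–Prince 5(4) embedded Runge–Kutta
pair with proportional–integral step control (safety 0.9, growth clamp
[0.2, 5], error exponents 0.17/0.04, defaults `rtol = 1e-8`,
`atol = 1e-10`, initial step `1e-4` of the span, at most 10^6 steps). A
single explicit solver is deliberate: every reduced regime produced by the
toolbox has its algebraic part available in closed form, so
differential-algebraic regimes are handled by *explicit substitution* of the
algebraic variables at every right-hand-side evaluation rather than by an
implicit solver, and the HH fixture is non-stiff at these tolerances.

Each accepted step stores `(t0, y0, f0, t1, y1, f1)`; the cubic Hermite
interpolant over these is the *dense output*, exact at the step endpoints
and O(h^4) in between. Event guards are scanned on `M = 20` equispaced
sub-samples of every accepted step (configurable via `opts$subsamples`);
each directional sign change is refined on the dense output by Brent's
safeguarded root finder to the event's time tolerance (`tol_t = 1e-10` by
default). Conventions that matter for reproducibility:

* several terminal candidates in one step: the earliest refined time wins;
  exact ties break by event declaration order;
* an event whose guard is already within `1e-9` of zero at a segment's
  initial time is suppressed for the first accepted step, so a reset that
  lands exactly on a guard does not immediately re-trigger;
* non-terminal events are pure observations: the stored trajectory is
  bit-identical with or without them; occurrences are recorded separately
  and as labels pointing at the nearest sample row;
* state-domain membership is checked at accepted steps only (the adaptive
  solver convention); leaving a domain raises an error naming the variable;
* three consecutive zero-duration hybrid segments at one time raise a
  livelock error.

# Hybrid models

A hybrid model is a finite regime set with a transition graph: each regime
carries a sub-model (possibly itself hybrid — the contract is recursive,
and the test surface exercises depth 2), each edge is triggered by a
terminal event of the source regime and may apply a reset map. Reset
right-hand sides are all evaluated on the pre-transition state
(simultaneous semantics: `{a -> b, b -> a}` swaps); unreset components pass
through bit-identically. Indicator variables are frozen constants set per
regime. Every sub-model formally exposes the full state vector through one
of four roles — dynamic (integrated), algebraic (substituted), shadow
(integrated, no feedback), frozen (dummy constant) — so each segment
reports the full n-dimensional state and segments abut exactly.

Evaluation of a stitched hybrid trajectory uses half-open segments
`[t_i, t_{i+1})` (final segment closed): at an exact transition time the
*post-reset* state is returned. The underlying formalism does not fix this
choice; it is this package's contract.

A nested hybrid sub-model that hits a terminal event with no internal
transition *surfaces* that event to its parent, which handles it with its
own transition table. This gives the hierarchy a simple, deterministic
semantics without parallel event processes (which are out of scope).

# Model interfaces

`model_interface()` wraps any model with pre-simulation hooks (request
validation/transformation), post-simulation hooks (output filtering),
conditions (sets of features with target truth values) and failure
recovery. Features are pure measures; condition evaluation never
short-circuits, and a feature that throws is reported as failed with an
error note so diagnostics stay complete. If the simulation itself fails
(stiffness, domain violation, dead end), `run_with_validation()` returns a
configurable sentinel objective (`1e10` by default, sign-configurable for
maximization) with `recovery_invoked = TRUE` instead of propagating the
error — the property that makes models safe inside optimization loops. The
sentinel is returned *iff* recovery ran. A neutral interface is
observationally equivalent to the bare model (bit-identical output).

# Dominant-scale analysis

For a conductance-based model the hub equation is

```
C dV/dt = sum_k G_k(x) (E_k - V) + s g_L (E_L - V) + c I_app
```

with gated conductances `G_k` in the gating variables, and 0/1 inclusion
flags `s` (leak) and `c` (applied current) that switch the passive terms in
or out of a reduced regime. The *quasi-static potential* is the
instantaneous fixed point of the hub with gating frozen:

```
V_qs = (sum_k G_k E_k + s g_L E_L + c I_app) / (sum_k G_k + s g_L)
```

and satisfies `rhs_V(V_qs) = 0` exactly. Influences are defined as:

* gating variable `x`: `Psi_x = |dV_qs/dx|`, obtained symbolically (the
  package's expression differentiator produces it in closed algebraic
  form); units mV per unit of the dimensionless gating variable;
* leak: `Psi_L = g_L |E_L - V_qs| / G_total`; applied current:
  `Psi_I = |I_app| / G_total` — the V_qs shift caused by removing the term.

This places all influences on a single mV scale so one threshold applies:
for scale tolerance `gamma > 1` the active set is
`A = { i : Psi_i >= Psi_max / gamma }` (inclusive at equality, monotone in
gamma). Timescales come from the first-order gating kinetics,
`tau_x = -1 / (d rhs_x / dx)` (equal to `1/(alpha+beta)` for alpha/beta
kinetics) and `tau_hub = C / G_total`.

`extract_epochs()` computes Psi along a trajectory on a uniform grid
(2000 points per window by default — Psi is a derived signal without solver
dense output), locates every zero crossing of `gamma Psi_i - Psi_max` with
root refinement on the trajectory interpolant, names each epoch's entry
change (which source joined or left) from the refined crossing at its
boundary, and merges epochs shorter than 0.5% of the analysis window.
When merging removes short intermediate epochs, the boundary naming prefers
a crossing that is realizable as a guard of the preceding merged epoch and
falls back to the set difference; multi-source boundaries are flagged as
non-generic. Timescale ratios are reported per epoch as diagnostics only —
they never trigger regime exits, since the guard set already encodes the
dominance assumptions and consistency violations are most useful as
*post-hoc* indicators of where a reduction is weakening.

## Reduced regimes and assembly

For an epoch with active set A, `build_reduced_regime()`:

* keeps only active terms in the hub equation (a gated term is kept when
  any of its gating variables is in A; the flags `s`, `c` are set to 0 for
  inactive passive terms);
* replaces each active gating variable that is uniformly fast in the epoch
  (`tau_x < tau_hub / rho` throughout, `rho = 2` by default) by its voltage
  asymptote `x = x_inf(V)` — the differential-algebraic reduction by
  substitution;
* keeps every inactive gating variable as a *shadow*: full kinetics driven
  by V, no feedback into the hub except through its (shadow) appearance
  inside an active term's conductance. Shadows are simulated rather than
  frozen because detecting where the regime's assumptions break requires
  tracking what the slaved variables do;
* installs a join guard (`gamma Psi_j - Psi_max` crossing zero upward) for
  every source outside A and a leave guard (downward) for every member,
  evaluated with all inclusion flags at 1 so the guards track the *full*
  model's dominance criteria.

`assemble_hybrid_reduction()` wires one regime per template element along
the cycle. In each regime only the guard named by the next element's entry
change is terminal; the other join/leave guards are kept as non-terminal
diagnostics. This is a deliberate design choice: the template defines
exactly one exit per regime, and making every guard terminal would turn any
benign transient reordering of a non-cycle crossing into a dead end of the
whole simulation. Resets are identity on retained variables (the reduction
has no discrete jumps); algebraic variables are re-initialized by
substitution on entry and the flags are set per regime as indicators.

# Calibration, results and honest limitations

Run on the canonical HH model in its repetitive-firing range (I_app = 10
µA/cm², 300 ms with the first 30% discarded as transient), the analysis at
the default `gamma = 3` yields a stable **four epochs per firing cycle**:

```
R1: {m, n}      recovery       (m joins)
R2: {m, h, n}   spike           (h joins)
R3: {h, n}      downstroke      (m leaves)
R4: {n}         refractory      (h leaves)
```

This is the classic four-phase mechanistic picture of the action potential,
and it is stable period-to-period (the acceptance suite checks the last two
cycles). The 0.5%-of-window merge threshold matters here: the raw crossing
sequence contains sub-millisecond flickers around the downstroke (m briefly
re-enters while Psi_h collapses) that merging absorbs; with the standard
300 ms / 30%-settle window the threshold is ~1 ms and the count is four.

The *reduction*, however, exposes a real limitation of this Psi
normalization, and we state it plainly rather than tune around it. Because
gating sensitivities are measured per full unit of a [0,1] gating variable
while the passive influences are instantaneous V_qs shifts, `Psi_n` exceeds
`Psi_leak` and `Psi_I` by a factor of 10–20 throughout the inter-spike
interval. Consequences, all reproducible with the bundled code:

* at `gamma = 3` the four sub-threshold regimes contain **no depolarizing
  drive** (neither leak nor I_app is ever active), so the assembled
  reduction relaxes to a fixed point and never fires;
* recruiting the passive terms needs `gamma >= ~19`, but there
  `gamma * Psi_I` hovers at `Psi_max` over an extended stretch of the
  upstroke — a ratio *plateau*, not a scale gap — so guard ordering is
  knife-edged and the reduced cycle either dead-stalls in the Na+K spike
  regime (which, entered a few mV too early, has a stable rest point) or
  lands on a qualitatively different attractor;
* the most robust working point found by the method's own tuning loop is
  `gamma = 15`, a three-regime template (`{m,n,Iapp}`, `{m,h,n}`,
  `{n,Iapp}`) that cycles indefinitely and reproduces the AP shape, but
  with firing periods ~25–45% longer than the full model across currents —
  the inter-spike regimes still lack the leak current.

`sweep_current()` therefore defaults to the calibrated `gamma = 15` (the
value at which the reduction actually oscillates), while the analysis
functions default to `gamma = 3`. A green four-regime test establishes that
the dominance segmentation is stable and matches the canonical mechanism;
it does **not** establish that the resulting hybrid reduction is
quantitatively faithful — with this Psi normalization it is not, and the
period-fidelity acceptance check is left failing by design rather than
weakened. Literature implementations of dominant-scale analysis use a
differently normalized (timescale-weighted) influence measure for which
close period agreement is reported; that exact formula is outside what this
package reimplements.

# Fixtures: what the generators emulate

`make_lif_squarespike()` builds the two-regime integrate-and-fire neuron:
leaky integration `tau dV/dt = -V + drive` (tau = 10 ms, drive = 2, both
normalized to a threshold of 1), a terminal upward threshold guard, and a
square spike: V is reset to `spike_height` (2) and held for exactly
`spike_duration` (1 ms) by a timer state `u` with `du/dt = 1` against the
guard `u - spike_duration`, then reset to 0. From V(0) = 0 the threshold
time is `-tau log(1 - V_th/drive) = 10 log 2 = 6.931 ms` and the cycle
period is exactly that plus the plateau, 7.931 ms — the closed forms the
event machinery is validated against. A sub-threshold drive (0.5) never
fires: period 0 by convention.

`make_hh_model("hh1952")` uses the canonical modern-convention squid
parameters (C = 1 µF/cm², gNa = 120, gK = 36, gL = 0.3 mS/cm²,
ENa = 50, EK = -77, EL = -54.4 mV) — textbook constants. The
`"interneuron"` tag is a **clearly synthetic stand-in** for a fast-spiking
cell: the same conductances with all rate functions sped up uniformly
2-fold (a temperature-like rescaling). A variant with selectively reduced
inactivation time constants was tried first and abolishes firing entirely
at these conductances, so it cannot serve as a firing fixture; no published
parameterization is reproduced and no literature-numeric claims attach to
this tag. Period measurement detects upward crossings of -10 mV (the
measured period shifts by under 0.01% for any detection level in
[-20, 0] mV), runs 300 ms and discards the first 30% as transient; `steady`
means the inter-spike intervals have a coefficient of variation at most
0.001, and fewer than two post-transient events give period exactly 0.

These fixtures emulate clean, noiseless, space-clamped membranes with
stationary parameters. Real recordings have channel noise, electrode
artifacts and adaptation; none of that is modeled, so green tests
establish correctness of the algorithms on the stated equations, not
robustness to experimental data.

# Degenerate inputs and numerical edge cases

* Zero total conductance makes V_qs undefined: `quasi_static_potential()`
  raises a degenerate-regime error; a reduced regime with neither
  conductance nor current is refused at construction.
* Non-first-order gating kinetics (rate depending on the gating variable
  itself) make the timescale analysis inapplicable and are rejected with a
  named error.
* Guard functions evaluating non-finite raise an event-evaluation error
  rather than silently skipping the step.
* `gamma <= 1` is a parameter error everywhere it appears.
* Step-size underflow (below ~1e-14 of the span) raises a stiffness error;
  hitting the step or transition caps flags the result as truncated rather
  than erroring, because self-transition models legitimately cycle forever.

# File formats

Models, hybrid models, epoch reports and templates serialize to
line-oriented structured text with canonical ordering and 17-digit number
formatting, so load → save → load is bit-exact. Trajectories and point sets
write CSV (independent variable first, header `t`) with labels in a JSON
sidecar; external inputs are two-column CSV. A thin command-line wrapper
(`inst/scripts/hybridsys-cli.R`) exposes `simulate`, `reduce`, `compare`
and `fixtures` over these files.
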