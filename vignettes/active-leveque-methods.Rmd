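---
title: "Methods: bacterial adhesion in shear flow, from agents to the active Lévêque law"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bacterial adhesion in shear flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **activeLeveque**, the
assumptions behind it, the numerical choices made where the design was
genuinely open, and what the test suite's reduced-scale reproductions do and
do not establish. It states no empirical result that the tests and
`scripts/acceptance.R` do not themselves compute.

## 1. Model and assumptions

We consider a dilute suspension of spheroidal swimmers in the half-plane
above a flat, perfectly absorbing surface, carried by a linear shear flow
`u = γ̇ y x̂`. Each swimmer carries a position and an in-plane orientation
angle θ and obeys the overdamped Langevin dynamics

* position: advection by the local flow plus self-propulsion at fixed speed
  `Vs` along `(cos θ, sin θ)`;
* orientation: the Jeffery drift of a spheroid in shear — in shear-rate
  units `ω(θ) = ½(β cos 2θ − 1)`, always clockwise, slowest near flow
  alignment — plus rotational diffusion with coefficient `Dr`.

Assumptions inherited from this setup, all of which bound the scope of the
package: the suspension is dilute (no steric or hydrodynamic cell–cell
interactions), the flow is not modified by the swimmers, there is no
hydrodynamic or biochemical cell–surface interaction, adhesion is perfect
and irreversible on first wall contact (`ρ = 0` at the wall), motion is
restricted to the flow plane, and thermal translational diffusion is
neglected — for the built-in species it is three orders of magnitude below
the activity-driven diffusivity (≈0.2 vs ≈240 µm²/s for E. coli). A
`thermal_diffusivity` field exists for users who need it; it is simply
added to the effective diffusivity. Run-and-tumble reorientation is folded
into `Dr` by substituting the tumble rate, valid for dilute, force-free
cells.

Two dimensionless groups govern everything: the relative swimming speed
`vs = Vs/(γ̇L)` (assumed small: flow faster than swimming) and the
rotational Péclet number `Per = γ̇/Dr`. The flow lengthscale `L` is the
user's choice of reference (pipe radius, viscous-sublayer height); the
default in the sweep pipeline is 750 µm.

## 2. The continuum hierarchy and its closures

Coarse-graining the agent dynamics yields transport equations for the
density ρ, polar order `n` (mean swimming direction) and nematic order `Q`
(alignment). The hierarchy is closed with the standard 2D symmetric
closures for the third- and fourth-order orientation tensors
(`closure_tensors()`). Far from the wall the steady state is `n = 0` (equal
numbers face up- and downstream) with

    Q = βPer/(4(16+Per²)) · [[Per, 4], [4, −Per]],

implemented in `far_field_Q()`. `moment_source_residual()` evaluates the
closed moment sources directly; the test suite verifies that this far-field
state annihilates them (to machine precision — the balance turns out to be
exact for the closed system, a stronger property than the leading-order
construction requires).

One caveat surfaced by the cross-check with the exact stationary
orientation distribution (Section 3): the closure's accuracy envelope. We warn —
never error — outside `Per ≤ 1` for `β > 0.5`, `Per ≤ 10` for
`0 < β ≤ 0.5`, and `Per ≤ 100` for spheres (`closure_validity()`).

## 3. The steady orientation distribution

The inlet orientations of the simulator are drawn from the stationary
distribution of the orientation SDE, i.e. the periodic Fokker–Planck
balance `∂θ(ω p) = Per⁻¹ ∂²θ p` with a nonzero constant probability flux
(the drift has nonzero mean — orientations circulate). We solve it by
Fourier spectral collocation: dense trigonometric differentiation matrices
on an even uniform grid, the singular stationary system augmented with the
unit-mass quadrature row, solved by least squares. Spectral accuracy makes
512 nodes ample (the suite checks max-norm convergence under refinement and
a residual below 1e-8; the solver errors, naming the residual, if that
tolerance is missed).

The test suite validates the solver against an independent closed form: the
constant-flux quadrature solution `p(θ) ∝ e^{U(θ)} ∫_θ^{θ+2π} e^{−U}` with
`U = Per(β sin 2θ/4 − θ/2)`, evaluated by cumulative trapezoid. A detail
worth recording: at moderate shear (`Per = 1`, `β = 0.88`) the density mode
sits *between* the flow and extensional axes (θ ≈ 0.67 mod π), not on the
flow axis; flow alignment is nevertheless real in the nematic sense
(`⟨cos 2θ⟩ > 0`), and the mode reaches the flow axis at large `Per`. Tests
assert the moment statement, not a mode position, at moderate shear.

Sampling is by inverse transform on the cumulative trapezoidal integral of
the tabulated density — monotone, fast, and identical (to interpolation
order) between the R and C++ code paths.

## 4. The active Lévêque boundary layer

Near an absorbing wall, adhesion depletes the density in a layer of
thickness `ε ỹ ~ (x/Peeff)^{1/3}`. Balancing streamwise advection against
wall-normal swimming down the density gradient — the gradient induces a
small polar order, `boundary_layer_orientation()` — produces a classic
Lévêque problem with an effective Péclet number

    Peeff = (16+Per²)(16+(4−β²)Per²) / [4 Per vs² (32+(2−β)(1−β)Per²)],

(`effective_peclet()`), whose dimensional counterpart `Deff`
(`effective_diffusivity()`) satisfies `Deff = γ̇L²/Peeff` exactly — an
identity the tests verify over a parameter grid, along with the algebraic
link between the orientation coefficient and `1/(ε³Peeff)`.

The similarity solution for the density is a regularised lower incomplete
gamma function, `ρ = P(1/3, Peeff y³/9x)`, evaluated through `pgamma` for
numerical stability (`density_field()`). Its wall flux gives the local
adhesion law `J(x) = 3^{1/3}/(Γ(1/3) Peeff^{2/3} x^{1/3})` with the classic
prefactor 0.538. Tests confirm the solution satisfies the layer PDE at
O(h²) under central differences and that the one-sided wall flux reproduces
the closed form to 1e-6.

**Critical shear.** The dimensional net rate ∝ `Deff^{2/3} γ̇^{1/3}` rises
as `γ̇^{1/3}` and falls as `γ̇⁻¹`, so it has a single interior maximum.
`critical_shear()` maximises the log-objective over log shear by Brent's
bracketed method on `[10⁻³Dr, 10³Dr]` (derivative-free; the objective is
unimodal; an edge hit raises an error). For spheres the stationarity
condition solves in closed form to `γ̇crit = 2Dr/√3 ≈ 1.155 Dr`, which the
tests cross-check against brute-force grid maximisation; for the built-in
elongated species the maximiser lands at 1.07 s⁻¹ (E. coli) and 0.0386 s⁻¹
(P. aeruginosa), i.e. 1.1 and 0.039 at the two-significant-figure reporting
convention used for these quantities.

**Collapse.** Multiplying the net rate by
`S = (16+(4−β²)Per²)^{2/3} / [vs^{4/3}(32+(2−β)(1−β)Per²)^{2/3}]` cancels
all shape and speed dependence of the theory, leaving
`J̄(Per, l) ∝ l^{2/3} (4Per/(16+Per²))^{2/3}`, maximal at `Per = 4`
(`collapse_curve()`). This is what lets simulations of different species be
compared on one axis.

## 5. Validity-regime classification

The asymptotics require: swimming slower than the flow; a depletion layer
thicker than a cell body; reorientation not fully shear-dominated; and
swimming fast enough to be the leading near-wall transport mechanism.
`classify_regime()` encodes these as regions A–D, checked in that fixed
precedence, against a single reference small scale `ε_body` — the
dimensionless bacterium body length, default 5×10⁻⁴ (a 5 µm cell in a 1 cm
flow), configurable:

* A: `vs ≥ 1`; B: `Peeff^{−1/3} ≤ ε_body`; C: `Per ≥ 1/ε_body`;
  D: `vs ≤ ε_body`; otherwise VALID.

Two genuinely open choices, resolved as follows. First, the layer thickness
entering B is evaluated at unit downstream position (`Peeff^{−1/3}`), the
natural O(1) station; any fixed station rescales the B boundary by an O(1)
factor. Second, all thresholds compare against the *constant* body scale —
using the dynamic layer thickness as the C/D threshold instead would
classify the package's own central demonstration point (`Per = 1`,
`vs = 0.01`) and the catheter scenarios as invalid, which is inconsistent
with the demonstrated theory–simulation agreement there. Under this
classifier all catheter scenario markers are VALID and half of all
species × scenario shear-range endpoints are; the rest (high-shear
intestine, river, artery) land in B or D, where the closed form still
serves as an upper bound rather than an estimate.

## 6. The agent-based simulator as synthetic-data generator

The simulator is the package's data generator: its defaults are the study
conditions, not tuning knobs. Swimmers enter at `x = 0` each timestep with
heights drawn from the flux-weighted inlet law `p(y) = 2y/H²` (a uniform
upstream suspension carried in by shear) and orientations from the Section 3
distribution at the run's own `(β, Per)`; a uniform-inlet option exists for
sensitivity checks. Integration is Euler–Maruyama at `δt = 10⁻²`; the wall
is absorbing with the crossing position and time linearly interpolated
within the step (sub-step accuracy removes a grid artifact from the event
histogram at negligible cost); crossing positions are clamped to `[0, l]`
so the rare upstream-swimming corner crossing stays on the surface.
Swimmers leaving at `x = l` are removed; the top boundary `y = H` reflects
specularly (position and orientation) by default — the physically neutral
choice for a boundary meant to be far away; a periodic option exists. The
configuration validator warns if `H` is within three layer thicknesses of
the wall. Net rates are estimated on whole measurement windows after a
burn-in; the SD across windows is the quoted uncertainty (windows of
decoupled agents are independent replicates). The continuum-equivalent
inlet density is computed from the protocol itself,
`ρ∞ = 2 n_inject/(δt H²)`, the exact flux balance of the injection law.

Determinism: one root-seeded R RNG stream drives everything in a fixed,
documented draw order (inlet heights, inlet angles, then one normal per
live agent in storage order). The compiled engine and the pure-R reference
engine consume draws identically, and the suite asserts their runs are
*equal* — events, histograms, bookkeeping — which is a stronger check than
statistical agreement. Bookkeeping (`injected = adhered + exited + live`)
is asserted exactly on every run.

Full-protocol presets (`"adhesion"`: H = 1.5, l = 3, 100 per step,
t ∈ [0, 10300], burn-in 300, four windows of 2500; `"density"`: H = 0.8,
t ≤ 1000, burn-in 300) correspond to ~10⁸ and ~10⁷ simulated swimmers and
are intended for users with hours of compute. The shipped reduced presets
scale injection and duration down ~25–100× (4/step, t ≤ 550 for adhesion;
10/step, t ≤ 400, every-5th-step recording for density) so that a run
takes seconds to tens of seconds on one CPU; these are the problem sizes
the test suite uses, chosen so that window event counts (hundreds at the
demonstration point) give few-percent Monte Carlo errors.

What the generator emulates: transport, shear alignment, rotational
diffusion, absorbing-wall depletion, and the full measurement protocol.
What it does not: three-dimensional motion, imperfect or reversible
adhesion, hydrodynamic wall interactions, cell–cell interactions, tumbling
as discrete events, thermal noise, and non-shear flow profiles. Passing
reduced-scale tests therefore demonstrates internal consistency of the two
levels under the stated model, not agreement with any particular
experiment.

## 7. Numerical tolerances and degenerate inputs

* Spectral FP solve: residual < 1e-8 in max norm or error; density
  renormalised to unit mass after the solve.
* `pgamma`/`qgamma` carry the incomplete-gamma evaluations (lower,
  regularised); no series are hand-rolled.
* `optimize` tolerance 1e-10 on log-shear for `critical_shear`; bracket
  `[10⁻³Dr, 10³Dr]`, edge detection errors out.
* Degenerate inputs: `Vs = 0` is legal for the simulator (passive tracers;
  zero adhesion is asserted in tests) but `effective_peclet` raises on
  `vs = 0` or `Per = 0`, naming the quiescent divergence. `x ≤ 0` is a
  domain error for the similarity solution and rate laws. Configs that do
  not divide into whole measurement windows are config errors.
* Window SD with a single window is reported as 0 and flagged
  (`sd_defined = FALSE`) rather than `NA`, so downstream arithmetic stays
  finite.

## 8. Known limitations

* The similarity solution omits the inlet-corner boundary layer near
  `x = y = 0`. At reduced scale this shows as a few-percent deficit of
  simulated net adhesion against theory, concentrated at small `x`;
  density comparisons therefore exclude a configurable inlet zone
  (default `x < 0.5`).
* Near-wall streamlines equilibrate on the transit timescale `l/y`, so
  time-averaged densities in the slowest lane converge only for runs much
  longer than `l/y_bin`; the passive-suspension fixed-point test restricts
  itself accordingly.
* At `Per ≫ 1` for elongated swimmers the closure envelope is exceeded and
  simulated rates depart from the closed form (visibly in the high-shear
  tail of the sweep); the theory there is an upper-bound statement, and
  the warnings say so.
* Euler–Maruyama is weak order 1; halving `δt` moves windowed rates by
  less than their Monte Carlo spread at the shipped settings, which is the
  accuracy the protocol needs and the suite checks.
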