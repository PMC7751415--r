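---
title: "Methods: transport modeling and current optimization in magsteer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transport modeling and current optimization in magsteer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magsteer)
```

magsteer simulates and optimally controls the concentration of
superparamagnetic nanoparticles in a two-dimensional fluid sample
surrounded by electromagnets, the core modeling problem of magnetic drug
targeting (MDT). This vignette explains the model, its assumptions, the
numerical choices, and what the packaged synthetic scenarios do and do
not establish.

## Physical model

**Magnetics.** Each electromagnet is an infinitely thin circular loop
with $N$ turns. Its field $\mathbf H$ and spatial Jacobian
$\partial \mathbf H/\partial \mathbf x$ are evaluated from the classical
semi-analytic loop expressions in cylindrical coordinates, written in
terms of the complete elliptic integrals $K(m)$ and $E(m)$ in the
modulus-squared convention $m = k^2$ (this convention matters:
implementations of $K$ and $E$ differ). The Jacobian is analytic, using
$\mathrm dK/\mathrm dm = -K/(2m) - E/(2m(m-1))$ and
$\mathrm dE/\mathrm dm = (E-K)/(2m)$ plus the cylindrical-to-cartesian
transform. Within $10^{-9}$ m of the symmetry axis the cylindrical form
is 0/0 and the closed-form on-axis limit is used instead (with
$\partial H_\rho/\partial\rho = H_\rho/\rho = -\tfrac12\,
\partial H_z/\partial z$ from axisymmetry and $\nabla\cdot\mathbf H = 0$).
Points on the filament itself are rejected. Superposition makes the
total field linear in the current vector $\mathbf u$.

**Particle moment.** A single-domain particle of core volume
$V = \pi d^3/6$ carries the equilibrium Langevin magnetization
$M(H) = M_s\,L(\mu_0 M_s V H / k_B T)$ with $L(x) = \coth x - 1/x$
(Taylor branch $x/3 - x^3/45$ below $|x| < 10^{-4}$ to avoid
cancellation). With the moment aligned to the field,
$\mathbf m = g(H)\mathbf H$ where $g(H) = V M(H)/H$ and
$g(0) = \mu_0 M_s^2 V^2 / 3 k_B T$ is the analytic limit. The magnetic
charge model gives the force
$$\mathbf F_m = (\mathbf m\cdot\nabla)\mathbf B
 = \mu_0\, g(H)\, \Big[\tfrac{\partial \mathbf H}{\partial \mathbf x}\Big]^{\!\top}\mathbf H
 = \tfrac{\mu_0}{2}\, g(H)\, \nabla(H^2),$$
directed toward higher field magnitude (the two forms coincide because
the source-free coil field is curl-free, so the Jacobian is symmetric).
For the packaged 400 nm magnetite particles the Langevin argument is
huge at any practical field, so the moment is effectively saturated at
$V M_s$; the full $g(H)$ is kept because it is what makes the force
nonlinear in the currents at low excitation.

**Drift.** Inertia, lift, gravity, buoyancy, the random Brownian force
and inter-particle forces are neglected relative to Stokes drag; the
particle velocity responds instantaneously:
$\mathbf v = \zeta^{-1}\mathbf F_m + \mathbf v_f$ with
$\zeta = 6\pi\eta R_p$. Brownian motion enters only through the
diffusion coefficient of the concentration model.

**Transport.** Ensembles are described by the dimensionless voxel
concentration field $c$ obeying the advection–diffusion equation
$\partial c/\partial t = \nabla\cdot(D\nabla c) - \nabla\cdot(\mathbf v c)$
with the no-flux wall condition
$\mathbf n\cdot(D\nabla c - \mathbf v c) = 0$: no particle crosses the
dish boundary and total mass is exactly conserved.

## Discretization

The square sample is divided into $n_x \times n_y$ square voxels and the
PDE becomes the linear state-space system $\dot{\mathbf c} = A(\mathbf u)
\mathbf c$. The operator is assembled in finite-volume (flux) form: for
each interior face, flux $= -D(c_R - c_L)/\Delta x + v_\text{face}(c_L +
c_R)/2$, entering the two adjacent balances with opposite signs;
boundary faces carry zero flux. Every column of $A$ therefore sums to
zero — discrete mass conservation by telescoping — and in the interior
the scheme coincides with second-order central differences. Choices
worth knowing:

- **Face velocities.** The magnetic drift is evaluated directly at face
  midpoints (not averaged from voxel centers); the background flow is
  sampled there too. Per-coil unit-current fields at all faces are
  precomputed once (`make_field_cache()`), so only the nonlinear force
  evaluation remains per current vector.
- **Central vs upwind.** The central scheme is the default. In strongly
  advection-dominated runs (the physical diffusion here is tiny,
  $D \approx 3.7\times10^{-13}$ m²/s by Stokes–Einstein) it produces
  small oscillations and slightly negative concentrations. Values are
  deliberately not clipped — clipping would break mass conservation — and
  a first-order upwind flux is available via `scheme = "upwind"` where
  monotonicity matters more than accuracy.
- **Time integration.** Classical RK4 with a fixed sub-step per
  constant-current segment, $\Delta t = 0.4\,\min(\Delta x^2/4D,\;
  \Delta x/\max|v|)$, a conservative bound inside the RK4 stability
  region for this operator. A norm-growth guard aborts with a step-size
  diagnostic if the bound is defeated (e.g. by a user-supplied `safety`).
  RK4 preserves linear invariants of column-sum-zero operators, so mass
  is conserved to rounding over the full $10^4$ s horizon.
- **Grid.** The state dimension follows the results-scale setup,
  $31\times31 = 961$ voxels over the 8 cm dish; a $30\times30$ grid
  ($\Delta x \approx 2.7$ mm) is equally supported through `grid_2d()`.

## Model order reduction

The snapshot matrix $X$ collects the 101 uniformly spaced states of a
full-order simulation (uniform selection is the simplest defensible
rule; optimal snapshot placement is an open problem in the POD
literature). Its SVD $X = U\Sigma V^\top$ yields the POD basis; the
retained rank $\ell$ is the smallest whose energy fraction
$\varepsilon(\ell) = \sum_{i\le\ell}\sigma_i^2 / \sum_i \sigma_i^2$
reaches the threshold $\varepsilon^\ast$ (default 0.98), or a fixed rank
can be forced. Snapshots are used raw — no mean-centering — matching the
formulation in which the reduced state is $\tilde{\mathbf x} =
U_\ell^\top \mathbf x$ and the reduced dynamics are
$\dot{\tilde{\mathbf x}} = U_\ell^\top A(\mathbf u) U_\ell
\tilde{\mathbf x}$ with reduced cost $\tilde Q = U_\ell^\top Q U_\ell$.
Modes are sign-normalized (largest-magnitude entry positive) so repeated
runs give bit-identical bases.

## Optimal control

The running cost $x^\top Q x + u^\top R u$ uses a diagonal $Q$ with $-1$
at the target voxel (its concentration is maximized) and zero elsewhere;
$R = 0$ and the final-time weight $\gamma = 0$ in the packaged
scenarios, with the horizon fixed at $t_f = 10^4$ s and currents bounded
by $|u| \le 13$ A. The currents are zero-order hold over $n_t$ equal
segments ($n_t = 4$, i.e. 2500 s levels, at the nominal scale).

**Transcription.** Direct multiple shooting with one shooting node per
current segment: decision variables are the $n_u \times n_t$ current
levels and the reduced states at the $n_t - 1$ interior nodes; each
segment is integrated by RK4 in the reduced space; equality constraints
enforce node continuity; the current bounds are a box. The cost integral
uses trapezoidal quadrature on 25 sub-intervals per segment.

**NLP.** No dedicated constrained-NLP library is required: the equality
constraints are handled by an augmented-Lagrangian outer loop (default 5
multiplier updates, penalty growth 10 when the violation stalls,
matching tolerance $10^{-5}$ relative to the initial reduced-state norm)
around `stats::optim`'s L-BFGS-B, which natively enforces the box.
Gradients are forward finite differences with step
$10^{-3}\,u_\text{max}$ on the currents and $10^{-6}$ of the state scale
on the nodes. The objective is internally normalized to $O(1)$ so the
inner solver's descent and gradient tolerances behave identically at any
physical cost magnitude. After every outer iteration the candidate
currents are re-simulated from the initial state and the best
re-simulated cost is kept, so the returned schedule is always feasible
and never worse than the guess. Optional per-voxel concentration bounds
would apply to the lifted state at shooting nodes only; they are
inactive by default.

**Initial guess.** A heuristic encodes the a-priori knowledge that
particles are pulled toward an energized coil: the coil(s) best aligned
with the centroid-to-target direction are activated at half the current
bound (for a holding problem, the coil opposing the flow; with no flow,
a zero guess). Ties in the alignment activate all tied coils.

**Alternating loop.** A POD basis built from guess snapshots cannot
"see" states far from the guess trajectory, so a single reduced
optimization is myopic. The outer loop alternates: simulate full-order
snapshots under the current best schedule, rebuild the basis, rerun the
DMS warm-started from the previous currents and the restriction of the
previous full-order node states under the *new* basis, re-simulate. The
reported best-so-far cost is monotone by construction, and in practice
the basis enriches substantially between the first iterations — the
reduced cost of a stale basis can differ from the full-order cost by
tens of percent, which is precisely the discrepancy the alternation
removes (it is reported per iteration in the solution history).

## The reference setup and its calibration

The coil geometry is the one genuinely open design choice: no radius,
turn count or standoff is available to reproduce, yet all absolute force
magnitudes hinge on it. The package's reference ring places four coils
of radius 0.08 m on the $\pm x$/$\pm y$ axes, 0.08 m from the sample
center, coplanar with the dish (field components out of the plane vanish
by symmetry for in-plane sources and points, which is why the model is
2-D). The turn count, 6000, is a calibration: with the 400 nm, $M_s =
4.78\times10^5$ A/m particles in a blood-viscosity fluid
($\eta = 3\times10^{-3}$ Pa·s), a sustained 13 A excitation then drifts
the blob at roughly 2–5 µm/s across the dish, i.e. a few centimeters
over the $10^4$ s horizon — the travel scale an in-vitro steering setup
of this size must deliver for the steering and holding scenarios to be
feasible at all. Equivalently, ~78 kA-turns of magnetomotive force,
which in a laboratory magnet would come from fewer turns around an iron
core; the filament model absorbs it into $N$.

Remaining defaults, with rationale:

| parameter | default | why |
|---|---|---|
| temperature $T$ | 300 K | room-temperature in-vitro dish |
| hydrodynamic radius $R_p$ | 200 nm | bare core radius (no coating modeled) |
| diffusion $D$ | Stokes–Einstein $k_BT/6\pi\eta R_p$ | no measured value; overridable |
| blob center | $(0, -3\ \text{cm})$ | particles pre-collected at a wall by one magnet |
| blob width $\sigma$ | 5 mm | a concentrated spot ~2 cm across on the 8 cm dish |
| steering target | $(0\ \text{cm}, 1\ \text{cm})$ | printed target of the first steering case |
| guess level | $0.5\,u_\text{max}$ | mid-range a-priori excitation |
| flows | $(0,3)$ and $(-3,3)$ µm/s | the holding/moving study conditions |

## What the synthetic scenarios do and do not show

The generator emulates a clean in-vitro petri-dish experiment: uniform
isotropic diffusion, a uniform (or user-supplied) background flow,
impermeable walls, non-interacting particles, perfectly known initial
distribution. It deliberately omits what an in-vivo setting would add:
vasculature and wall/membrane effects on drag, shear-induced diffusion
from red blood cells, particle chaining and agglomeration, imaging noise
in the initial state, and coil electrical dynamics (voltage–current lag,
mutual inductance). Passing tests therefore establish the correctness of
the numerics and the soundness of the optimization on this idealized
physics — not targeting performance in tissue. The feed-forward controls
are also open-loop: modeling error is not corrected by measurements.

## Problem sizes and determinism

The packaged scenarios ship at two scales: the nominal one
($31\times31$, $n_t = 4$, $t_f = 10^4$ s) and a coarse one
(`scale = "ci"`: $15\times15$, $n_t = 2$, $t_f = 5000$ s) that the test
suite uses for every optimization end-to-end so the whole suite runs in
a few minutes; the physics and code paths are identical, only the voxel
count and horizon shrink. The entire pipeline is deterministic — SVD sign
convention fixed, no stochastic multi-start — so rerunning a scenario
reproduces its outputs bit for bit; the `seed` configuration field
exists for hygiene and for any future stochastic extension.

## Known limitations

- The central scheme's small negative undershoots (order $10^{-3}$ of
  the peak) are visible in advection-dominated runs; switch to
  `"upwind"` if positivity matters.
- The finite-difference gradients make each DMS iteration cost one
  reduced simulation per decision variable; fine for $n_u n_t +
  \ell(n_t-1) \lesssim 100$ variables, not for large $n_t$.
- The POD basis is trajectory-dependent; a schedule optimized under one
  basis is only guaranteed good for the full model after re-simulation,
  which is why the solver re-simulates every candidate.
- Free final time and terminal constraints are formulated away
  ($\gamma = 0$, no terminal cost); only fixed-horizon problems are
  solved.
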