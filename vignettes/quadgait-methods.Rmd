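---
title: "Work-minimizing quadrupedal walking: model, transcription and solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Work-minimizing quadrupedal walking: model, transcription and solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(quadgait)
```

## The scientific question

Cursorial quadrupeds walk with a highly stereotyped four-beat ("singlefoot")
pattern: each leg touches down individually, support alternates between two
and three limbs, duty factors sit near 0.5, and the vertical ground reaction
force (GRF) of each limb shows a characteristic double hump. `quadgait` asks
which notion of mechanical work, if minimized, *predicts* that pattern. Three
competing per-stride cost functionals are implemented:

* **Net COM Work (NCW)** — the positive part of net GRF power on the centre
  of mass, `NCW = ∫ [F_net · v_com]⁺ dt`, equivalently the positive
  fluctuations of COM kinetic plus gravitational potential energy. Low NCW is
  the classical signature of "pendular" walking.
* **Individual Limbs COM Work (ILCW)** — `Σ_i ∫ [F_i · v_com]⁺ dt`, which
  retains the simultaneous positive and negative work of different limbs that
  cancels inside NCW.
* **Limb Extension Work (LEW)** — `Σ_i ∫ [F_i · l̇_i]⁺ dt`, the positive
  mechanical work of telescoping each limb strut, which also prices the work
  of pitching the elongate body.

Net System Work (NSW, positive fluctuations of the total mechanical energy
including trunk rotation) and the Cavagna percent recovery,
`100 (W⁺_Ek + W⁺_Ep − W⁺_{Ek+Ep}) / (W⁺_Ek + W⁺_Ep)`, are computed as
descriptive statistics. Recovery uses COM energies only — no rotational term
— because it is paired conceptually with NCW; whether a rotational correction
belongs in the reported recovery of pitching solutions is ambiguous, and the
COM-only convention is adopted throughout.

## The model

The body is a planar rigid trunk of mass `m` with four massless telescoping
limb actuators: hindlimbs at the hips, forelimbs at the shoulders, separated
by the glenoacetabular distance (GAD). Each limb pushes (never pulls) along
the axis from its fixed footfall to its attachment, and force is allowed only
while the limb is no longer than its maximum length — contact is therefore a
complementarity condition, not a prescribed sequence. Sliding friction is
infinite (feet do not slip), and the ground is rigid.

Internally `m = g = l_H_max = 1`: forces are in body weights, lengths in
hindlimb lengths, works in `m g l_H`, and time in `sqrt(l_H/g)`. The shipped
Warmblood horse preset has `l_H_max = 1.38` m, forelimb length and GAD equal
to the hindlimb length (an alternate preset uses the empirical 1.14 m and
1.63 m), the COM at 0.57 GAD from the hips, Murphy number
`4 I / (m GAD²) = 0.82`, walking speed `U' = 0.43` and stride length
`D' = 1.34`; the stride period is derived, `T' = D'/U'`. The point-mass
variant removes the rotational state (the trunk stays level and forces
produce no moments) but keeps the limb-length constraint geometry, with
attachments at the hip/shoulder offsets of the level trunk.

## Transcription

One gait is a half cycle of a symmetric stride, discretized by direct
collocation (Hermite–Simpson by default, trapezoidal optionally) on a uniform
grid over `t' ∈ [0, 0.5]`. States are the trunk pose and velocities, the five
footfall forces and the running integral of the leading fore force; controls
are the force rates; slack pairs split the signed work integrand
(`s⁺ − s⁻ = p`, `s± ≥ 0`), making the objective linear and smooth. Decision
parameters are the footfall positions of the left limbs; under gait symmetry
right-limb trajectories repeat the left ones half a period later, translated
by half a stride. Within the half-cycle window the right limbs are always
*finishing* stances begun half a stride earlier, so their contacts sit `D/2`
behind the corresponding left touchdowns. The left fore acts through a
trailing and a leading contact separated by a full stride, with an exclusion
complementarity (`F_LFt · ∫F_LFl = 0`) preventing both being loaded at once;
an additional guard (`F_LFt · Ḟ_LFl = 0`), used for the NCW objective, rules
out brief five-contact intervals between collocation points.

Boundary conditions: the horizontal COM position runs from 0 to `D/2`,
kinematics are periodic over the half cycle, left forces at `t' = 0` equal
the matching right forces at `t' = 0.5`, and the reference-limb conventions
(`F_LH(0) = 0`, `F_RH(0.5) = 0`, `F_LFt(0.5) = 0`, `F_LFl(0) = 0`) pin the
phase. Hip and shoulder must stay above ground, pitch within ±π/2, forces
nonnegative.

The objective is the smoothed work metric plus a force-rate regularization
`c1 Σ_i ∫ (dF_i/dt')² dt'` with `c1 = 3e-5` (forces in body weights, time
normalized to the stride period) and relaxation penalties on the
complementarity products, increased tenfold per optimization round. Explicit
per-node relaxation variables are eliminated algebraically: a linear penalty
on a product of nonnegative factors is equivalent to the epsilon-variable
relaxation at its optimum, and the slack split is exact at the inner optimum
for any positive penalty weight.

## Solving the NLP

No large-scale NLP library is assumed. The solver is built from three
ingredients, all operating on an analytic merit gradient (hand-coded adjoint,
compiled in C++ and cross-checked against a pure-R reference):

1. an **augmented-Lagrangian** outer loop with L-BFGS-B inner solves for the
   bound constraints;
2. a **damped exact-Hessian Newton step** on the merit after each inner
   solve — the Hessian is obtained by forward-differencing the analytic
   gradient, and absolute Levenberg damping preserves the tiny curvature of
   the tangent directions along the constraint manifold. These second-order
   steps are what traverse the long, ill-conditioned valleys of the
   collocation problem (first-order methods stall there with projected
   gradients far from zero);
3. a **Gauss–Newton feasibility polish**: the exact constraint Jacobian is
   assembled one adjoint evaluation per row, and minimum-norm Newton
   corrections drive collocation defects and boundary residuals to near
   round-off without leaving the solution. Violated force-length rows are
   repaired by correcting the limb geometry when the limb is marginally
   overextended, or by zeroing the force when the contact is out of reach.

The staged protocol follows the multi-start recipe: every restart is screened
through a first round with loose relaxation penalties and an iteration cap,
downsampling to 16 evenly spaced nodes, and further rounds with tenfold
penalty increases; mesh refinement follows success rather than preceding it,
so the lowest-objective restarts (`finish_top`, default 3) then receive a
deep finish — heavy outer iterations at 16 nodes, a midpoint mesh-refinement
round (16 → 31 nodes) at a further tenfold penalty, and a final polish. A
restart is *accepted* when the equality residuals (including the symmetry
boundary conditions) are below 1e-6, all complementarity products at the
nodes are below 1e-4, and the optimized work metric changes by less than
`mesh_tol` when the solution is re-collocated on a doubled mesh. The accepted
restart with the smallest total objective (work + force-rate penalty +
relaxation penalties) is the *pseudoglobal* optimum.

`mesh_tol` defaults to 0.01 m g l_H. With a uniform 16 → 31 node refinement
and a first-order-plus-Newton solver, the reproducible work resolution is of
order 1e-3–1e-2; demanding 1e-4 would reject essentially every solve,
including ones whose works are stable under further refinement. The package
treats 0.01 — matching its
overall desk-scale work tolerance of ±15% — as the meaningful mesh
acceptance level.

## Initial guesses

`random_guess()` draws, per restart: trunk height near standing with a small
two-per-stride periodic fluctuation, linear horizontal progression, small
random pitch, stance-bump force profiles with random touchdown phases and
duty factors (the left hind, the reference limb, touches down within the
first half cycle; trailing fore and right-limb forces are tails of stances
begun half a stride earlier), amplitudes scaled so the mean total vertical
force is one body weight, and footfalls near the attachment position at
mid-stance. The distribution is this package's own design, chosen to cover
compliant (high-duty), vaulting (low-duty) and intermediate gaits; the
guess-generation method of the original study is not published in detail.

## What the defaults mean

| parameter | default | meaning |
|---|---|---|
| `n_nodes` | 16 | collocation nodes on the half cycle before refinement |
| `relaxation_w0` | 0.1 | first-round complementarity penalty weight |
| `c1` | 3e-5 | force-rate regularization (dimensionless) |
| `n_guesses` | 12 | desk-scale restarts used by the acceptance workflow (the original study used 250) |
| `comp_tol` | 1e-4 | complementarity residual accepted at nodes |
| `mesh_tol` | 0.01 | work change accepted under mesh refinement (m g l_H) |

A single staged solve takes tens of seconds on one CPU; a 10-restart campaign
for one objective takes a few minutes.

## Validation oracles

The conservative toy systems in `toy_system()`/`simulate_toy()` provide
closed-form checks of the energy accounting: a point pendulum and a bead on a
frictionless wire have 100% pendular recovery; a rod pivoted at its end
recovers `6/7` (COM share 3/4 of kinetic energy); a uniform sphere rolling in
a circular valley recovers `5/6` (translational share 5/7); and the passive
four-bar quadruped vaults with perfect recovery in the parallelogram
("walking trot") geometry but imperfect recovery with staggered feet, because
energy passes through rotational kinetic energy that COM accounting cannot
see. The work–energy theorem (total energy change equals integrated actuator
power) is verified on forward-integrated random force histories.

## What the synthetic conditions do and do not show

The generator and presets emulate the study conditions: a planar,
rigid-trunk, massless-legged horse walking at fixed speed and stride length.
Passing tests show that the optimization reproduces the energetic structure
of that idealization — they do not show that real horses minimize any of
these costs. Lateral dynamics (and hence the lateral- vs diagonal-sequence
distinction), limb mass and swing cost, muscle-level physiology, compliant
ground and slipping are all outside the model.

## Numerical choices and known limitations

* Works are reported by trapezoidal quadrature of the positive-part power on
  the trajectory grid, over a full stride obtained by mirroring the solved
  half cycle (works are exactly twice the half-cycle values by symmetry).
* The stance threshold for gait diagrams is 0.02 body weights; duty factors
  therefore include low-force tails of smooth force profiles.
* Hump counting smooths the limb GRF with a 3-point moving average and
  requires a trough at least 5% of the peak between local maxima.
* Percent recovery is a ratio of positive-part integrals; for near-flat NCW
  solutions both numerator and denominator are small and the reported
  recovery of such solutions is numerically delicate.
* The NCW objective is degenerate (many trajectories achieve NCW ≈ 0); the
  force-rate penalty is the effective tie-breaker, so the non-optimized
  metrics of an NCW solution (its ILCW, LEW, NSW) vary between near-optimal
  ties and are not sharply reproducible.
* The multi-start search is a pseudoglobal heuristic: with 10 desk-scale
  restarts it reliably recovers the qualitative optima (compliant high-duty
  for NCW, single-stance vaulting for ILCW, four-beat singlefoot with
  double-hump GRFs for LEW under distributed mass), while the non-optimized
  metrics of a selected solution can differ from any particular published
  local optimum. In this implementation the pseudoglobal LEW and ILCW
  solutions attain their objectives at values at or slightly below the
  originally reported ones, with less body pitching.

## Reproducing the study conditions

```{r, eval = FALSE}
hp <- horse_preset("distributed_mass")
spec <- transcription_spec(n_nodes = 16, c1 = hp$c1)
ms <- multistart(12, base_seed = 1, hp$body, hp$task, metric = "lew",
                 spec = spec, control = solver_control())
best <- ms$best
work_breakdown(best$trajectory, c1 = hp$c1)
gd <- gait_diagram(best$trajectory)
classify_gait(gd, best$trajectory)
```
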