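---
title: "Stiffness-scheduled lookup-table FES control: model, calibration and design choices"
author: "stiffarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stiffness-scheduled lookup-table FES control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffarm)
```

## The control problem

Functional electrical stimulation (FES) can restore reaching to people with
high cervical spinal cord injury, but any given arm configuration can be
produced by infinitely many stimulation patterns: antagonist muscles can
cocontract to a greater or lesser degree, and redundant muscles can share
work in different proportions. `stiffarm` implements a feedforward
lookup-table controller that resolves this redundancy by making **limb
stiffness an explicit commanded degree of freedom**.

Stiffness is defined here as the magnitude `S` (Nm) of balanced opposing
torques about a joint: at a held posture the net torque is zero because all
passive plus active flexion torques exactly balance all passive plus active
extension torques,

    S = Pf + Af = -(Pe + Ae).

For each joint this yields one flexion and one extension equation,

    S - Pf = sum_i Cf_i * Af_max_i
    -S - Pe = sum_i Ce_i * Ae_max_i,

where `Af_max_i` / `Ae_max_i` are the maximum active torques each muscle can
deliver at that configuration and `Cf_i`, `Ce_i` in `[0, 1]` are the
proportions of those maxima actually commanded. Stacking both equations for
both joints gives a linear system `x = A c` with four rows (shoulder
flexion, shoulder extension, elbow flexion, elbow extension) and one column
per stimulation channel; biarticular muscles occupy two rows of their
column, and at least half of `A` is structurally zero. The controller
solves this system for `c` with the least-squares **minimum-norm** solution
(an energy-efficient way to spread work over redundant muscles), clamps the
coefficients into `[0, 1]`, converts them to stimulation levels through each
channel's measured stimulation-to-torque curve, and stores the result in a
lookup table over (shoulder angle, elbow angle, stiffness). At run time a
desired posture and stiffness are simply looked up (with per-dimension
linear interpolation) every 50 ms.

## The synthetic plant

The package ships its own quasi-static musculoskeletal plant
(`make_default_arm()`): a planar two-link chain (0.33 m upper arm, 0.45 m
forearm-plus-hand) moving in the horizontal plane — no gravity, as if on a
frictionless tabletop — actuated by six muscles on six channels: anterior
and posterior deltoid (±40 Nm on the shoulder), brachialis and the lateral
triceps head (±30 Nm on the elbow), and two biarticular muscles, biceps
(+10 shoulder / +25 elbow) and the long triceps head (−10 / −25). The
workspace spans shoulder 15–85°, elbow 20–130°.

Torque of muscle *i* at joint *j* is
`peak_ij * FL_j(theta_j) * r_i(u) * capacity_i`:

* **Recruitment** `r_i(u)` is a logistic in normalized stimulation
  `u ∈ [0, 1]`, normalized so `r(0) = 0` and `r(1) = 1`, with threshold 0.1
  and saturation 0.9 by default.
* **Force–length scaling** `FL` is a Gaussian in the acted joint's angle
  (width 60°, floor 0.3). Its peak is offset 40° toward the side where the
  muscle is stretched — flexors peak below the joint's mid-range, extensors
  above. This was a deliberate design choice: if flexors and extensors
  shared one mid-range peak, their slopes would cancel at a balanced
  posture and cocontraction would add *no* net joint stiffness, defeating
  the premise that `S` is a stiffness. With the offset, the restoring
  stiffness at equilibrium grows in proportion to `S` (about 0.2 Nm/deg at
  `S` = 8 Nm), so a stiff command really does hold the posture harder.
* **Passive torques** are two one-sided exponentials per joint
  (amplitude 3 Nm at the range limit, 15° length constant): a non-negative
  flexion component resisting approach to the extension limit and a
  non-positive extension component resisting the flexion limit. At
  mid-range they cancel; the relaxed arm rests there.
* **Fatigue** multiplies a muscle's torque by
  `capacity = max(0, 1 - rate * t)`.

Because every muscle's torque at a joint depends only on that joint's angle,
torque superposes across channels and a channel's joint-torque *ratio* is
independent of stimulation — the benign regime for the plain solver. The
spillover arms (`make_spillover_arm("A")`, `"B"`) break exactly this
property: the biceps channel is replaced by one electrode driving two
hypothetical monoarticular flexors with different recruitment curves, so the
shoulder-to-elbow torque ratio drifts with current (scenario A) or even
reverses ordering (scenario B, early saturation of the first muscle).

Dynamics, used only for the reach demonstrations, are standard two-link
rigid-body equations (RK4, 1 ms step) with joint viscous damping
`2.5 + 0.5 * (total activation)` Nm·s/rad — damping grows with
cocontraction — and plausible segment inertias. The controller itself is
quasi-static and never consults these parameters.

## Calibration (the simulated exoskeleton)

`calibrate()` reproduces the clinical parameterization protocol on a
configuration grid (inclusive lower bound, floor upper bound; 15–85° ×
20–130° at 1/5/10/20° give 7881/345/96/24 nodes):

1. passive torques per joint, measured with the arm held stationary —
   either as the two one-sided components (`"component"` mode, the plant
   exposes them) or as a net torque attributed by sign (`"net"` mode; the
   protocol never dictates how a single net measurement should be split, so
   both readings are available and component mode is the default;
2. a stimulation sweep per channel, 0 → 1 in 201 even levels, truncated
   once no joint's torque changes by more than 0.01 Nm over three steps;
   passive torques are subtracted so curves are active-only;
3. signed maximum active torques per channel and joint — the `A`-matrix
   entries.

Measurements are exact by default; seeded Gaussian noise is available for
robustness studies. A channel is flagged as *spillover* when its
joint-torque ratio varies by more than 1% across the sweep.

**Numerical choice — curve inversion.** Converting a coefficient `c_i` into
stimulation inverts the tabulated sweep at torque `c_i * max_i`. We
interpolate the sweep with a monotone cubic (Hyman) spline and invert by
bisection, rather than piecewise-linearly: with 201 levels the spline tracks
a smooth recruitment curve to ~1e-8 of its range, so a standard and a
rebalanced table (which target different per-muscle torques) place the plant
at equilibria within ~3e-7 cm of each other at time zero. Piecewise-linear
inversion at a 101-level sweep leaves ~3e-3 Nm quantization and ~0.01 cm
discrepancies, which would mask the rebalancing-conservation property the
design relies on. Ties on flat stretches resolve toward lower stimulation
(less charge).

## The bounded minimum-norm solve and its limits

`solve_bounded_min_norm()` computes the SVD minimum-norm least-squares
solution (singular values below 1e-12 of the largest are discarded), then
repairs bound violations one at a time, largest first: a negative
coefficient means a muscle would have to push — its column is dropped; a
coefficient above one saturates — it is fixed at 1, its full torque moved to
the right-hand side. Columns strictly decrease, so termination is
guaranteed, and every returned coefficient lies in `[0, 1]`.

This one-directional procedure (it never un-clamps) matches a
box-constrained QP reference (`solve_box_qp()`, projected gradient plus a
Dykstra alternating-projection stage for the minimum-norm point of the
feasible polytope) on every system we draw whose row demands are within the
total capacity of their columns — 0 mismatches in 5000 random
physiologically-scaled systems. On grossly under-powered systems (primary
movers of a few Nm facing 13 Nm demands) it can terminate above the QP
optimum by up to ~10%; it is never *below* it. A dedicated test documents
this limitation. In the controller such nodes are flagged infeasible
anyway.

**Spillover iteration.** When a flagged electrode is present, the solve
alternates with a ratio update: invert the electrode's reference-joint curve
(the joint with the larger maximum) at the currently commanded torque,
read the other joint's torque at that stimulation, and replace the
non-reference `A` entry with that ratio times the reference maximum. The
loop stops when the coefficient vector changes by less than 0.001 (vector
norm by default; per-element available) or after 1000 iterations. Over all
3795 workspace-by-stiffness systems both spillover scenarios converge at
100%, median 3 (A) and 7 (B) iterations, and the curve-aware solution error
never increases across the iteration.

**Rebalancing.** Scaling a channel's column by `alpha ∈ (0, 1]` before
solving shifts work away from it. The bookkeeping matters: the resulting
coefficient is converted to stimulation by targeting
`c_i * alpha_i * max_i` on the *unscaled* curve, so at time zero a
rebalanced table commands different muscle shares but the identical net
torques, hence the identical posture. The effective coefficients
`c_i * alpha_i` can never have smaller norm than the true minimum-norm
solution, so rebalancing always costs some efficiency.

## Lookup tables

`build_initial_table()` solves every (configuration, stiffness) node;
`verify_table()` applies each node's stimulation to the plant and records
the achieved static equilibrium (damped Newton on the torque field,
residual < 1e-6 Nm, stability checked via the Jacobian eigenvalues);
`finalize_table()` re-keys the table by the achieved configurations, so
querying an achieved posture returns the node's stimulation exactly.
Queries interpolate linearly one dimension at a time — shoulder, then
elbow, then stiffness — matching the clinical protocol's simple scheme;
cubic alternatives gave similar results in the source studies, and the
linear choice is an upper bound on interpolation error. Because achieved
configurations form a slightly irregular grid, the final-table query
interpolates along the achieved coordinates per axis (index grid plus
offset); with noise-free calibration the two geometries coincide to
solver tolerance. Queries outside the hull extrapolate linearly and are
flagged; more than 10° outside they are refused.

## The studies and their problem sizes

* **Sampling resolution** (`resolution_experiment`): calibrate densely,
  rebuild from 20/10/5° subsets, interpolate back to 1° (7881 nodes), apply
  every node and measure fingertip error. Sampled nodes are exact by
  construction; at 20° and `S` = 8 Nm the workspace median is ~0.83 cm,
  with errors concentrated at the workspace edges where the passive
  exponentials curve fastest and some nodes extrapolate.
* **Spillover** (`spillover_experiment`): all 11 stiffness levels × 345
  configurations = 3795 systems per scenario, tolerance 0.001, cap 1000.
* **Fatigue** (`fatigue_experiment`): eleven scenarios mark one or two
  muscles at 0.5%/s capacity loss; fatigue-resistant tables scale the
  marked columns by 0.5 (the anticipated capacity after ~100 s). Errors
  are evaluated by holding all 3795 combinations at t = 0, 5, …, 100 s
  (the evaluation cadence is ours; holding is quasi-static so capacity
  depends on elapsed time only) and compared with two-sided Wilcoxon
  rank-sum tests at each time point, plus distribution-free median
  differences.
* **Reaching** (`center_out_experiment`): eight 14 cm radial targets from
  the workspace-center posture, minimum-jerk speed profile over 1.3 s at
  the 50 ms command cadence, followed by a 1.2 s hold. Stiffness is
  scheduled linearly in speed — `S = S_max − (S_max − S_min)·|v|/v_peak`,
  our stand-in for velocity-derived cocontraction scheduling: soft while
  moving fast, stiff at the endpoints; the policy is configurable. With
  visual feedback the commanded velocity is re-aimed from the simulated
  fingertip toward the target each loop, and during the hold the user
  keeps nudging the command by 10% of the remaining error per loop — a
  deliberately small gain: the arm settles in roughly 0.3–0.6 s, and
  larger per-loop corrections (≥0.2) interact with that lag and ring.
  Inverse kinematics uses the elbow-flexed branch throughout.

## What the synthetic plant does and does not show

The plant is smooth, noise-free, deterministic and perfectly stationary
between calibration and use; its recruitment curves are exactly logistic
and its spillover profiles smooth. Passing tests therefore demonstrate the
*analytical machinery* — equation assembly, bounded minimum-norm
distribution, spillover fixed-point, rebalancing bookkeeping,
interpolation — not robustness to measurement noise, electrode migration,
spasticity, day-to-day variation, or muscle dynamics (activation lags,
history-dependent fatigue), none of which are modelled. Noise modes exist
but default off.

Known limitations worth stating plainly:

* With the plain piecewise-constant-in-time capacity model, fatigue is
  independent of the stimulation actually applied.
* In the two "crossed" rebalancing scenarios (a flexor at one joint plus
  an extensor at the other), the fatigue-resistant table reduces drift at
  *both joints* yet can show a larger *fingertip*-error median than the
  standard table: the standard table's correlated opposite-sign joint
  drifts partially cancel through the two-link fingertip map. The
  stiffness-error ordering and the remaining nine scenarios behave as
  designed. This is a geometry effect of this plant, and the per-joint
  numbers make the mechanism visible.
* The bounded solver inherits the one-directional clamping described
  above; on infeasible nodes its residual is an upper bound on the
  constrained optimum.
* Quasi-static equilibria are found by local root-finding; at stimulation
  far outside the calibrated regime the torque field can pin against the
  extended joint limits, and such nodes are flagged rather than solved.

## A minimal session

```{r, eval = FALSE}
arm <- make_default_arm()
calib <- calibrate(arm, sampling_grid(step = 20, stiffness = 3:13))
tab <- build_initial_table(calib)
ver <- verify_table(tab, arm)
final <- finalize_table(tab, ver)
query_table(final, 47, 93, 8)$u          # stimulation for a posture
ev <- evaluate_table(
  interp_table_grid(tab, grid_points(15, 85, 1), grid_points(20, 130, 1)),
  arm)
median(ev$endpoint_error_cm[ev$S == 8])  # ~0.8 cm at S = 8
```
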