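# stiffarm

Stiffness-scheduled lookup-table control of functional electrical
stimulation (FES) for planar reaching, exercised end-to-end against a
self-contained synthetic two-joint, six-muscle arm.

## What problem this solves

FES controllers for paralyzed arms must decide how much to stimulate each
muscle to reach a posture — but any posture can be held with infinitely
many stimulation patterns, differing in how much antagonists cocontract and
how redundant muscles share work. `stiffarm` implements a calibration and
control pipeline that removes this ambiguity by commanding **limb stiffness
S** — the magnitude of balanced opposing flexion/extension torques (Nm)
about each joint — as an explicit degree of freedom alongside the joint
angles.

For a desired configuration and stiffness, the torque balance at each joint
gives one flexion and one extension equation,

```
 S - Pf = Σ_i Cf_i · Af_max_i        (flexion side)
-S - Pe = Σ_i Ce_i · Ae_max_i        (extension side)
```

(`Pf`, `Pe` passive torques; `Af_max_i`, `Ae_max_i` each muscle's measured
maximum active torque at that configuration). Stacked over both joints this
is a linear system **x = A c** whose bounded (`c ∈ [0,1]`) least-squares
minimum-norm solution distributes work efficiently across redundant and
biarticular muscles. Solved over a grid of configurations and stiffness
levels and pushed through each channel's measured stimulation-to-torque
curve, the solutions form a lookup table queried every 50 ms at run time.

The package covers, as tested code:

* a synthetic planar arm plant (passive elastic torques, sigmoidal
  recruitment, force–length scaling, biarticular coupling, electrode
  spillover variants, per-muscle fatigue) standing in for a clinical arm;
* the simulated exoskeleton calibration protocol (passive torques,
  stimulation sweeps, max active torques on a configuration grid);
* the bounded minimum-norm solver, an iterative fixed-point correction for
  current spillover (one electrode recruiting muscles with different lines
  of action), and work rebalancing for fatigue resistance;
* lookup-table construction, plant-in-the-loop verification, per-dimension
  linear interpolation and serialization (CSV + JSON);
* the in-silico studies: sampling-resolution sweep, whole-workspace
  spillover convergence (3795 systems per scenario), fatigue timecourses
  with Wilcoxon comparisons, and closed-loop center-out reaches driven by
  a simulated user with visual feedback.

## Worked example

```r
library(stiffarm)

arm   <- make_default_arm()
calib <- calibrate(arm, sampling_grid(step = 20, stiffness = 8))
tab   <- build_initial_table(calib, stiffness = 8)

# interpolate the 24-node table to the full 1-degree workspace and measure
# where the arm actually settles under each node's stimulation
dense <- interp_table_grid(tab, shoulder = grid_points(15, 85, 1),
                           elbow = grid_points(20, 130, 1))
ev <- evaluate_table(dense, arm)
median(ev$endpoint_error_cm)
#> [1] 0.8299338
```

0.83 cm is the median fingertip position error over all 7881 intended
postures at 8 Nm stiffness when the controller was calibrated at only 24
postures (20° spacing) — sparse clinical-scale calibration plus linear
interpolation keeps the median error under 1 cm. Errors are zero at
sampled nodes and largest near the workspace edges where passive torques
change fastest.

A single posture query returns the per-channel stimulation (anterior
deltoid, posterior deltoid, brachialis, lateral triceps, biceps, long
triceps):

```r
round(query_table(tab, 47, 93, 8)$u, 3)
#>    AD    PD    Br  TLat    Bi TLong
#> 0.301 0.332 0.348 0.270 0.351 0.298
```

Mid-workspace at moderate stiffness, all six channels sit near one third of
their range — balanced cocontraction holding 8 Nm of opposing torque on
each joint.

A command-line wrapper over the same functions lives in
`inst/scripts/stiffarm.R`
(`Rscript stiffarm.R <calibrate|build-table|resolution-sweep|spillover|fatigue|reach> --config cfg.yaml --out dir`).

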