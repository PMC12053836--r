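Package: stiffarm
Title: Stiffness-Scheduled Lookup-Table Control of Functional Electrical
    Stimulation for Planar Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates feedforward lookup-table controllers for
    functional electrical stimulation (FES) of a planar two-joint,
    six-muscle arm, with limb stiffness (the magnitude of balanced
    opposing flexion/extension torques about each joint) as an explicit
    degree of freedom.  Provides a synthetic musculoskeletal plant with
    sigmoidal recruitment and force-length scaling, a simulated
    exoskeleton calibration harness (passive torques,
    stimulation-to-torque sweeps, maximum active torques on a joint-angle
    grid), a bounded minimum-norm torque-distribution solver, a
    fixed-point iteration that accounts for current spillover across
    electrodes, fatigue-aware rebalancing of work across redundant
    muscles, lookup-table construction, verification and interpolation,
    and closed-loop quasi-static reach simulations with a simulated user.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
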