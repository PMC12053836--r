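#' @title Synthetic planar two-joint, six-muscle arm
#'
#' @description
#' The plant used throughout the package: a planar two-link chain (shoulder,
#' elbow) moving in the horizontal plane ("frictionless tabletop", so no
#' gravity), actuated by six muscles through stimulation electrodes.  Each
#' muscle maps normalized stimulation \code{u} in \code{[0, 1]} to activation
#' through a normalized sigmoidal recruitment curve, and produces joint torque
#' \code{peak * force_length(theta) * activation * capacity}.  Passive elastic
#' torques are modelled as two one-sided exponential components per joint: a
#' non-negative flexion component \code{Pf} that stiffens toward the extension
#' limit and a non-positive extension component \code{Pe} that stiffens toward
#' the flexion limit.  Torque signs follow the right-hand rule with flexion
#' positive.
#'
#' @details
#' Default geometry and strength: link lengths 0.33 m (shoulder to elbow) and
#' 0.45 m (elbow to fingertip); peak torques anterior deltoid +40, posterior
#' deltoid -40, brachialis +30, triceps lateral head -30, biceps (+10 shoulder,
#' +25 elbow), triceps long head (-10 shoulder, -25 elbow) Nm.  Force-length
#' scaling is Gaussian in the acted joint's angle (width 60 deg, floor 0.3)
#' with the peak offset 40 deg toward the stretched side of the muscle
#' (flexors peak below joint mid-range, extensors above), so cocontraction
#' raises net joint stiffness.  Angles are degrees at every interface.
#'
#' @name arm_model
NULL

JOINTS <- c("shoulder", "elbow")

# ---- recruitment and force-length primitives ---------------------------------

#' Normalized sigmoidal recruitment curve
#'
#' Logistic recruitment normalized so that activation is exactly 0 at u = 0 and
#' exactly 1 at u = 1, with the steep region between \code{threshold} and
#' \code{saturation}.
#'
#' @param u normalized stimulation in \code{[0, 1]}.
#' @param threshold,saturation recruitment threshold and saturation levels.
#' @return activation in \code{[0, 1]}, same length as \code{u}.
#' @export
recruitment_activation <- function(u, threshold = 0.1, saturation = 0.9) {
  m <- (threshold + saturation) / 2
  k <- 2 * log(19) / (saturation - threshold)
  s  <- stats::plogis(k * (u - m))
  s0 <- stats::plogis(k * (0 - m))
  s1 <- stats::plogis(k * (1 - m))
  (s - s0) / (s1 - s0)
}

fl_factor <- function(theta_deg, center, width = 60, floor = 0.3) {
  pmax(floor, exp(-0.5 * ((theta_deg - center) / width)^2))
}

# ---- arm construction --------------------------------------------------------

new_muscle <- function(name, electrode, actions, threshold = 0.1,
                       saturation = 0.9, fatigue_rate = 0) {
  list(name = name, electrode = electrode, actions = actions,
       recruit = list(threshold = threshold, saturation = saturation),
       fatigue_rate = fatigue_rate)
}

# actions: data.frame(joint = 1 or 2, peak = signed Nm); force-length centers
# are derived from the joint and torque direction when the arm is assembled.
assemble_arm <- function(muscles, electrodes, scenario) {
  joints <- list(shoulder = list(lo = 15, hi = 85),
                 elbow    = list(lo = 20, hi = 130))
  fl <- list(width = 60, floor = 0.3, offset = 40)
  rows <- do.call(rbind, lapply(seq_along(muscles), function(i) {
    m <- muscles[[i]]
    a <- m$actions
    data.frame(muscle = i, name = m$name,
               electrode = match(m$electrode, electrodes),
               joint = a$joint, peak = a$peak,
               threshold = m$recruit$threshold,
               saturation = m$recruit$saturation,
               stringsAsFactors = FALSE)
  }))
  mids <- vapply(joints, function(j) (j$lo + j$hi) / 2, 0)
  rows$center <- mids[rows$joint] + ifelse(rows$peak > 0, -fl$offset, fl$offset)
  rows$row <- 2L * (rows$joint - 1L) + ifelse(rows$peak > 0, 1L, 2L)
  structure(list(
    scenario = scenario,
    links = c(upper = 0.33, fore = 0.45),   # metres
    joints = joints,
    passive = list(amplitude = 3, length_const = 15),  # Nm, deg
    fl = fl,
    muscles = muscles,
    electrodes = electrodes,
    actions = rows,
    dynamics = list(m1 = 2.1, m2 = 1.65, r1 = 0.15, r2 = 0.19,
                    I1 = 0.025, I2 = 0.045, b0 = 2.5, b_act = 0.5)
  ), class = "fes_arm")
}

#' Construct the default six-electrode arm
#'
#' One electrode per muscle; every electrode's joint-torque ratio is constant
#' in stimulation (the uniform-recruitment regime), so the biarticular muscles
#' couple the joints with a configuration-dependent but
#' stimulation-independent ratio.
#'
#' @return an object of class \code{fes_arm}.
#' @export
make_default_arm <- function() {
  sho <- 1L; elb <- 2L
  muscles <- list(
    new_muscle("anterior_deltoid", "AD", data.frame(joint = sho, peak = 40)),
    new_muscle("posterior_deltoid", "PD", data.frame(joint = sho, peak = -40)),
    new_muscle("brachialis", "Br", data.frame(joint = elb, peak = 30)),
    new_muscle("triceps_lateral", "TLat", data.frame(joint = elb, peak = -30)),
    new_muscle("biceps", "Bi", data.frame(joint = c(sho, elb), peak = c(10, 25))),
    new_muscle("triceps_long", "TLong", data.frame(joint = c(sho, elb),
                                                   peak = c(-10, -25)))
  )
  assemble_arm(muscles, c("AD", "PD", "Br", "TLat", "Bi", "TLong"), "default")
}

#' Construct an arm with a current-spillover electrode
#'
#' Replaces the biceps channel with a single electrode driving two hypothetical
#' monoarticular flexors (one shoulder, one elbow) whose recruitment curves
#' differ, so the electrode's shoulder-to-elbow torque ratio depends on the
#' stimulation level.
#'
#' Scenario \code{"A"} (the more common shape): the second muscle simply
#' recruits at higher stimulation, so both torques are monotone but the ratio
#' drifts with stimulation.  Scenario \code{"B"} (less common): staggered
#' recruitment plus early saturation of the first muscle, so the ordering of
#' the two joint torques reverses across the stimulation range.
#'
#' @param scenario \code{"A"} or \code{"B"}.
#' @return an object of class \code{fes_arm}.
#' @export
make_spillover_arm <- function(scenario = c("A", "B")) {
  scenario <- match.arg(scenario)
  sho <- 1L; elb <- 2L
  spill <- if (scenario == "A") {
    list(
      new_muscle("spill_elbow_flexor", "SP", data.frame(joint = elb, peak = 25),
                 threshold = 0.08, saturation = 0.55),
      new_muscle("spill_shoulder_flexor", "SP", data.frame(joint = sho, peak = 10),
                 threshold = 0.45, saturation = 0.92)
    )
  } else {
    list(
      new_muscle("spill_elbow_flexor", "SP", data.frame(joint = elb, peak = 12),
                 threshold = 0.05, saturation = 0.35),
      new_muscle("spill_shoulder_flexor", "SP", data.frame(joint = sho, peak = 18),
                 threshold = 0.40, saturation = 0.90)
    )
  }
  muscles <- c(list(
    new_muscle("anterior_deltoid", "AD", data.frame(joint = sho, peak = 40)),
    new_muscle("posterior_deltoid", "PD", data.frame(joint = sho, peak = -40)),
    new_muscle("brachialis", "Br", data.frame(joint = elb, peak = 30)),
    new_muscle("triceps_lateral", "TLat", data.frame(joint = elb, peak = -30))
  ), spill, list(
    new_muscle("triceps_long", "TLong", data.frame(joint = c(sho, elb),
                                                   peak = c(-10, -25)))
  ))
  assemble_arm(muscles, c("AD", "PD", "Br", "TLat", "SP", "TLong"),
               paste0("spillover_", scenario))
}

#' Construct an arm by scenario name
#'
#' @param scenario one of \code{"default"}, \code{"spillover_A"},
#'   \code{"spillover_B"}.
#' @return an object of class \code{fes_arm}.
#' @export
make_arm <- function(scenario = "default") {
  switch(scenario,
         default = make_default_arm(),
         spillover_A = make_spillover_arm("A"),
         spillover_B = make_spillover_arm("B"),
         stop("unknown arm scenario: ", scenario))
}

n_electrodes <- function(arm) length(arm$electrodes)

#' Set per-muscle fatigue rates
#'
#' @param arm an \code{fes_arm}.
#' @param rates named numeric vector, fraction of torque capacity lost per
#'   second (names are muscle names); unnamed muscles keep their current rate.
#' @return the modified arm.
#' @export
set_fatigue_rates <- function(arm, rates) {
  stopifnot(all(rates >= 0))
  nm <- vapply(arm$muscles, `[[`, "", "name")
  for (i in seq_along(rates)) {
    j <- match(names(rates)[i], nm)
    if (is.na(j)) stop("unknown muscle: ", names(rates)[i])
    arm$muscles[[j]]$fatigue_rate <- rates[[i]]
  }
  arm
}

#' Fatigue state after a period of use
#'
#' Capacity decays linearly with elapsed time at each muscle's fatigue rate:
#' \code{capacity = max(0, 1 - rate * t)}.
#'
#' @param arm an \code{fes_arm}.
#' @param elapsed_s seconds of use.
#' @return list with per-muscle \code{capacity} and \code{elapsed_s}.
#' @export
fatigue_state <- function(arm, elapsed_s = 0) {
  rates <- vapply(arm$muscles, `[[`, 0, "fatigue_rate")
  cap <- pmax(0, 1 - rates * elapsed_s)
  names(cap) <- vapply(arm$muscles, `[[`, "", "name")
  list(capacity = cap, elapsed_s = elapsed_s)
}

#' Write / read an arm parameterization as YAML
#'
#' Serializes everything that defines the plant: geometry, joint ranges,
#' passive-torque and force-length parameters, per-muscle actions and
#' recruitment, electrode assignment, and dynamics constants.  A re-read arm
#' reproduces the original torque field exactly.
#'
#' @param arm an \code{fes_arm}.
#' @param path YAML file path.
#' @return \code{write_arm}: the path, invisibly; \code{read_arm}: the
#'   reconstructed \code{fes_arm}.
#' @export
write_arm <- function(arm, path) {
  spec <- list(
    scenario = arm$scenario,
    links = as.list(arm$links),
    joints = lapply(arm$joints, function(j) list(lo = j$lo, hi = j$hi)),
    passive = arm$passive,
    force_length = arm$fl,
    dynamics = arm$dynamics,
    muscles = lapply(arm$muscles, function(m) {
      list(name = m$name, electrode = m$electrode,
           joints = m$actions$joint, peaks = m$actions$peak,
           threshold = m$recruit$threshold,
           saturation = m$recruit$saturation,
           fatigue_rate = m$fatigue_rate)
    }),
    electrodes = arm$electrodes)
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_arm
#' @export
read_arm <- function(path) {
  spec <- yaml::read_yaml(path)
  muscles <- lapply(spec$muscles, function(m) {
    new_muscle(m$name, m$electrode,
               data.frame(joint = unlist(m$joints), peak = unlist(m$peaks)),
               threshold = m$threshold, saturation = m$saturation,
               fatigue_rate = m$fatigue_rate)
  })
  arm <- assemble_arm(muscles, unlist(spec$electrodes), spec$scenario)
  arm$links <- unlist(spec$links)
  arm$joints <- lapply(spec$joints, function(j) list(lo = j$lo, hi = j$hi))
  arm$passive <- spec$passive
  arm$fl <- spec$force_length
  arm$dynamics <- spec$dynamics
  # re-derive force-length centers and row indices under the (possibly
  # edited) joint ranges and offset
  mids <- vapply(arm$joints, function(j) (j$lo + j$hi) / 2, 0)
  arm$actions$center <- mids[arm$actions$joint] +
    ifelse(arm$actions$peak > 0, -arm$fl$offset, arm$fl$offset)
  arm
}

#' Check the arm's torque capacity over the workspace
#'
#' Builds and solves the torque-balance system at every (grid configuration,
#' stiffness) node and reports the fraction with a fully interior solution
#' (every scale factor strictly inside (0, 1)).  The default arm is designed
#' so that this fraction is at least 0.95 over the 3-13 Nm stiffness range;
#' the shortfall is concentrated at low stiffness near the range limits,
#' where the passive torque approaches or exceeds the requested S and no
#' muscle can push the balance back.
#'
#' @param arm an \code{fes_arm}.
#' @param grid an \code{fes_grid} (default 5-degree, S = 3..13 Nm).
#' @return list with \code{fraction_interior}, \code{fraction_feasible} and
#'   the per-stiffness interior fractions.
#' @export
check_arm_capacity <- function(arm, grid = sampling_grid(step = 5,
                                                         stiffness = 3:13)) {
  calib <- calibrate(arm, grid, sweep_steps = 21)
  tab <- build_initial_table(calib, grid$stiffness)
  n <- prod(dim(tab$u)[1:3]); m <- dim(tab$u)[4]
  cm <- matrix(tab$c, n, m)
  interior <- apply(cm, 1, function(v) all(v > 1e-9 & v < 1 - 1e-9))
  Svec <- rep(grid$stiffness, each = grid_count(grid))
  list(fraction_interior = mean(interior),
       fraction_feasible = mean(tab$feasible),
       by_stiffness = tapply(interior, Svec, mean))
}

#' Workspace membership
#'
#' @param arm an \code{fes_arm}.
#' @param config numeric \code{c(shoulder_deg, elbow_deg)} or an N x 2 matrix.
#' @return logical vector.
#' @export
in_workspace <- function(arm, config) {
  cfg <- rbind(config)
  cfg[, 1] >= arm$joints$shoulder$lo & cfg[, 1] <= arm$joints$shoulder$hi &
    cfg[, 2] >= arm$joints$elbow$lo & cfg[, 2] <= arm$joints$elbow$hi
}

# ---- kinematics --------------------------------------------------------------

#' Fingertip position of the two-link chain
#'
#' @param arm an \code{fes_arm}.
#' @param config \code{c(shoulder_deg, elbow_deg)} or an N x 2 matrix.
#' @return fingertip position in cm: length-2 vector or N x 2 matrix (x, y).
#' @export
forward_kinematics <- function(arm, config) {
  cfg <- rbind(config)
  a <- deg2rad(cfg[, 1]); b <- deg2rad(cfg[, 1] + cfg[, 2])
  L <- arm$links * 100  # cm
  out <- cbind(x = L[1] * cos(a) + L[2] * cos(b),
               y = L[1] * sin(a) + L[2] * sin(b))
  if (is.null(dim(config))) drop(out) else out
}

#' Closed-form inverse kinematics (elbow-flexed branch)
#'
#' @param arm an \code{fes_arm}.
#' @param xy fingertip position in cm, \code{c(x, y)} or an N x 2 matrix.
#' @return joint configuration in degrees (same shape convention as input).
#'   Errors if the point is outside the reachable annulus.
#' @export
inverse_kinematics <- function(arm, xy) {
  p <- rbind(xy)
  L <- arm$links * 100
  r2 <- p[, 1]^2 + p[, 2]^2
  ce <- (r2 - L[1]^2 - L[2]^2) / (2 * L[1] * L[2])
  if (any(ce > 1 + 1e-9 | ce < -1 + 1e-12)) {
    stop("endpoint outside the reachable annulus of the two-link arm")
  }
  te <- acos(clamp(ce, -1, 1))
  ts <- atan2(p[, 2], p[, 1]) - atan2(L[2] * sin(te), L[1] + L[2] * cos(te))
  out <- cbind(shoulder = ts, elbow = te) * 180 / pi
  if (is.null(dim(xy))) drop(out) else out
}

# ---- torques -----------------------------------------------------------------

#' Passive elastic joint torques
#'
#' @param arm an \code{fes_arm}.
#' @param config \code{c(shoulder_deg, elbow_deg)} or an N x 2 matrix.
#' @return for a single config, a data.frame with one row per joint and
#'   columns \code{Pf} (>= 0), \code{Pe} (<= 0), \code{net}; for a matrix of
#'   configs, a list of N x 2 matrices \code{Pf}, \code{Pe}, \code{net}
#'   (columns shoulder, elbow).
#' @export
passive_torques <- function(arm, config) {
  cfg <- rbind(config)
  amp <- arm$passive$amplitude; lam <- arm$passive$length_const
  Pf <- sapply(1:2, function(j) {
    amp * exp(-(cfg[, j] - arm$joints[[j]]$lo) / lam)
  })
  Pe <- sapply(1:2, function(j) {
    -amp * exp(-(arm$joints[[j]]$hi - cfg[, j]) / lam)
  })
  Pf <- matrix(Pf, ncol = 2, dimnames = list(NULL, JOINTS))
  Pe <- matrix(Pe, ncol = 2, dimnames = list(NULL, JOINTS))
  if (is.null(dim(config))) {
    data.frame(joint = JOINTS, Pf = Pf[1, ], Pe = Pe[1, ],
               net = Pf[1, ] + Pe[1, ], row.names = NULL)
  } else {
    list(Pf = Pf, Pe = Pe, net = Pf + Pe)
  }
}

# Muscle activations for a stimulation matrix (N x electrodes): N x muscles.
muscle_activations <- function(arm, u) {
  acts <- arm$actions
  mus <- !duplicated(acts$muscle)
  out <- matrix(0, nrow(u), length(arm$muscles))
  for (k in which(mus)) {
    i <- acts$muscle[k]
    out[, i] <- recruitment_activation(u[, acts$electrode[k]],
                                       acts$threshold[k], acts$saturation[k])
  }
  out
}

# Net joint torque field (passive + active), vectorized across rows.
# theta: N x 2 (deg), u: N x electrodes, capacity: per-muscle vector.
# Returns list(tau = N x 2 Nm, activation_total = N).
plant_net_torque <- function(arm, theta, u, capacity = NULL) {
  if (is.null(capacity)) capacity <- rep(1, length(arm$muscles))
  acts <- arm$actions
  a_mus <- muscle_activations(arm, u)
  tau <- matrix(0, nrow(theta), 2)
  for (k in seq_len(nrow(acts))) {
    j <- acts$joint[k]
    tau[, j] <- tau[, j] + acts$peak[k] *
      fl_factor(theta[, j], acts$center[k], arm$fl$width, arm$fl$floor) *
      a_mus[, acts$muscle[k]] * capacity[acts$muscle[k]]
  }
  p <- passive_torques(arm, theta)
  if (is.null(dim(p$net))) p <- passive_torques(arm, rbind(theta))
  list(tau = tau + p$net, activation_total = rowSums(a_mus))
}

#' Active torques produced by a stimulation vector
#'
#' Per-electrode, per-joint signed torques at a fixed configuration.  Torques
#' superpose across electrodes (no cross-channel interaction is modelled).
#'
#' @param arm an \code{fes_arm}.
#' @param stim normalized stimulation per electrode, values in \code{[0, 1]}.
#' @param config \code{c(shoulder_deg, elbow_deg)}.
#' @param fatigue optional result of \code{\link{fatigue_state}}.
#' @return 2 x m matrix (rows shoulder, elbow; columns electrodes), Nm.
#' @export
active_torques <- function(arm, stim, config, fatigue = NULL) {
  if (any(stim < 0 | stim > 1)) stop("stimulation values must lie in [0, 1]")
  capacity <- if (is.null(fatigue)) rep(1, length(arm$muscles)) else fatigue$capacity
  acts <- arm$actions
  u <- matrix(stim, 1, n_electrodes(arm))
  a_mus <- muscle_activations(arm, u)
  out <- matrix(0, 2, n_electrodes(arm),
                dimnames = list(JOINTS, arm$electrodes))
  for (k in seq_len(nrow(acts))) {
    out[acts$joint[k], acts$electrode[k]] <-
      out[acts$joint[k], acts$electrode[k]] + acts$peak[k] *
      fl_factor(config[acts$joint[k]], acts$center[k], arm$fl$width, arm$fl$floor) *
      a_mus[1, acts$muscle[k]] * capacity[acts$muscle[k]]
  }
  out
}

# ---- static equilibrium ------------------------------------------------------

# Vectorized damped-Newton solve of the static torque balance for many
# stimulation vectors at once.  Central-difference Jacobian, step capped at
# 5 deg, angles clamped to the joint ranges extended by `slack` deg.
equilibrium_batch <- function(arm, stim, init, fatigue = NULL,
                              tol = 1e-9, max_iter = 150, slack = 10) {
  u <- rbind(stim); theta <- rbind(init)
  n <- nrow(theta)
  capacity <- if (is.null(fatigue)) NULL else fatigue$capacity
  lo <- c(arm$joints$shoulder$lo, arm$joints$elbow$lo) - slack
  hi <- c(arm$joints$shoulder$hi, arm$joints$elbow$hi) + slack
  h <- 1e-3
  f <- plant_net_torque(arm, theta, u, capacity)$tau
  active <- rep(TRUE, n)
  for (iter in seq_len(max_iter)) {
    active <- pmax(abs(f[, 1]), abs(f[, 2])) > tol
    if (!any(active)) break
    idx <- which(active)
    th <- theta[idx, , drop = FALSE]; uu <- u[idx, , drop = FALSE]
    pert <- function(dj, dh) {
      t2 <- th; t2[, dj] <- t2[, dj] + dh
      plant_net_torque(arm, t2, uu, capacity)$tau
    }
    J11 <- (pert(1, h)[, 1] - pert(1, -h)[, 1]) / (2 * h)
    J21 <- (pert(1, h)[, 2] - pert(1, -h)[, 2]) / (2 * h)
    J12 <- (pert(2, h)[, 1] - pert(2, -h)[, 1]) / (2 * h)
    J22 <- (pert(2, h)[, 2] - pert(2, -h)[, 2]) / (2 * h)
    det <- J11 * J22 - J12 * J21
    f1 <- f[idx, 1]; f2 <- f[idx, 2]
    bad <- abs(det) < 1e-10
    ds <- ifelse(bad, f1 / (abs(J11) + 1e-6), -( J22 * f1 - J12 * f2) / det)
    de <- ifelse(bad, f2 / (abs(J22) + 1e-6), -(-J21 * f1 + J11 * f2) / det)
    ds <- clamp(ds, -5, 5); de <- clamp(de, -5, 5)
    th[, 1] <- clamp(th[, 1] + ds, lo[1], hi[1])
    th[, 2] <- clamp(th[, 2] + de, lo[2], hi[2])
    theta[idx, ] <- th
    f[idx, ] <- plant_net_torque(arm, th, uu, capacity)$tau
  }
  resid <- pmax(abs(f[, 1]), abs(f[, 2]))
  # stability: both eigenvalues of the torque-field Jacobian negative
  pert_all <- function(dj, dh) {
    t2 <- theta; t2[, dj] <- t2[, dj] + dh
    plant_net_torque(arm, t2, u, capacity)$tau
  }
  J11 <- (pert_all(1, h)[, 1] - pert_all(1, -h)[, 1]) / (2 * h)
  J21 <- (pert_all(1, h)[, 2] - pert_all(1, -h)[, 2]) / (2 * h)
  J12 <- (pert_all(2, h)[, 1] - pert_all(2, -h)[, 1]) / (2 * h)
  J22 <- (pert_all(2, h)[, 2] - pert_all(2, -h)[, 2]) / (2 * h)
  stable <- (J11 + J22 < 0) & (J11 * J22 - J12 * J21 > 0)
  colnames(theta) <- JOINTS
  list(config = theta, residual = resid, converged = resid < 1e-6,
       stable = stable, iterations = iter)
}

#' Static equilibrium configuration under constant stimulation
#'
#' Finds a configuration where the net joint torque (passive plus active)
#' vanishes, by damped multivariate Newton root-finding started from
#' \code{init}.  Roots where the torque-field Jacobian has a non-negative
#' eigenvalue are unstable and reported as such.
#'
#' @param arm an \code{fes_arm}.
#' @param stim normalized stimulation per electrode in \code{[0, 1]}.
#' @param init starting configuration \code{c(shoulder_deg, elbow_deg)}.
#' @param fatigue optional result of \code{\link{fatigue_state}}.
#' @param tol torque tolerance in Nm (converged when below \code{1e-6}).
#' @return list with \code{config} (degrees), \code{residual} (Nm),
#'   \code{converged}, \code{stable}.
#' @export
equilibrium <- function(arm, stim, init, fatigue = NULL, tol = 1e-9) {
  if (any(stim < 0 | stim > 1)) stop("stimulation values must lie in [0, 1]")
  res <- equilibrium_batch(arm, matrix(stim, 1), matrix(init, 1),
                           fatigue = fatigue, tol = tol)
  if (!res$converged[1]) {
    # retry from perturbed starts before reporting failure
    starts <- expand.grid(ds = c(-20, 0, 20), de = c(-30, 0, 30))
    for (k in seq_len(nrow(starts))) {
      alt <- equilibrium_batch(arm, matrix(stim, 1),
                               matrix(init + c(starts$ds[k], starts$de[k]), 1),
                               fatigue = fatigue, tol = tol)
      if (alt$converged[1] && alt$stable[1]) { res <- alt; break }
    }
  }
  list(config = res$config[1, ], residual = res$residual[1],
       converged = res$converged[1], stable = res$stable[1])
}

# ---- forward dynamics --------------------------------------------------------

#' Simulate rigid-body dynamics under a piecewise-constant stimulation schedule
#'
#' Two-link rigid-body dynamics with joint viscous damping that increases
#' linearly with total muscle activation (damping rises with cocontraction),
#' integrated with a fixed-step classical 4th-order Runge-Kutta scheme.  The
#' stimulation schedule is piecewise-constant at the command cadence.
#'
#' @param arm an \code{fes_arm}.
#' @param stim_schedule matrix with one row per command interval (columns are
#'   electrodes), or a single stimulation vector held for the whole duration.
#' @param duration_s simulated time in seconds.
#' @param dt_s integration step (must be <= 1 ms).
#' @param init initial configuration \code{c(shoulder_deg, elbow_deg)}.
#' @param init_vel initial joint velocities in deg/s.
#' @param command_dt_s command cadence in seconds (default 0.05).
#' @param fatigue optional result of \code{\link{fatigue_state}}.
#' @return list with \code{trajectory} (data.frame: t, shoulder, elbow, x, y),
#'   \code{halted} flag (joint-limit guard band exceeded) and the final state.
#' @export
simulate_dynamics <- function(arm, stim_schedule, duration_s, dt_s = 1e-3,
                              init, init_vel = c(0, 0), command_dt_s = 0.05,
                              fatigue = NULL) {
  stopifnot(dt_s <= 1e-3 + 1e-12)
  u_sched <- rbind(stim_schedule)
  if (any(u_sched < 0 | u_sched > 1)) stop("stimulation values must lie in [0, 1]")
  capacity <- if (is.null(fatigue)) NULL else fatigue$capacity
  dyn <- arm$dynamics; L1 <- arm$links[[1]]
  lo <- c(arm$joints$shoulder$lo, arm$joints$elbow$lo) - 25
  hi <- c(arm$joints$shoulder$hi, arm$joints$elbow$hi) + 25

  deriv <- function(state, u_row) {
    th <- state[1:2]; om <- state[3:4]           # rad, rad/s
    nt <- plant_net_torque(arm, matrix(th * 180 / pi, 1), u_row, capacity)
    b <- dyn$b0 + dyn$b_act * nt$activation_total
    tau <- nt$tau[1, ] - b * om
    c2 <- cos(th[2]); s2 <- sin(th[2])
    M11 <- dyn$I1 + dyn$I2 + dyn$m1 * dyn$r1^2 +
      dyn$m2 * (L1^2 + dyn$r2^2 + 2 * L1 * dyn$r2 * c2)
    M12 <- dyn$I2 + dyn$m2 * (dyn$r2^2 + L1 * dyn$r2 * c2)
    M22 <- dyn$I2 + dyn$m2 * dyn$r2^2
    hcor <- dyn$m2 * L1 * dyn$r2 * s2
    rhs1 <- tau[1] + hcor * om[2] * (2 * om[1] + om[2])
    rhs2 <- tau[2] - hcor * om[1]^2
    det <- M11 * M22 - M12^2
    acc <- c(M22 * rhs1 - M12 * rhs2, -M12 * rhs1 + M11 * rhs2) / det
    c(om, acc)
  }

  nstep <- max(1L, round(duration_s / dt_s))
  state <- c(deg2rad(init), deg2rad(init_vel))
  keep_every <- max(1L, round(0.005 / dt_s))  # record at 5 ms
  ts <- numeric(); traj <- list(); halted <- FALSE
  rec <- function(t, s) list(t = t, th = s[1:2] * 180 / pi)
  out_t <- 0; k <- 0L
  snaps <- vector("list", nstep %/% keep_every + 2L)
  snaps[[1]] <- rec(0, state); ns <- 1L
  for (i in seq_len(nstep)) {
    t <- (i - 1L) * dt_s
    row <- min(nrow(u_sched), 1L + floor(t / command_dt_s + 1e-9))
    u_row <- u_sched[row, , drop = FALSE]
    k1 <- deriv(state, u_row)
    k2 <- deriv(state + dt_s / 2 * k1, u_row)
    k3 <- deriv(state + dt_s / 2 * k2, u_row)
    k4 <- deriv(state + dt_s * k3, u_row)
    state <- state + dt_s / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    th_deg <- state[1:2] * 180 / pi
    if (any(th_deg < lo) || any(th_deg > hi)) { halted <- TRUE }
    if (i %% keep_every == 0L || i == nstep || halted) {
      ns <- ns + 1L; snaps[[ns]] <- rec(i * dt_s, state)
    }
    if (halted) break
  }
  snaps <- snaps[seq_len(ns)]
  th <- t(vapply(snaps, `[[`, numeric(2), "th"))
  xy <- forward_kinematics(arm, th)
  traj <- data.frame(t = vapply(snaps, `[[`, 0, "t"),
                     shoulder = th[, 1], elbow = th[, 2],
                     x = xy[, 1], y = xy[, 2])
  list(trajectory = traj, halted = halted,
       final_config = th[nrow(th), ],
       final_vel = state[3:4] * 180 / pi)
}

#' @export
print.fes_arm <- function(x, ...) {
  cat("<fes_arm> scenario:", x$scenario, "\n")
  cat(" ", length(x$muscles), "muscles on", length(x$electrodes),
      "electrodes; workspace shoulder",
      paste0("[", x$joints$shoulder$lo, ", ", x$joints$shoulder$hi, "]"),
      "elbow", paste0("[", x$joints$elbow$lo, ", ", x$joints$elbow$hi, "] deg\n"))
  invisible(x)
}
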