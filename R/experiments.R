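#' @title In-silico studies: sampling resolution, spillover, fatigue, reaching
#'
#' @description
#' The three quantitative studies the package reproduces on its synthetic
#' plant — lookup-table accuracy versus calibration sampling resolution,
#' convergence of the spillover fixed-point iteration over the whole
#' workspace, and the benefit of fatigue-resistant rebalancing — plus a
#' closed-loop quasi-static center-out reach demonstration driven by a
#' simulated user with optional visual-feedback redirection.
#'
#' @name experiments
NULL

#' Lookup-table accuracy versus calibration sampling resolution
#'
#' Calibrates the arm densely once, then for each angular resolution builds
#' the table from the down-sampled calibration only, interpolates back to the
#' dense grid, applies every node's stimulation to the plant and measures the
#' fingertip error.  Sampled nodes have zero error by construction (noise-free
#' calibration); the workspace median quantifies the interpolation cost.
#'
#' @param arm an \code{fes_arm}.
#' @param resolutions angular steps in degrees (each a multiple of
#'   \code{base_step}).
#' @param stiffness stiffness levels in Nm.
#' @param base_step dense calibration/evaluation step in degrees.
#' @param calibration optional pre-computed dense calibration.
#' @return list with \code{medians} (data.frame: resolution, S, median
#'   endpoint error in cm) and \code{fields} (per-resolution node-level
#'   data.frames from \code{\link{evaluate_table}}).
#' @export
resolution_experiment <- function(arm, resolutions = c(1, 5, 10, 20),
                                  stiffness = 8, base_step = 1,
                                  calibration = NULL) {
  calib <- calibration %||%
    calibrate(arm, sampling_grid(step = base_step, stiffness = stiffness))
  fields <- list()
  meds <- list()
  for (r in resolutions) {
    tab <- downsample_and_interpolate(calib, r, stiffness = stiffness)
    ev <- evaluate_table(tab, arm)
    fields[[as.character(r)]] <- ev
    meds[[as.character(r)]] <- data.frame(
      resolution = r, S = stiffness,
      median_error_cm = vapply(stiffness, function(s)
        stats::median(ev$endpoint_error_cm[ev$S == s]), 0))
  }
  list(medians = do.call(rbind, meds), fields = fields)
}

#' Spillover fixed-point iteration over the full workspace
#'
#' Runs the iterative solve for every combination of stiffness level and
#' 5-degree joint-angle grid node (11 x 15 x 23 = 3795 systems by default)
#' on a spillover arm, recording iteration counts and the solution error
#' before and after iterating.
#'
#' @param scenario \code{"A"} or \code{"B"} (or an already-built spillover
#'   \code{fes_arm}).
#' @param grid an \code{fes_grid} (default 5-degree, S = 3..13 Nm).
#' @param tol,max_iter iteration settings (defaults 0.001 and 1000).
#' @param calibration optional pre-computed calibration for the arm.
#' @return list with \code{results} (data.frame: shoulder, elbow, S,
#'   iterations, converged, initial/final residual norms) and \code{summary}.
#' @export
spillover_experiment <- function(scenario = "A",
                                 grid = sampling_grid(step = 5, stiffness = 3:13),
                                 tol = 1e-3, max_iter = 1000L,
                                 calibration = NULL) {
  arm <- if (inherits(scenario, "fes_arm")) scenario else
    make_spillover_arm(scenario)
  calib <- calibration %||% calibrate(arm, grid)
  tab <- build_initial_table(calib, stiffness = grid$stiffness,
                             spillover_tol = tol,
                             spillover_max_iter = max_iter)
  ns <- length(grid$shoulder); ne <- length(grid$elbow)
  res <- data.frame(
    shoulder = rep(grid$shoulder, times = ne * length(grid$stiffness)),
    elbow = rep(rep(grid$elbow, each = ns), times = length(grid$stiffness)),
    S = rep(grid$stiffness, each = ns * ne),
    iterations = as.vector(tab$iterations),
    converged = as.vector(tab$converged),
    initial_residual = as.vector(tab$initial_residual),
    final_residual = as.vector(tab$residual))
  list(results = res,
       summary = list(
         n = nrow(res),
         n_converged = sum(res$converged),
         fraction_converged = mean(res$converged),
         median_iterations = stats::median(res$iterations[res$converged]),
         median_initial_residual = stats::median(res$initial_residual),
         median_final_residual = stats::median(res$final_residual)),
       table = tab)
}

#' Fatigue experiment: standard versus fatigue-resistant tables
#'
#' For one of the eleven rebalancing scenarios: marks the scenario's muscles
#' with a 0.5 percent-per-second capacity loss, builds the standard table and
#' a fatigue-resistant table (marked columns scaled by 0.5), then attempts to
#' hold the arm at every (angle, stiffness) combination at each time point
#' and records endpoint and stiffness errors for both tables, with a
#' two-sided Wilcoxon rank-sum comparison per time point.
#'
#' @param arm the default \code{fes_arm} (fatigue rates are set internally).
#' @param scenario one element of \code{\link{fatigue_scenarios}} or its
#'   integer id.
#' @param times evaluation times in seconds (default \code{seq(0, 100, 5)}).
#' @param grid an \code{fes_grid} (default 5-degree, S = 3..13).
#' @param calibration optional pre-computed calibration.
#' @param standard_table optional pre-built standard table (it does not depend
#'   on the scenario).
#' @return list with \code{timecourse} (data.frame per time point: median
#'   endpoint/stiffness errors for both tables, median paired differences,
#'   Wilcoxon p-values) and the two tables.
#' @export
fatigue_experiment <- function(arm = make_default_arm(), scenario,
                               times = seq(0, 100, by = 5),
                               grid = sampling_grid(step = 5, stiffness = 3:13),
                               calibration = NULL, standard_table = NULL) {
  if (is.numeric(scenario)) scenario <- fatigue_scenarios()[[scenario]]
  calib <- calibration %||% calibrate(arm, grid)
  std <- standard_table %||% build_initial_table(calib, grid$stiffness)
  fac <- stats::setNames(rep(scenario$factor, length(scenario$electrodes)),
                         scenario$electrodes)
  resist <- build_initial_table(rebalance(calib, fac), grid$stiffness)
  rates <- stats::setNames(rep(scenario$fatigue_rate, length(scenario$muscles)),
                           scenario$muscles)
  plant <- set_fatigue_rates(arm, rates)
  ns <- length(grid$shoulder); ne <- length(grid$elbow)
  nS <- length(grid$stiffness)
  n <- ns * ne * nS
  cfg <- grid_configs(grid)
  intended <- cfg[rep(seq_len(ns * ne), nS), ]
  Svec <- rep(grid$stiffness, each = ns * ne)
  m <- length(calib$electrodes)
  u_std <- matrix(std$u, n, m)
  u_res <- matrix(resist$u, n, m)
  p0 <- forward_kinematics(plant, intended)
  rows <- lapply(times, function(t) {
    fat <- fatigue_state(plant, t)
    e_std <- equilibrium_batch(plant, u_std, intended, fatigue = fat)
    e_res <- equilibrium_batch(plant, u_res, intended, fatigue = fat)
    ok <- e_std$converged & e_res$converged
    err_std <- sqrt(rowSums((forward_kinematics(plant, e_std$config) - p0)^2))
    err_res <- sqrt(rowSums((forward_kinematics(plant, e_res$config) - p0)^2))
    sf_std <- abs(achieved_stiffness(plant, e_std$config, u_std, fat) - Svec)
    sf_res <- abs(achieved_stiffness(plant, e_res$config, u_res, fat) - Svec)
    wp <- if (t > 0) stats::wilcox.test(err_std[ok], err_res[ok])$p.value else NA
    ws <- if (t > 0) stats::wilcox.test(sf_std[ok], sf_res[ok])$p.value else NA
    data.frame(t = t, n_ok = sum(ok),
               med_pos_standard = stats::median(err_std[ok]),
               med_pos_resistant = stats::median(err_res[ok]),
               med_pos_diff = stats::median(err_std[ok] - err_res[ok]),
               med_stiff_standard = stats::median(sf_std[ok]),
               med_stiff_resistant = stats::median(sf_res[ok]),
               med_stiff_diff = stats::median(sf_std[ok] - sf_res[ok]),
               p_position = wp, p_stiffness = ws)
  })
  list(timecourse = do.call(rbind, rows), scenario = scenario,
       standard_table = std, resistant_table = resist)
}

#' Stiffness from commanded speed
#'
#' Linear-in-speed schedule: maximum stiffness at rest (movement endpoints),
#' minimum stiffness at peak speed.  This realizes the qualitative policy of
#' lowering cocontraction while the arm is moving fast and stiffening as it
#' decelerates toward the target.
#'
#' @param speed commanded speed(s), cm/s.
#' @param v_peak the profile's peak speed, cm/s.
#' @param S_min,S_max stiffness range in Nm (within \code{[3, 13]}).
#' @return stiffness value(s) in Nm.
#' @export
stiffness_schedule <- function(speed, v_peak, S_min = 3, S_max = 13) {
  stopifnot(S_min >= 3 - 1e-9, S_max <= 13 + 1e-9, S_min <= S_max)
  S_max - (S_max - S_min) * clamp(abs(speed) / v_peak, 0, 1)
}

#' Center-out target set
#'
#' @param arm an \code{fes_arm}.
#' @param start_config starting configuration (deg).
#' @param radius_cm target distance (default 14 cm).
#' @param n number of radial targets (default 8).
#' @return n x 2 matrix of target fingertip positions (cm).
#' @export
center_out_targets <- function(arm, start_config = c(50, 75),
                               radius_cm = 14, n = 8) {
  p0 <- forward_kinematics(arm, start_config)
  ang <- 2 * pi * (0:(n - 1)) / n
  cbind(x = p0[1] + radius_cm * cos(ang), y = p0[2] + radius_cm * sin(ang))
}

#' Open-loop reach command from a simulated user
#'
#' Generates the 50 ms command sequence a simulated user would issue to move
#' the fingertip from the start configuration to a target along a straight
#' line with a minimum-jerk (bell-shaped) speed profile, followed by a hold
#' phase at the target.  Stiffness is scheduled from the commanded speed.
#'
#' @param arm an \code{fes_arm}.
#' @param start_config starting configuration (deg).
#' @param target fingertip target \code{c(x, y)} in cm (must be reachable).
#' @param duration_s movement time (default 1.3 s).
#' @param hold_s hold time appended at the target (default 1.2 s).
#' @param dt_s command cadence (default 0.05 s).
#' @param S_min,S_max stiffness schedule range.
#' @return object of class \code{fes_command}: data.frame with one row per
#'   50 ms step (t, x, y, shoulder, elbow, speed, S) plus attributes
#'   \code{target}, \code{duration_s}, \code{v_peak}.
#' @export
simulated_user <- function(arm, start_config, target, duration_s = 1.3,
                           hold_s = 1.2, dt_s = 0.05, S_min = 3, S_max = 13) {
  p0 <- forward_kinematics(arm, start_config)
  d <- sqrt(sum((target - p0)^2))
  v_peak <- 1.875 * d / duration_s  # minimum-jerk peak speed
  tgrid <- seq(0, duration_s + hold_s, by = dt_s)
  sp <- minjerk_speed(tgrid, duration_s, d)
  sp[tgrid > duration_s] <- 0
  dir <- if (d > 0) (target - p0) / d else c(0, 0)
  # closed-form minimum-jerk position fraction avoids integration drift
  frac <- minjerk_pos_frac(clamp(tgrid / duration_s, 0, 1))
  pos <- cbind(p0[1] + dir[1] * d * frac, p0[2] + dir[2] * d * frac)
  cfg <- inverse_kinematics(arm, pos)
  S <- if (d > 0) stiffness_schedule(sp, v_peak, S_min, S_max) else
    rep(S_max, length(sp))   # start = target: hold at maximum stiffness
  cmd <- data.frame(t = tgrid, x = pos[, 1], y = pos[, 2],
                    shoulder = cfg[, 1], elbow = cfg[, 2], speed = sp, S = S)
  structure(cmd, class = c("fes_command", "data.frame"),
            target = target, duration_s = duration_s, hold_s = hold_s,
            v_peak = v_peak, start_config = start_config,
            S_min = S_min, S_max = S_max)
}

minjerk_pos_frac <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Quasi-static closed-loop reach simulation
#'
#' At each 50 ms step the commanded configuration and stiffness are looked up
#' in the table and the resulting stimulation is held while the rigid-body
#' dynamics advance.  With \code{feedback = TRUE} the commanded velocity is
#' re-aimed from the current simulated fingertip toward the target at every
#' loop (the simulated user watching the arm), and during the hold phase the
#' user keeps nudging the command proportionally to the remaining error.
#'
#' @param table an \code{fes_lookup}.
#' @param command an \code{fes_command} from \code{\link{simulated_user}}.
#' @param arm the plant.
#' @param feedback re-aim the command using visual feedback.
#' @param dt_s integration step for the dynamics (default 1 ms).
#' @param fb_gain proportional correction gain during the hold phase (per
#'   step, 0..1).
#' @param fatigue optional \code{\link{fatigue_state}}.
#' @return list with \code{path} (data.frame: t, x, y, shoulder, elbow),
#'   \code{terminal_error_cm}, \code{commanded} (the possibly re-aimed
#'   command), \code{extrapolated} (any query outside the table hull).
#' @export
reach_simulation <- function(table, command, arm, feedback = FALSE,
                             dt_s = 1e-3, fb_gain = 0.1, fatigue = NULL) {
  target <- attr(command, "target")
  duration <- attr(command, "duration_s")
  start_cfg <- attr(command, "start_config")
  hull <- list(s = range(table$shoulder), e = range(table$elbow))
  state_cfg <- start_cfg
  state_vel <- c(0, 0)
  p_cmd <- c(command$x[1], command$y[1])
  nstep <- nrow(command)
  path <- vector("list", nstep)
  any_extrap <- FALSE
  cmd_out <- command
  for (k in seq_len(nstep)) {
    t_k <- command$t[k]
    p_sim <- forward_kinematics(arm, state_cfg)
    if (feedback) {
      gap <- target - p_sim
      dist <- sqrt(sum(gap^2))
      dirv <- if (dist > 1e-9) gap / dist else c(0, 0)
      step_len <- if (t_k <= duration + 1e-9) {
        command$speed[k] * 0.05
      } else {
        fb_gain * dist  # hold phase: proportional homing on the residual
      }
      p_cmd <- p_cmd + dirv * step_len
    } else {
      p_cmd <- c(command$x[k], command$y[k])
    }
    cfg_cmd <- inverse_kinematics(arm, p_cmd)
    cfg_cmd <- c(clamp(cfg_cmd[1], hull$s[1] - 9.5, hull$s[2] + 9.5),
                 clamp(cfg_cmd[2], hull$e[1] - 9.5, hull$e[2] + 9.5))
    q <- query_table(table, cfg_cmd[1], cfg_cmd[2], command$S[k])
    any_extrap <- any_extrap || q$extrapolated
    cmd_out$x[k] <- p_cmd[1]; cmd_out$y[k] <- p_cmd[2]
    cmd_out$shoulder[k] <- cfg_cmd[1]; cmd_out$elbow[k] <- cfg_cmd[2]
    sim <- simulate_dynamics(arm, q$u, duration_s = 0.05, dt_s = dt_s,
                             init = state_cfg, init_vel = state_vel,
                             fatigue = fatigue)
    state_cfg <- sim$final_config
    state_vel <- sim$final_vel
    path[[k]] <- data.frame(t = t_k + sim$trajectory$t,
                            x = sim$trajectory$x, y = sim$trajectory$y,
                            shoulder = sim$trajectory$shoulder,
                            elbow = sim$trajectory$elbow)
  }
  path <- do.call(rbind, path)
  p_final <- forward_kinematics(arm, state_cfg)
  list(path = path,
       terminal_error_cm = sqrt(sum((p_final - target)^2)),
       final_config = state_cfg,
       commanded = cmd_out,
       extrapolated = any_extrap)
}

#' Run a full center-out reach set
#'
#' @param table an \code{fes_lookup}.
#' @param arm the plant.
#' @param start_config starting configuration (deg).
#' @param radius_cm target distance (default 14).
#' @param n_targets number of radial targets (default 8).
#' @param feedback visual-feedback redirection on/off.
#' @param ... passed to \code{\link{simulated_user}} / \code{\link{reach_simulation}}.
#' @return data.frame with one row per target: direction, terminal error (cm).
#' @export
center_out_experiment <- function(table, arm, start_config = c(50, 75),
                                  radius_cm = 14, n_targets = 8,
                                  feedback = TRUE, ...) {
  targets <- center_out_targets(arm, start_config, radius_cm, n_targets)
  out <- lapply(seq_len(nrow(targets)), function(i) {
    cmd <- simulated_user(arm, start_config, targets[i, ])
    res <- reach_simulation(table, cmd, arm, feedback = feedback, ...)
    data.frame(target = i,
               angle_deg = round(360 * (i - 1) / n_targets),
               terminal_error_cm = res$terminal_error_cm,
               extrapolated = res$extrapolated)
  })
  do.call(rbind, out)
}
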