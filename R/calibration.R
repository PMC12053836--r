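#' @title Simulated exoskeleton calibration
#'
#' @description
#' Plays the role of the sensored exoskeleton that parameterizes the
#' controller: it holds the (simulated) arm stationary on a grid of joint
#' configurations and records (a) the passive torques, (b) the
#' stimulation-to-active-torque curve of every electrode, and (c) each
#' electrode's maximum active torque on every joint.  With measurement noise
#' off (the default) these records are an exact function of the plant.
#'
#' @name calibration
NULL

#' Grid points along one angular axis
#'
#' Inclusive-start floor convention: \code{lo, lo + step, ...} up to the
#' largest value not exceeding \code{hi}.
#'
#' @param lo,hi axis range in degrees.
#' @param step positive step in degrees.
#' @return numeric vector of angles.
#' @export
grid_points <- function(lo, hi, step) {
  if (step <= 0) stop("step must be positive")
  if (hi < lo) stop("hi must be >= lo")
  lo + step * (0:floor((hi - lo) / step + 1e-9))
}

#' Construct a sampling grid
#'
#' @param shoulder,elbow numeric \code{c(lo, hi)} ranges in degrees.
#' @param step angular step in degrees (shared by both axes), or length-2
#'   vector \code{c(shoulder_step, elbow_step)}.
#' @param stiffness stiffness levels in Nm.
#' @return an object of class \code{fes_grid}.
#' @export
sampling_grid <- function(shoulder = c(15, 85), elbow = c(20, 130),
                          step = 5, stiffness = 3:13) {
  step <- rep(step, length.out = 2)
  structure(list(shoulder = grid_points(shoulder[1], shoulder[2], step[1]),
                 elbow = grid_points(elbow[1], elbow[2], step[2]),
                 stiffness = stiffness, step = step),
            class = "fes_grid")
}

#' Number of angular grid configurations
#'
#' Product of per-axis counts; stiffness levels are counted separately.
#'
#' @param grid an \code{fes_grid}.
#' @return integer count.
#' @export
grid_count <- function(grid) length(grid$shoulder) * length(grid$elbow)

grid_configs <- function(grid) {
  as.matrix(expand.grid(shoulder = grid$shoulder, elbow = grid$elbow,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Measure passive torques over a grid
#'
#' Records, per configuration and joint, the flexion and extension passive
#' components.  In \code{"component"} mode the two one-sided components are
#' measured separately (the plant exposes them); in \code{"net"} mode only the
#' net holding torque is observable and a positive net value is attributed to
#' \code{Pf}, a negative one to \code{Pe}.
#'
#' @param arm an \code{fes_arm}.
#' @param grid an \code{fes_grid}.
#' @param attribution \code{"component"} (default) or \code{"net"}.
#' @param noise_sd additive Gaussian measurement noise SD in Nm (default 0).
#' @param seed RNG seed used when \code{noise_sd > 0}.
#' @return array \code{[config, joint, component]} with components
#'   \code{Pf}, \code{Pe}.
#' @export
measure_passive <- function(arm, grid, attribution = c("component", "net"),
                            noise_sd = 0, seed = 1L) {
  attribution <- match.arg(attribution)
  cfg <- grid_configs(grid)
  p <- passive_torques(arm, cfg)
  out <- array(0, c(nrow(cfg), 2, 2),
               dimnames = list(NULL, JOINTS, c("Pf", "Pe")))
  if (attribution == "component") {
    out[, , "Pf"] <- p$Pf
    out[, , "Pe"] <- p$Pe
  } else {
    out[, , "Pf"] <- pmax(p$net, 0)
    out[, , "Pe"] <- pmin(p$net, 0)
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
    out[, , "Pf"] <- pmax(out[, , "Pf"], 0)
    out[, , "Pe"] <- pmin(out[, , "Pe"], 0)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Measure one electrode's stimulation-to-active-torque curve
#'
#' Sweeps normalized stimulation over an even grid from 0 to 1, subtracting
#' the passive torques so the curve is active-only, and truncates the sweep at
#' the first level where no joint's torque changed by more than
#' \code{plateau_eps} over the last three steps (the torque has stopped
#' changing) or at maximum stimulation, whichever comes first.
#'
#' @param arm an \code{fes_arm}.
#' @param config \code{c(shoulder_deg, elbow_deg)}.
#' @param electrode electrode id (name) or index.
#' @param sweep_steps number of sweep levels including 0 (>= 21).
#' @param plateau_eps plateau tolerance in Nm.
#' @param fatigue optional \code{\link{fatigue_state}}.
#' @return object of class \code{fes_curve}: list with \code{u} (levels),
#'   \code{torque} (levels x 2 joints, Nm), \code{max_torque} (signed per
#'   joint), \code{truncated_at}, \code{monotone_warning}.
#' @export
measure_recruitment <- function(arm, config, electrode, sweep_steps = 201,
                                plateau_eps = 0.01, fatigue = NULL) {
  stopifnot(sweep_steps >= 21)
  e <- if (is.character(electrode)) match(electrode, arm$electrodes) else electrode
  if (is.na(e)) stop("unknown electrode: ", electrode)
  u <- seq(0, 1, length.out = sweep_steps)
  tq <- t(vapply(u, function(ui) {
    s <- rep(0, n_electrodes(arm)); s[e] <- ui
    rowSums(active_torques(arm, s, config, fatigue))
  }, numeric(2)))
  colnames(tq) <- JOINTS
  cut <- sweep_steps
  for (i in 4:sweep_steps) {
    if (all(abs(tq[i, ] - tq[i - 3, ]) < plateau_eps)) { cut <- i; break }
  }
  u <- u[1:cut]; tq <- tq[1:cut, , drop = FALSE]
  imax <- apply(abs(tq), 2, which.max)
  max_torque <- tq[cbind(imax, 1:2)]
  ref <- which.max(abs(max_torque))
  mono <- diff(abs(tq[, ref]))
  structure(list(electrode = arm$electrodes[e], config = config, u = u,
                 torque = tq, max_torque = max_torque,
                 truncated_at = u[cut],
                 monotone_warning = any(mono < -plateau_eps)),
            class = "fes_curve")
}

#' Collect full calibration data on a grid
#'
#' Runs the passive-torque and recruitment measurements at every grid
#' configuration for every electrode and assembles them into a
#' \code{fes_calibration} object.  All electrodes share a common stimulation
#' sweep grid; curves are stored dense (no truncation) so that interpolation
#' across configurations stays aligned, with each electrode's plateau point
#' recorded separately.
#'
#' @param arm an \code{fes_arm}.
#' @param grid an \code{fes_grid}.
#' @param sweep_steps stimulation sweep resolution (default 201).
#' @param plateau_eps plateau tolerance in Nm (default 0.01).
#' @param attribution passive attribution mode, see \code{\link{measure_passive}}.
#' @param noise_sd,seed optional Gaussian measurement noise on passive and
#'   active torques.
#' @return an object of class \code{fes_calibration} with elements
#'   \code{grid}, \code{configs}, \code{passive [config, joint, comp]},
#'   \code{A [4, electrode, config]} (signed max active torques in row order
#'   shoulder-flexion, shoulder-extension, elbow-flexion, elbow-extension),
#'   \code{curves [config, electrode, level, joint]}, \code{u_levels},
#'   \code{spillover} (per-electrode flag: joint-torque ratio varies with
#'   stimulation).
#' @export
calibrate <- function(arm, grid, sweep_steps = 201, plateau_eps = 0.01,
                      attribution = "component", noise_sd = 0, seed = 1L) {
  cfg <- grid_configs(grid)
  n <- nrow(cfg); m <- n_electrodes(arm)
  passive <- measure_passive(arm, grid, attribution, noise_sd, seed)
  u <- seq(0, 1, length.out = sweep_steps)
  curves <- array(0, c(n, m, sweep_steps, 2))
  acts <- arm$actions
  for (e in seq_len(m)) {
    rows <- acts[acts$electrode == e, , drop = FALSE]
    for (iu in seq_along(u)) {
      if (u[iu] == 0) next
      for (k in seq_len(nrow(rows))) {
        a <- recruitment_activation(u[iu], rows$threshold[k], rows$saturation[k])
        curves[, e, iu, rows$joint[k]] <- curves[, e, iu, rows$joint[k]] +
          rows$peak[k] * a *
          fl_factor(cfg[, rows$joint[k]], rows$center[k], arm$fl$width, arm$fl$floor)
      }
    }
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed + 1L)
    noise <- array(stats::rnorm(length(curves), 0, noise_sd), dim(curves))
    noise[, , 1, ] <- 0  # u = 0 anchors the curve at zero active torque
    curves <- curves + noise
  }
  # signed max torques into A-row layout [4, m, n]
  A <- array(0, c(4, m, n))
  for (e in seq_len(m)) {
    for (j in 1:2) {
      tj <- curves[, e, , j, drop = FALSE]
      dim(tj) <- c(n, sweep_steps)
      imax <- max.col(abs(tj), ties.method = "first")
      mx <- tj[cbind(seq_len(n), imax)]
      r <- ifelse(mx >= 0, 2L * (j - 1L) + 1L, 2L * (j - 1L) + 2L)
      for (ri in unique(r)) {
        sel <- r == ri
        A[ri, e, sel] <- mx[sel]
      }
    }
  }
  # spillover detection: does the ratio between the electrode's two joint
  # torques vary with stimulation level? (checked at the first config)
  spill <- vapply(seq_len(m), function(e) {
    tq <- curves[1, e, , ]
    mx <- apply(abs(tq), 2, max)
    if (min(mx) < 1e-6) return(FALSE)  # effectively single-joint
    ref <- which.max(mx); oth <- 3 - ref
    sel <- abs(tq[, ref]) > 0.2 * mx[ref]
    ratio <- tq[sel, oth] / tq[sel, ref]
    diff(range(ratio)) > 0.01 * max(1, abs(mean(ratio)))
  }, TRUE)
  structure(list(arm_scenario = arm$scenario, grid = grid, configs = cfg,
                 passive = passive, A = A, curves = curves, u_levels = u,
                 spillover = spill, electrodes = arm$electrodes,
                 sweep_steps = sweep_steps, plateau_eps = plateau_eps,
                 attribution = attribution, noise_sd = noise_sd, seed = seed),
            class = "fes_calibration")
}

# Bilinear interpolation of calibration records at an off-grid configuration.
# Returns list(passive = 2x2 [joint, comp], A = 4 x m, curves = [m, levels, 2]).
calibration_at <- function(calib, config) {
  gs <- calib$grid$shoulder; ge <- calib$grid$elbow
  ns <- length(gs)
  is_ <- findInterval(config[1], gs, all.inside = TRUE)
  ie <- findInterval(config[2], ge, all.inside = TRUE)
  ts <- if (length(gs) > 1) (config[1] - gs[is_]) / (gs[is_ + 1] - gs[is_]) else 0
  te <- if (length(ge) > 1) (config[2] - ge[ie]) / (ge[ie + 1] - ge[ie]) else 0
  idx <- function(i, j) (j - 1L) * ns + i
  corners <- c(idx(is_, ie), idx(min(is_ + 1, ns), ie),
               idx(is_, min(ie + 1, length(ge))),
               idx(min(is_ + 1, ns), min(ie + 1, length(ge))))
  w <- c((1 - ts) * (1 - te), ts * (1 - te), (1 - ts) * te, ts * te)
  pas <- matrix(0, 2, 2, dimnames = list(JOINTS, c("Pf", "Pe")))
  A <- matrix(0, 4, length(calib$electrodes))
  cur <- array(0, c(length(calib$electrodes), length(calib$u_levels), 2))
  for (k in 1:4) {
    if (w[k] == 0) next
    pas <- pas + w[k] * calib$passive[corners[k], , ]
    A <- A + w[k] * calib$A[, , corners[k]]
    cur <- cur + w[k] * calib$curves[corners[k], , , ]
  }
  list(passive = pas, A = A, curves = cur)
}

#' @export
print.fes_calibration <- function(x, ...) {
  cat("<fes_calibration>", x$arm_scenario, "arm;", nrow(x$configs),
      "configurations x", length(x$electrodes), "electrodes;",
      length(x$u_levels), "sweep levels\n")
  if (any(x$spillover)) {
    cat("  spillover electrodes:",
        paste(x$electrodes[x$spillover], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read calibration data as plain-text artifacts
#'
#' The passive-torque and max-torque tables go to CSV; the sweep curves and
#' metadata to a JSON sidecar.
#'
#' @param calib an \code{fes_calibration}.
#' @param dir output directory (created if needed).
#' @return \code{write_calibration}: invisibly, the file paths;
#'   \code{read_calibration}: the reconstructed \code{fes_calibration}.
#' @export
write_calibration <- function(calib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(calib$configs)
  pas <- data.frame(shoulder = calib$configs[, 1], elbow = calib$configs[, 2],
                    Pf_shoulder = calib$passive[, 1, 1],
                    Pe_shoulder = calib$passive[, 1, 2],
                    Pf_elbow = calib$passive[, 2, 1],
                    Pe_elbow = calib$passive[, 2, 2])
  utils::write.csv(pas, file.path(dir, "passive_torques.csv"), row.names = FALSE)
  mx <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(shoulder = calib$configs[i, 1], elbow = calib$configs[i, 2],
               electrode = calib$electrodes,
               sho_flex = calib$A[1, , i], sho_ext = calib$A[2, , i],
               elb_flex = calib$A[3, , i], elb_ext = calib$A[4, , i],
               row.names = NULL)
  }))
  utils::write.csv(mx, file.path(dir, "max_torques.csv"), row.names = FALSE)
  meta <- list(arm_scenario = calib$arm_scenario,
               grid = list(shoulder = calib$grid$shoulder,
                           elbow = calib$grid$elbow,
                           stiffness = calib$grid$stiffness,
                           step = calib$grid$step),
               u_levels = calib$u_levels, spillover = calib$spillover,
               electrodes = calib$electrodes, sweep_steps = calib$sweep_steps,
               plateau_eps = calib$plateau_eps, attribution = calib$attribution,
               noise_sd = calib$noise_sd, seed = calib$seed,
               curves = calib$curves)
  jsonlite::write_json(meta, file.path(dir, "calibration_meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(file.path(dir, c("passive_torques.csv", "max_torques.csv",
                             "calibration_meta.json")))
}

#' @rdname write_calibration
#' @export
read_calibration <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "calibration_meta.json"),
                              simplifyVector = TRUE)
  grid <- structure(list(shoulder = meta$grid$shoulder,
                         elbow = meta$grid$elbow,
                         stiffness = meta$grid$stiffness,
                         step = meta$grid$step), class = "fes_grid")
  pas <- utils::read.csv(file.path(dir, "passive_torques.csv"))
  n <- nrow(pas)
  passive <- array(0, c(n, 2, 2), dimnames = list(NULL, JOINTS, c("Pf", "Pe")))
  passive[, 1, 1] <- pas$Pf_shoulder; passive[, 1, 2] <- pas$Pe_shoulder
  passive[, 2, 1] <- pas$Pf_elbow; passive[, 2, 2] <- pas$Pe_elbow
  mx <- utils::read.csv(file.path(dir, "max_torques.csv"))
  m <- length(meta$electrodes)
  A <- array(0, c(4, m, n))
  for (i in seq_len(n)) {
    blk <- mx[((i - 1) * m + 1):(i * m), ]
    A[1, , i] <- blk$sho_flex; A[2, , i] <- blk$sho_ext
    A[3, , i] <- blk$elb_flex; A[4, , i] <- blk$elb_ext
  }
  curves <- meta$curves
  dim(curves) <- c(n, m, length(meta$u_levels), 2)
  structure(list(arm_scenario = meta$arm_scenario, grid = grid,
                 configs = cbind(shoulder = pas$shoulder, elbow = pas$elbow),
                 passive = passive, A = A, curves = curves,
                 u_levels = meta$u_levels, spillover = meta$spillover,
                 electrodes = meta$electrodes, sweep_steps = meta$sweep_steps,
                 plateau_eps = meta$plateau_eps, attribution = meta$attribution,
                 noise_sd = meta$noise_sd, seed = meta$seed),
            class = "fes_calibration")
}
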