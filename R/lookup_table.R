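#' @title Stimulation lookup tables over (shoulder, elbow, stiffness)
#'
#' @description
#' Turns solved scale vectors into stimulation values and organizes them on a
#' grid over shoulder angle, elbow angle and stiffness.  The initial table L0
#' holds the stimulation that should achieve each node; verification applies
#' each node's stimulation to the plant and records where the arm actually
#' settles; the final table L keys stimulation by those achieved
#' configurations.  Queries interpolate linearly one dimension at a time
#' (shoulder, then elbow, then stiffness); queries outside the grid hull are
#' linearly extrapolated and flagged.
#'
#' @name lookup_table
NULL

#' Convert scale coefficients to stimulation values
#'
#' Per electrode, inverts the recorded stimulation-to-torque curve (the
#' reference joint for multi-joint electrodes) at the target torque
#' \code{c_i * alpha_i * max_i}.  A zero coefficient maps to zero stimulation;
#' a unit coefficient with unit adjustment maps to the stimulation of the
#' recorded maximum.
#'
#' @param scales an \code{fes_scales} (or bare coefficient vector).
#' @param system the \code{fes_system} the coefficients solve (carries curves,
#'   unadjusted maxima and adjustment factors).
#' @return list with \code{u} (per-electrode stimulation in \code{[0, 1]})
#'   and \code{clamped} (per-electrode flag: target torque exceeded the
#'   curve's recorded maximum).
#' @export
scales_to_stims <- function(scales, system) {
  cvec <- if (inherits(scales, "fes_scales")) scales$c else scales
  m <- length(cvec)
  u <- numeric(m); clamped <- logical(m)
  for (e in seq_len(m)) {
    ce <- cvec[e] * system$adjustments[e]
    if (ce <= 0) next
    Acol <- system$A_unadjusted[, e]
    if (all(abs(Acol) < 1e-12)) next
    tq <- system$curves[e, , ]
    ref_joint <- which.max(apply(abs(tq), 2, max))
    ref_max <- Acol[which.max(abs(Acol))]
    ui <- invert_curve(system$u_levels, tq[, ref_joint], ce * ref_max)
    u[e] <- ui
    clamped[e] <- isTRUE(attr(ui, "clamped"))
  }
  names(u) <- system$electrodes
  list(u = clamp(u, 0, 1), clamped = clamped)
}

#' Build the initial lookup table L0
#'
#' For every (grid configuration, stiffness level): assemble the
#' torque-balance system, solve it (with the spillover fixed-point iteration
#' when the calibration flagged any spillover electrode), and convert the
#' scale factors to stimulation values.  Infeasible nodes are flagged but the
#' table always completes.
#'
#' @param calibration an \code{fes_calibration} or \code{fes_rebalance}.
#' @param stiffness stiffness levels in Nm (default: the calibration grid's).
#' @param adjustments optional per-electrode column factors (overridden by a
#'   \code{fes_rebalance} input).
#' @param spillover_tol,spillover_max_iter spillover iteration settings.
#' @return object of class \code{fes_lookup}: arrays indexed
#'   \code{[shoulder, elbow, stiffness]} holding stimulation \code{u}
#'   (last dim: electrode), residual norms, feasibility/convergence flags,
#'   \code{c}-vector norms, provenance, and build metadata.
#' @export
build_initial_table <- function(calibration, stiffness = NULL,
                                adjustments = NULL,
                                spillover_tol = 1e-3,
                                spillover_max_iter = 1000L) {
  if (inherits(calibration, "fes_rebalance")) {
    adjustments <- calibration$adjustments
    calibration <- calibration$calibration
  }
  stiffness <- stiffness %||% calibration$grid$stiffness
  gs <- calibration$grid$shoulder; ge <- calibration$grid$elbow
  m <- length(calibration$electrodes)
  ns <- length(gs); ne <- length(ge); nS <- length(stiffness)
  adj <- if (is.null(adjustments)) rep(1, m) else rep(adjustments, length.out = m)
  use_spill <- any(calibration$spillover)
  u <- array(0, c(ns, ne, nS, m))
  resid <- array(0, c(ns, ne, nS))
  feas <- array(TRUE, c(ns, ne, nS))
  conv <- array(TRUE, c(ns, ne, nS))
  iters <- array(1L, c(ns, ne, nS))
  cnorm <- array(0, c(ns, ne, nS))
  init_resid <- array(0, c(ns, ne, nS))
  cmat <- array(0, c(ns, ne, nS, m))
  for (i in seq_len(ns)) for (j in seq_len(ne)) {
    node <- (j - 1L) * ns + i
    curves_node <- calibration$curves[node, , , ]
    for (k in seq_len(nS)) {
      sys <- structure(list(
        x = c(stiffness[k] - calibration$passive[node, 1, 1],
              -stiffness[k] - calibration$passive[node, 1, 2],
              stiffness[k] - calibration$passive[node, 2, 1],
              -stiffness[k] - calibration$passive[node, 2, 2]),
        A = calibration$A[, , node] * rep(adj, each = 4),
        S = stiffness[k], config = c(gs[i], ge[j]), adjustments = adj,
        A_unadjusted = calibration$A[, , node], curves = curves_node,
        u_levels = calibration$u_levels, spillover = calibration$spillover,
        electrodes = calibration$electrodes), class = "fes_system")
      sol <- if (use_spill) {
        iterate_spillover(sys, tol = spillover_tol,
                          max_iter = spillover_max_iter)
      } else {
        solve_bounded_min_norm(sys)
      }
      st <- scales_to_stims(sol, sys)
      u[i, j, k, ] <- st$u
      resid[i, j, k] <- sol$residual_norm
      feas[i, j, k] <- sol$feasible
      cnorm[i, j, k] <- sqrt(sum(sol$c^2))
      cmat[i, j, k, ] <- sol$c
      if (use_spill) {
        conv[i, j, k] <- sol$converged
        iters[i, j, k] <- sol$iterations
        init_resid[i, j, k] <- sol$initial_residual
        resid[i, j, k] <- sol$final_residual
      }
    }
  }
  structure(list(shoulder = gs, elbow = ge, stiffness = stiffness,
                 u = u, c = cmat, residual = resid, feasible = feas,
                 converged = conv, iterations = iters,
                 initial_residual = init_resid, c_norm = cnorm,
                 provenance = array("measured", c(ns, ne, nS)),
                 arm_scenario = calibration$arm_scenario,
                 adjustments = adj, spillover = use_spill,
                 electrodes = calibration$electrodes,
                 grid_step = calibration$grid$step),
            class = "fes_lookup")
}

#' Verify a lookup table on the plant
#'
#' Applies each node's stimulation to the arm and records the static
#' equilibrium configuration it actually settles at (started from the intended
#' configuration), together with the fingertip displacement from the intended
#' node.
#'
#' @param table an \code{fes_lookup}.
#' @param arm the plant (normally the arm the calibration was measured on).
#' @param fatigue optional \code{\link{fatigue_state}}.
#' @return list with \code{achieved} array \code{[s, e, S, joint]} (deg),
#'   \code{converged} flags, and \code{displacement_cm}.
#' @export
verify_table <- function(table, arm, fatigue = NULL) {
  ns <- length(table$shoulder); ne <- length(table$elbow)
  nS <- length(table$stiffness); m <- dim(table$u)[4]
  n <- ns * ne * nS
  um <- matrix(aperm(table$u, c(1, 2, 3, 4)), n, m)
  intended <- as.matrix(expand.grid(table$shoulder, table$elbow,
                                    KEEP.OUT.ATTRS = FALSE))
  intended <- intended[rep(seq_len(ns * ne), nS), ]
  eq <- equilibrium_batch(arm, um, intended, fatigue = fatigue)
  disp <- sqrt(rowSums((forward_kinematics(arm, eq$config) -
                        forward_kinematics(arm, intended))^2))
  list(achieved = array(eq$config, c(ns, ne, nS, 2)),
       converged = array(eq$converged, c(ns, ne, nS)),
       stable = array(eq$stable, c(ns, ne, nS)),
       displacement_cm = array(disp, c(ns, ne, nS)))
}

#' Build the final lookup table from achieved configurations
#'
#' @param table the initial \code{fes_lookup}.
#' @param verification result of \code{\link{verify_table}}.
#' @return an \code{fes_lookup} with class \code{fes_lookup_final} prepended:
#'   stimulation keyed by the achieved configurations.
#' @export
finalize_table <- function(table, verification) {
  table$achieved <- verification$achieved
  table$achieved_converged <- verification$converged
  class(table) <- c("fes_lookup_final", class(table))
  table
}

# interpolate a [k, ...] slab along its first axis at position xq
axis_interp <- function(coords, values, xq) {
  lin_interp(coords, values, xq)
}

#' Query a lookup table
#'
#' Interpolates the stored stimulation vectors linearly one dimension at a
#' time: shoulder, then elbow, then stiffness.  For a final table the
#' shoulder/elbow interpolation runs on the achieved coordinates, so querying
#' a measured node's achieved configuration returns that node's stimulation
#' exactly.  Queries outside the hull are linearly extrapolated and flagged;
#' queries more than 10 degrees beyond the hull are refused.
#'
#' @param table an \code{fes_lookup} or \code{fes_lookup_final}.
#' @param shoulder,elbow configuration in degrees.
#' @param S stiffness in Nm.
#' @return list with \code{u} (per-electrode stimulation, clamped to
#'   \code{[0, 1]}), \code{u_raw} (before clamping), \code{extrapolated}.
#' @export
query_table <- function(table, shoulder, elbow, S) {
  gs <- table$shoulder; ge <- table$elbow; gS <- table$stiffness
  if (shoulder < min(gs) - 10 || shoulder > max(gs) + 10 ||
      elbow < min(ge) - 10 || elbow > max(ge) + 10) {
    stop("query more than 10 degrees outside the table hull")
  }
  extrap <- shoulder < min(gs) || shoulder > max(gs) ||
    elbow < min(ge) || elbow > max(ge) || S < min(gS) || S > max(gS)
  m <- dim(table$u)[4]
  ns <- length(gs); ne <- length(ge); nS <- length(gS)
  final <- inherits(table, "fes_lookup_final")
  u_S <- matrix(0, nS, m)
  for (k in seq_len(nS)) {
    # step 1: along shoulder for every elbow line
    u_e <- matrix(0, ne, m)
    elb_coord <- numeric(ne)
    for (j in seq_len(ne)) {
      xs <- if (final) table$achieved[, j, k, 1] else gs
      slab <- matrix(table$u[, j, k, ], ns, m)
      u_e[j, ] <- lin_interp(xs, slab, shoulder)
      elb_coord[j] <- if (final) {
        lin_interp(xs, table$achieved[, j, k, 2], shoulder)
      } else ge[j]
    }
    # step 2: along elbow
    u_S[k, ] <- lin_interp(elb_coord, u_e, elbow)
  }
  # step 3: along stiffness
  u_raw <- drop(lin_interp(gS, u_S, S))
  names(u_raw) <- table$electrodes
  list(u = clamp(u_raw, 0, 1), u_raw = u_raw, extrapolated = extrap)
}

#' Interpolate a table onto a denser regular grid
#'
#' Axis-by-axis linear interpolation (with linear extrapolation outside the
#' source hull) of the stored stimulation arrays onto new shoulder/elbow/
#' stiffness axes.  Nodes that coincide with source nodes keep provenance
#' \code{"measured"}; others are \code{"interpolated"} or
#' \code{"extrapolated"}.
#'
#' @param table an \code{fes_lookup} (initial; intended-grid geometry).
#' @param shoulder,elbow,stiffness the target axes.
#' @return a new \code{fes_lookup} on the target axes.
#' @export
interp_table_grid <- function(table, shoulder = NULL, elbow = NULL,
                              stiffness = NULL) {
  shoulder <- shoulder %||% table$shoulder
  elbow <- elbow %||% table$elbow
  stiffness <- stiffness %||% table$stiffness
  interp_axis <- function(arr, axis, old, new) {
    perm <- c(axis, setdiff(1:4, axis))
    a <- aperm(arr, perm)
    d <- dim(a)
    out <- lin_interp(old, matrix(a, d[1], prod(d[-1])), new)
    dim(out) <- c(length(new), d[-1])
    aperm(out, order(perm))
  }
  u4 <- interp_axis(table$u, 1, table$shoulder, shoulder)
  u4 <- interp_axis(u4, 2, table$elbow, elbow)
  u4 <- interp_axis(u4, 3, table$stiffness, stiffness)
  on_axis <- function(new, old) {
    vapply(new, function(v) any(abs(v - old) < 1e-9), TRUE)
  }
  inside <- function(new, old) new >= min(old) - 1e-9 & new <= max(old) + 1e-9
  meas <- outer(on_axis(shoulder, table$shoulder),
                outer(on_axis(elbow, table$elbow),
                      on_axis(stiffness, table$stiffness), "&"), "&")
  ins <- outer(inside(shoulder, table$shoulder),
               outer(inside(elbow, table$elbow),
                     inside(stiffness, table$stiffness), "&"), "&")
  prov <- array("interpolated", dim(meas))
  prov[!ins] <- "extrapolated"
  prov[meas] <- "measured"
  out <- table
  out$shoulder <- shoulder; out$elbow <- elbow; out$stiffness <- stiffness
  out$u <- clamp(u4, 0, 1)
  out$u_raw <- u4
  out$provenance <- prov
  out$c <- NULL; out$residual <- NULL; out$feasible <- NULL
  out$converged <- NULL; out$iterations <- NULL; out$c_norm <- NULL
  out$initial_residual <- NULL
  out
}

#' Build a table from down-sampled calibration data and interpolate back
#'
#' Subsets a dense calibration to a sparser angular grid (the target step must
#' be a multiple of the dense step), builds the lookup table from the sparse
#' subset only, and interpolates the stimulation values back onto the dense
#' grid.
#'
#' @param calibration a dense \code{fes_calibration}.
#' @param target_step sparse sampling step in degrees.
#' @param stiffness stiffness levels for the table.
#' @param ... passed to \code{\link{build_initial_table}}.
#' @return an \code{fes_lookup} on the dense grid, built from sparse nodes.
#' @export
downsample_and_interpolate <- function(calibration, target_step,
                                       stiffness = NULL, ...) {
  step <- calibration$grid$step
  if (any(abs(target_step / step - round(target_step / step)) > 1e-9)) {
    stop("target_step must be a multiple of the dense calibration step")
  }
  sub <- subset_calibration(calibration, target_step)
  sparse <- build_initial_table(sub, stiffness = stiffness, ...)
  interp_table_grid(sparse, shoulder = calibration$grid$shoulder,
                    elbow = calibration$grid$elbow)
}

# Restrict a calibration to the sub-grid sampled at `target_step`.
subset_calibration <- function(calibration, target_step) {
  gs <- calibration$grid$shoulder; ge <- calibration$grid$elbow
  ks <- grid_points(min(gs), max(gs), target_step)
  ke <- grid_points(min(ge), max(ge), target_step)
  si <- match(ks, gs); ei <- match(ke, ge)
  if (anyNA(si) || anyNA(ei)) stop("sparse nodes missing from dense grid")
  keep <- as.vector(outer(si, (ei - 1L) * length(gs), "+"))
  out <- calibration
  out$grid <- structure(list(shoulder = ks, elbow = ke,
                             stiffness = calibration$grid$stiffness,
                             step = rep(target_step, 2)), class = "fes_grid")
  out$configs <- calibration$configs[keep, , drop = FALSE]
  out$passive <- calibration$passive[keep, , , drop = FALSE]
  out$A <- calibration$A[, , keep, drop = FALSE]
  out$curves <- calibration$curves[keep, , , , drop = FALSE]
  out
}

#' Evaluate a lookup table against the plant
#'
#' Applies every node's stimulation, finds the static equilibrium and reports
#' per-node fingertip error (cm) and achieved-stiffness error (Nm, the mean
#' over joints of the flexion-side torque sum minus the commanded S).
#'
#' @param table an \code{fes_lookup} (any provenance mix).
#' @param arm the plant.
#' @param fatigue optional \code{\link{fatigue_state}}.
#' @return data.frame with one row per node: intended angles, stiffness,
#'   achieved angles, endpoint error (cm), stiffness error (Nm), provenance,
#'   convergence flag.
#' @export
evaluate_table <- function(table, arm, fatigue = NULL) {
  ns <- length(table$shoulder); ne <- length(table$elbow)
  nS <- length(table$stiffness); m <- dim(table$u)[4]
  n <- ns * ne * nS
  um <- matrix(table$u, n, m)
  cfg <- as.matrix(expand.grid(table$shoulder, table$elbow,
                               KEEP.OUT.ATTRS = FALSE))
  intended <- cfg[rep(seq_len(ns * ne), nS), ]
  Svec <- rep(table$stiffness, each = ns * ne)
  eq <- equilibrium_batch(arm, um, intended, fatigue = fatigue)
  err <- sqrt(rowSums((forward_kinematics(arm, eq$config) -
                       forward_kinematics(arm, intended))^2))
  Sach <- achieved_stiffness(arm, eq$config, um, fatigue = fatigue)
  data.frame(shoulder = intended[, 1], elbow = intended[, 2], S = Svec,
             achieved_shoulder = eq$config[, 1],
             achieved_elbow = eq$config[, 2],
             endpoint_error_cm = err,
             stiffness_error_Nm = Sach - Svec,
             provenance = as.vector(table$provenance),
             converged = eq$converged)
}

#' Achieved stiffness at a configuration under stimulation
#'
#' Stiffness here is the magnitude of balanced opposing torques: at a static
#' equilibrium the flexion-side torque sum (passive flexion component plus all
#' active flexion torques) equals the extension-side magnitude.  Returns the
#' mean over the two joints of the flexion-side sum.
#'
#' @param arm an \code{fes_arm}.
#' @param config configuration (vector or N x 2 matrix, deg).
#' @param stim stimulation (vector or N x m matrix).
#' @param fatigue optional \code{\link{fatigue_state}}.
#' @return numeric vector of achieved stiffness values (Nm).
#' @export
achieved_stiffness <- function(arm, config, stim, fatigue = NULL) {
  theta <- rbind(config); u <- rbind(stim)
  capacity <- if (is.null(fatigue)) rep(1, length(arm$muscles)) else fatigue$capacity
  acts <- arm$actions
  a_mus <- muscle_activations(arm, u)
  flex <- matrix(0, nrow(theta), 2)
  for (k in seq_len(nrow(acts))) {
    if (acts$peak[k] <= 0) next
    j <- acts$joint[k]
    flex[, j] <- flex[, j] + acts$peak[k] *
      fl_factor(theta[, j], acts$center[k], arm$fl$width, arm$fl$floor) *
      a_mus[, acts$muscle[k]] * capacity[acts$muscle[k]]
  }
  p <- passive_torques(arm, theta)
  if (is.data.frame(p)) p <- passive_torques(arm, rbind(theta))
  rowMeans(flex + p$Pf)
}

#' Write / read a lookup table as CSV + JSON metadata
#'
#' Long-format CSV: one row per (shoulder, elbow, stiffness) node with the
#' stimulation vector, provenance and (final tables) achieved angles.
#'
#' @param table an \code{fes_lookup}.
#' @param path CSV path; a JSON sidecar is written next to it.
#' @return \code{write_lookup}: invisibly, the paths; \code{read_lookup}: the
#'   reconstructed table.
#' @export
write_lookup <- function(table, path) {
  ns <- length(table$shoulder); ne <- length(table$elbow)
  nS <- length(table$stiffness); m <- dim(table$u)[4]
  n <- ns * ne * nS
  df <- data.frame(
    shoulder = rep(table$shoulder, times = ne * nS),
    elbow = rep(rep(table$elbow, each = ns), times = nS),
    stiffness = rep(table$stiffness, each = ns * ne))
  um <- matrix(table$u, n, m)
  colnames(um) <- paste0("u_", table$electrodes)
  df <- cbind(df, um)
  df$provenance <- as.vector(table$provenance)
  if (!is.null(table$achieved)) {
    df$achieved_shoulder <- as.vector(table$achieved[, , , 1])
    df$achieved_elbow <- as.vector(table$achieved[, , , 2])
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(arm_scenario = table$arm_scenario,
               adjustments = table$adjustments,
               electrodes = table$electrodes,
               spillover = table$spillover,
               grid_step = table$grid_step,
               final = inherits(table, "fes_lookup_final"),
               axes = list(shoulder = table$shoulder, elbow = table$elbow,
                           stiffness = table$stiffness))
  jpath <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(meta, jpath, digits = NA, auto_unbox = TRUE)
  invisible(c(path, jpath))
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  gs <- meta$axes$shoulder; ge <- meta$axes$elbow; gS <- meta$axes$stiffness
  ns <- length(gs); ne <- length(ge); nS <- length(gS)
  m <- length(meta$electrodes)
  ucols <- paste0("u_", meta$electrodes)
  u <- array(as.matrix(df[, ucols]), c(ns, ne, nS, m))
  out <- structure(list(shoulder = gs, elbow = ge, stiffness = gS, u = u,
                        provenance = array(df$provenance, c(ns, ne, nS)),
                        arm_scenario = meta$arm_scenario,
                        adjustments = meta$adjustments,
                        spillover = meta$spillover,
                        electrodes = meta$electrodes,
                        grid_step = meta$grid_step),
                   class = "fes_lookup")
  if (!is.null(df$achieved_shoulder)) {
    out$achieved <- array(c(df$achieved_shoulder, df$achieved_elbow),
                          c(ns, ne, nS, 2))
    if (isTRUE(meta$final)) class(out) <- c("fes_lookup_final", class(out))
  }
  out
}

#' @export
print.fes_lookup <- function(x, ...) {
  cat("<fes_lookup", if (inherits(x, "fes_lookup_final")) " (final)", "> ",
      length(x$shoulder), " x ", length(x$elbow), " x ",
      length(x$stiffness), " nodes (shoulder x elbow x stiffness), ",
      dim(x$u)[4], " electrodes [", x$arm_scenario, " arm]\n", sep = "")
  tab <- table(as.vector(x$provenance))
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
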