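#' @title Balanced-torque equation systems and the bounded minimum-norm solver
#'
#' @description
#' The analytical core of the controller.  For a joint configuration and a
#' stiffness level S (Nm of balanced opposing torques), the torque-balance
#' conditions \code{S - Pf = sum(Cf_i * Af_max_i)} and
#' \code{-S - Pe = sum(Ce_i * Ae_max_i)} for each joint are assembled into a
#' linear system \code{x = A c} with one flexion and one extension row per
#' joint (row order: shoulder-flexion, shoulder-extension, elbow-flexion,
#' elbow-extension) and one column per electrode.  The scale vector \code{c}
#' is the least-squares minimum-norm solution with every entry constrained to
#' \code{[0, 1]}: negative entries mean a muscle would have to push (it
#' cannot; the column is dropped), entries above one mean a muscle would have
#' to exceed its maximum (it is saturated at one and its full contribution is
#' moved to the right-hand side).
#'
#' @name torque_solver
NULL

ROW_LABELS <- c("sho_flex", "sho_ext", "elb_flex", "elb_ext")

#' Assemble the torque-balance system for one configuration and stiffness
#'
#' @param config \code{c(shoulder_deg, elbow_deg)}; off-grid configurations
#'   use per-dimension linear interpolation of the calibration records.
#' @param S desired stiffness in Nm (> 0).
#' @param calibration an \code{fes_calibration}.
#' @param adjustments optional per-electrode factors in \code{(0, 1]} applied
#'   to the A-matrix columns (work rebalancing); \code{NULL} for none.
#' @return object of class \code{fes_system}: list with \code{x} (length 4),
#'   \code{A} (4 x m), \code{S}, \code{config}, \code{adjustments},
#'   \code{curves} (per-electrode sweep torques at this configuration),
#'   \code{spillover} flags and \code{u_levels}.
#' @export
build_system <- function(config, S, calibration, adjustments = NULL) {
  if (S <= 0) stop("stiffness S must be positive")
  gs <- calibration$grid$shoulder; ge <- calibration$grid$elbow
  if (config[1] < min(gs) - 25 || config[1] > max(gs) + 25 ||
      config[2] < min(ge) - 25 || config[2] > max(ge) + 25) {
    stop("configuration outside the calibrated (extrapolable) region")
  }
  rec <- calibration_at(calibration, config)
  m <- ncol(rec$A)
  adj <- if (is.null(adjustments)) rep(1, m) else rep(adjustments, length.out = m)
  if (any(adj <= 0 | adj > 1)) stop("adjustment factors must lie in (0, 1]")
  x <- c(S - rec$passive[1, "Pf"], -S - rec$passive[1, "Pe"],
         S - rec$passive[2, "Pf"], -S - rec$passive[2, "Pe"])
  names(x) <- ROW_LABELS
  A <- sweep(rec$A, 2, adj, "*")
  dimnames(A) <- list(ROW_LABELS, calibration$electrodes)
  structure(list(x = x, A = A, S = S, config = config, adjustments = adj,
                 A_unadjusted = rec$A, curves = rec$curves,
                 u_levels = calibration$u_levels,
                 spillover = calibration$spillover,
                 electrodes = calibration$electrodes),
            class = "fes_system")
}

#' Bounded least-squares minimum-norm solve
#'
#' Computes the least-squares minimum-norm solution of \code{x = A c}, then
#' iteratively enforces the \code{[0, 1]} bounds: one violation per pass
#' (largest magnitude first); a negative coefficient drops its column, a
#' coefficient above one is fixed at one and its column's full torque is
#' subtracted from the target before re-solving.  Columns strictly decrease,
#' so the loop terminates.
#'
#' @param system an \code{fes_system}, or a list with elements \code{A} and
#'   \code{x}.
#' @param sv_tol relative singular-value cutoff for the pseudoinverse.
#' @return object of class \code{fes_scales}: list with \code{c} (bounded
#'   scale factors), \code{status} per column (\code{interior},
#'   \code{clamped_zero}, \code{clamped_one}, \code{dropped}),
#'   \code{residual} (A c - x), \code{residual_norm}, \code{feasible}
#'   (residual norm below 1e-6) and \code{passes}.
#' @export
solve_bounded_min_norm <- function(system, sv_tol = 1e-12) {
  A <- system$A; x <- system$x
  if (is.null(dim(A)) || ncol(A) < 1) stop("A must have at least one column")
  m <- ncol(A)
  status <- rep("interior", m)
  cvec <- numeric(m)
  zero_cols <- colSums(abs(A)) < 1e-12
  status[zero_cols] <- "dropped"
  free <- which(!zero_cols)
  x_adj <- x
  passes <- 0L
  btol <- 1e-10
  while (TRUE) {
    passes <- passes + 1L
    cf <- if (length(free)) {
      pinv_min_norm(A[, free, drop = FALSE], x_adj, tol = sv_tol)
    } else numeric(0)
    viol <- pmax(-cf, cf - 1)
    if (!length(cf) || max(viol) <= btol) {
      cvec[free] <- if (length(cf)) clamp(cf, 0, 1) else numeric(0)
      break
    }
    k <- which.max(viol)
    if (cf[k] < 0) {
      status[free[k]] <- "clamped_zero"
      cvec[free[k]] <- 0
    } else {
      status[free[k]] <- "clamped_one"
      cvec[free[k]] <- 1
      x_adj <- x_adj - A[, free[k]]
    }
    free <- free[-k]
  }
  resid <- drop(A %*% cvec - x)
  names(cvec) <- colnames(A)
  structure(list(c = cvec, status = status, residual = resid,
                 residual_norm = sqrt(sum(resid^2)),
                 feasible = sqrt(sum(resid^2)) < 1e-6, passes = passes),
            class = "fes_scales")
}

#' Reference box-constrained quadratic-program solver (projected gradient)
#'
#' Minimizes \code{||A c - x||^2} subject to \code{0 <= c <= 1} by projected
#' gradient descent with a fixed \code{1/L} step.  When the optimum attains a
#' (numerically) zero residual the solution set is generally a polytope; in
#' that case a second stage runs Dykstra's alternating-projection algorithm
#' between the affine set \code{A c = x} and the unit box, started from the
#' origin, which converges to the minimum-norm point of the intersection.
#' This is a deliberately independent route used to cross-check
#' \code{\link{solve_bounded_min_norm}}; it is much slower and is not used by
#' the controller.
#'
#' @param A,x the system.
#' @param tol stopping tolerance on the projected-gradient iterate change.
#' @param max_iter iteration cap.
#' @return list with \code{c}, \code{residual_norm}, \code{iterations} and
#'   \code{c_min_norm} (the minimum-norm zero-residual point, or \code{NULL}
#'   when the system is infeasible).
#' @export
solve_box_qp <- function(A, x, tol = 1e-13, max_iter = 100000L) {
  m <- ncol(A)
  L <- 2 * max(svd(A, nu = 0, nv = 0)$d)^2
  if (L <= 0) return(list(c = numeric(m), residual_norm = sqrt(sum(x^2)),
                          iterations = 0L, c_min_norm = NULL))
  step <- 1 / L
  cc <- rep(0.5, m)
  AtA <- crossprod(A); Atx <- crossprod(A, x)
  for (i in seq_len(max_iter)) {
    g <- 2 * (AtA %*% cc - Atx)
    cn <- clamp(cc - step * g, 0, 1)
    if (max(abs(cn - cc)) < tol) { cc <- cn; break }
    cc <- cn
  }
  r <- drop(A %*% cc - x)
  res <- sqrt(sum(r^2))
  cmn <- NULL
  if (res < 1e-8) {
    At <- t(A)
    M <- A %*% At
    diag(M) <- diag(M) + 1e-12 * max(diag(M))
    proj_aff <- function(z) drop(z - At %*% solve(M, A %*% z - x))
    c0 <- numeric(m); p <- numeric(m); q <- numeric(m)
    for (k in seq_len(20000L)) {
      y <- clamp(c0 + p, 0, 1)
      p <- c0 + p - y
      z <- proj_aff(y + q)
      q <- y + q - z
      if (k > 5 && max(abs(z - c0)) < 1e-14) { c0 <- z; break }
      c0 <- z
    }
    cmn <- c0
  }
  list(c = drop(cc), residual_norm = res, iterations = i, c_min_norm = cmn)
}

# Smooth interpolant of a recorded stimulation-to-torque sweep.  Monotone
# cubic (Hyman-filtered) splines keep the interpolated curve monotone where
# the data are monotone and track a smooth recruitment profile to ~1e-8 of
# its range at 101 sweep levels; non-monotone sweeps fall back to a natural
# spline.
curve_fun <- function(u_levels, torque) {
  if (all(abs(torque) < 1e-15)) return(function(u) rep(0, length(u)))
  f <- tryCatch(stats::splinefun(u_levels, torque, method = "hyman"),
                error = function(e)
                  stats::splinefun(u_levels, torque, method = "natural"))
  f
}

# Invert a monotone stimulation-to-torque curve at a target torque, by
# bisection on the monotone spline interpolant of the recorded sweep; ties
# (flat stretches) break toward lower stimulation (less charge); targets
# beyond the recorded maximum clamp to the level of the maximum (flagged via
# attribute).
invert_curve <- function(u_levels, torque, target) {
  s <- sign(torque[which.max(abs(torque))])
  if (s == 0) return(structure(0, clamped = FALSE))
  tq <- s * torque; tg <- s * target
  if (tg <= 0) return(structure(0, clamped = FALSE))
  mx <- which.max(tq)
  if (tg >= tq[mx] - 1e-12) {
    # lowest level attaining the maximum (flat plateaus resolve to lower u)
    hit <- which(tq >= tq[mx] - 1e-12)[1]
    return(structure(u_levels[hit], clamped = tg > tq[mx] + 1e-12))
  }
  f <- curve_fun(u_levels[1:mx], tq[1:mx])
  lo <- 0; hi <- u_levels[mx]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < tg) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, clamped = FALSE)
}

# Realized per-row torques for a scale vector, read off the recorded sweep
# curves (spillover-aware).  Adjustment factors translate each coefficient
# into a target torque on the unadjusted curve.
realized_torques <- function(system, cvec) {
  m <- length(cvec)
  rows <- numeric(4)
  for (e in seq_len(m)) {
    Acol <- system$A_unadjusted[, e]
    ce <- cvec[e] * system$adjustments[e]
    if (ce <= 0) next
    tq <- system$curves[e, , ]  # levels x 2 joints
    mx <- apply(abs(tq), 2, max)
    ref_joint <- which.max(mx)
    ref_max <- Acol[which.max(abs(Acol))]
    u_star <- invert_curve(system$u_levels, tq[, ref_joint], ce * ref_max)
    for (j in 1:2) {
      tj <- curve_fun(system$u_levels, tq[, j])(u_star)
      r <- if (tj >= 0) 2L * (j - 1L) + 1L else 2L * (j - 1L) + 2L
      rows[r] <- rows[r] + tj
    }
  }
  names(rows) <- ROW_LABELS
  rows
}

#' Torque residual of a scale vector
#'
#' With \code{curves = NULL} the residual is the linear prediction error
#' \code{A c - x}.  When curves are supplied, the "actual" torques are read
#' off the recorded stimulation-to-torque curves at the stimulation implied by
#' \code{c} (this is what a spillover electrode would really deliver).
#'
#' @param system an \code{fes_system}.
#' @param cvec scale coefficients in \code{[0, 1]}.
#' @param use_curves read realized torques off the sweep curves.
#' @return list with per-row \code{errors} and their Euclidean \code{norm}.
#' @export
residual_torques <- function(system, cvec, use_curves = FALSE) {
  if (any(cvec < -1e-9 | cvec > 1 + 1e-9)) stop("coefficients must lie in [0, 1]")
  err <- if (use_curves) {
    realized_torques(system, cvec) - system$x
  } else {
    drop(system$A %*% cvec) - system$x
  }
  list(errors = err, norm = sqrt(sum(err^2)))
}

#' Fixed-point iteration for current spillover
#'
#' When an electrode activates muscles on two joints with dissimilar
#' recruitment, the entry ratio in its A-matrix column depends on the
#' stimulation level actually applied.  Starting from the max-torque
#' parameterization, this loop alternates (1) a bounded minimum-norm solve,
#' (2) inversion of the electrode's reference-joint curve (the joint with the
#' larger maximum torque) at the torque implied by the current coefficient,
#' and (3) replacement of the non-reference entry by the curve ratio at that
#' stimulation level times the reference maximum, until the coefficient
#' vector changes by less than \code{tol} or \code{max_iter} is reached.
#'
#' @param system an \code{fes_system} (carrying curves).
#' @param tol stopping tolerance (norm of the coefficient change by default).
#' @param max_iter iteration cap (default 1000).
#' @param per_element compare coefficient changes element-wise instead of by
#'   vector norm.
#' @return an \code{fes_scales} with extra elements \code{iterations},
#'   \code{converged}, \code{residual_trace} (curve-aware residual norm per
#'   iteration) and \code{initial_residual} / \code{final_residual}.
#' @export
iterate_spillover <- function(system, tol = 1e-3, max_iter = 1000L,
                              per_element = FALSE) {
  spill <- which(system$spillover)
  sys_i <- system
  sol <- solve_bounded_min_norm(sys_i)
  trace <- residual_torques(system, sol$c, use_curves = TRUE)$norm
  converged <- length(spill) == 0L
  iter <- 1L
  notes <- character(0)
  while (!converged && iter < max_iter) {
    A_new <- sys_i$A
    for (e in spill) {
      Acol <- system$A_unadjusted[, e]
      nz <- which(abs(Acol) > 1e-12)
      if (length(nz) < 2) next
      ref_row <- nz[which.max(abs(Acol[nz]))]
      oth_row <- setdiff(nz, ref_row)
      ref_joint <- (ref_row + 1L) %/% 2L
      oth_joint <- (oth_row + 1L) %/% 2L
      ce <- sol$c[e] * system$adjustments[e]
      if (ce <= 0) {
        notes <- c(notes, sprintf("iter %d: electrode %s at zero, ratio kept",
                                  iter, system$electrodes[e]))
        next
      }
      tq <- system$curves[e, , ]
      u_star <- invert_curve(system$u_levels, tq[, ref_joint], ce * Acol[ref_row])
      t_ref <- curve_fun(system$u_levels, tq[, ref_joint])(u_star)
      t_oth <- curve_fun(system$u_levels, tq[, oth_joint])(u_star)
      if (abs(t_ref) > 1e-12) {
        A_new[oth_row, e] <- (t_oth / t_ref) * Acol[ref_row] *
          system$adjustments[e]
      }
    }
    sys_i$A <- A_new
    sol_new <- solve_bounded_min_norm(sys_i)
    delta <- sol_new$c - sol$c
    step_ok <- if (per_element) max(abs(delta)) < tol else sqrt(sum(delta^2)) < tol
    sol <- sol_new
    iter <- iter + 1L
    trace <- c(trace, residual_torques(system, sol$c, use_curves = TRUE)$norm)
    if (step_ok) converged <- TRUE
  }
  sol$iterations <- iter
  sol$converged <- converged
  sol$residual_trace <- trace
  sol$initial_residual <- trace[1]
  sol$final_residual <- trace[length(trace)]
  sol$notes <- notes
  sol$system <- sys_i
  sol
}

#' Rebalance work across muscles by scaling A-matrix columns
#'
#' De-emphasizes chosen muscles by multiplying their maximum active torques by
#' a factor in \code{(0, 1]} before solving; the minimum-norm solution then
#' shifts work onto the remaining muscles.  The factors are carried into the
#' stimulation conversion: the target torque for electrode i is
#' \code{c_i * alpha_i * max_i} inverted on the unscaled curve, so at time
#' zero the rebalanced and standard tables place the plant identically.
#'
#' @param calibration an \code{fes_calibration}.
#' @param factors named (by electrode) or full-length numeric vector of
#'   factors in \code{(0, 1]}; omitted electrodes get 1.
#' @return object of class \code{fes_rebalance}: the calibration plus bound
#'   adjustment factors, accepted by \code{\link{build_initial_table}} and
#'   \code{\link{build_system}} users.
#' @export
rebalance <- function(calibration, factors) {
  m <- length(calibration$electrodes)
  adj <- rep(1, m); names(adj) <- calibration$electrodes
  if (!is.null(names(factors)) && any(nzchar(names(factors)))) {
    bad <- setdiff(names(factors), calibration$electrodes)
    if (length(bad)) stop("unknown electrode(s): ", paste(bad, collapse = ", "))
    adj[names(factors)] <- factors
  } else {
    adj <- rep(factors, length.out = m)
  }
  if (any(adj <= 0 | adj > 1)) stop("adjustment factors must lie in (0, 1]")
  structure(list(calibration = calibration, adjustments = adj),
            class = "fes_rebalance")
}

#' The eleven fatigue-rebalancing scenarios
#'
#' Scenarios 1-6 mark one muscle, 7-11 mark two; every marked muscle has its
#' A-matrix column scaled by 0.5 in the fatigue-resistant table and fatigues
#' at 0.5 percent of capacity per second in the plant.
#'
#' @return list of 11 elements, each with \code{id}, \code{muscles} (marked
#'   muscle names), \code{electrodes} (their channels), \code{factor} (0.5)
#'   and \code{fatigue_rate} (0.005 per second).
#' @export
fatigue_scenarios <- function() {
  marks <- list("anterior_deltoid", "posterior_deltoid", "brachialis",
                "triceps_lateral", "biceps", "triceps_long",
                c("anterior_deltoid", "triceps_lateral"),
                c("posterior_deltoid", "brachialis"),
                c("anterior_deltoid", "brachialis"),
                c("posterior_deltoid", "triceps_lateral"),
                c("biceps", "triceps_long"))
  chan <- c(anterior_deltoid = "AD", posterior_deltoid = "PD",
            brachialis = "Br", triceps_lateral = "TLat",
            biceps = "Bi", triceps_long = "TLong")
  lapply(seq_along(marks), function(i) {
    list(id = i, muscles = marks[[i]], electrodes = unname(chan[marks[[i]]]),
         factor = 0.5, fatigue_rate = 0.005)
  })
}

#' Serialize a system and (optionally) its solution to JSON
#'
#' Debugging artifact: the equation system's rows, columns and, when given,
#' the solved scale factors, statuses and residuals.
#'
#' @param system an \code{fes_system}.
#' @param path JSON file path.
#' @param scales optional \code{fes_scales} for the same system.
#' @return the path, invisibly.
#' @export
write_system_json <- function(system, path, scales = NULL) {
  out <- list(config = system$config, S = system$S,
              rows = ROW_LABELS, electrodes = system$electrodes,
              x = unname(system$x), A = unname(system$A),
              adjustments = unname(system$adjustments),
              spillover = system$spillover)
  if (!is.null(scales)) {
    out$solution <- list(c = unname(scales$c), status = scales$status,
                         residual = unname(scales$residual),
                         residual_norm = scales$residual_norm,
                         feasible = scales$feasible)
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.fes_scales <- function(x, ...) {
  cat("<fes_scales> c = [", paste(sprintf("%.4f", x$c), collapse = ", "),
      "]\n  status:", paste(x$status, collapse = ", "),
      "\n  residual norm:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' @export
print.fes_system <- function(x, ...) {
  cat("<fes_system> config (", x$config[1], ",", x$config[2], ") deg, S =",
      x$S, "Nm\n")
  print(cbind(x = x$x, x$A))
  invisible(x)
}
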