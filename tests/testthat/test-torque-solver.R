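test_that("build_system assembles x and A with the documented layout", {
  cal <- calib20()
  # zero-passive analogue: mid-workspace passives are ~0.3 Nm, so check the
  # algebra exactly against the stored calibration records
  sys <- build_system(c(55, 80), 8, cal)
  node <- which(cal$configs[, 1] == 55 & cal$configs[, 2] == 80)
  expect_equal(unname(sys$x),
               c(8 - cal$passive[node, 1, 1], -8 - cal$passive[node, 1, 2],
                 8 - cal$passive[node, 2, 1], -8 - cal$passive[node, 2, 2]))
  expect_equal(unname(sys$A), unname(cal$A[, , node]))
  # biceps column is nonzero exactly in the two flexion rows
  expect_true(all(sys$A[c(1, 3), "Bi"] > 0))
  expect_true(all(sys$A[c(2, 4), "Bi"] == 0))
  # at least half of A is zeros (each muscle flexes or extends, never both)
  expect_gte(mean(sys$A == 0), 0.5)
  # adjustment factors scale exactly one column
  adj <- build_system(c(55, 80), 8, cal, adjustments = c(0.5, 1, 1, 1, 1, 1))
  expect_equal(adj$A[, "AD"], sys$A[, "AD"] * 0.5)
  expect_equal(adj$A[, -1], sys$A[, -1])
  expect_error(build_system(c(55, 80), 0, cal), "positive")
  expect_error(build_system(c(55, 80), -2, cal), "positive")
  expect_error(build_system(c(200, 80), 8, cal), "outside")
  expect_error(build_system(c(55, 80), 8, cal, adjustments = rep(0, 6)),
               "\\(0, 1\\]")
})

test_that("bounded min-norm solve matches closed-form Lagrange solutions", {
  # one joint, two flexors (10, 10), one extensor (-15), targets (5, -5):
  # per independent row c_i = a_i * T / sum(a^2)
  sys <- list(A = rbind(c(10, 10, 0), c(0, 0, -15),
                        c(0, 0, 0), c(0, 0, 0)),
              x = c(5, -5, 0, 0))
  sol <- solve_bounded_min_norm(sys)
  expect_equal(unname(sol$c), c(0.25, 0.25, 1 / 3), tolerance = 1e-12)
  expect_lt(sol$residual_norm, 1e-12)
  expect_identical(sol$status, rep("interior", 3))

  # forced saturation: single flexor max 10, target 12
  sys2 <- list(A = rbind(10, 0, 0, 0), x = c(12, 0, 0, 0))
  sol2 <- solve_bounded_min_norm(sys2)
  expect_equal(unname(sol2$c), 1)
  expect_identical(sol2$status, "clamped_one")
  expect_equal(sol2$residual_norm, 2)
  expect_false(sol2$feasible)

  # S below net passive flexion torque: flexion target negative with only a
  # flexor in that row -> clamped to zero and flagged infeasible
  sys3 <- list(A = rbind(c(10, 0), c(0, -15), 0, 0), x = c(-2, -5, 0, 0))
  sol3 <- solve_bounded_min_norm(sys3)
  expect_equal(unname(sol3$c), c(0, 1 / 3))
  expect_identical(sol3$status[1], "clamped_zero")
  expect_equal(sol3$residual_norm, 2)

  # degenerate zero column is dropped before solving
  sys4 <- list(A = rbind(c(10, 0), c(0, 0), 0, 0), x = c(5, 0, 0, 0))
  sol4 <- solve_bounded_min_norm(sys4)
  expect_identical(sol4$status, c("interior", "dropped"))
  expect_equal(unname(sol4$c), c(0.5, 0))
})

test_that("bounds are always respected and the residual is reported on the full system", {
  set.seed(301)
  for (i in 1:50) {
    s <- random_system()
    sol <- solve_bounded_min_norm(s)
    expect_true(all(sol$c >= 0 & sol$c <= 1))
    expect_equal(sol$residual_norm,
                 sqrt(sum((s$A %*% sol$c - s$x)^2)), tolerance = 1e-10)
  }
})

test_that("bounded solve matches the projected-gradient box-QP oracle", {
  set.seed(117)
  n_checked <- 0
  for (i in 1:60) {
    s <- random_system()
    sol <- solve_bounded_min_norm(s)
    qp <- solve_box_qp(s$A, s$x)
    expect_lt(abs(sol$residual_norm - qp$residual_norm), 1e-6)
    if (sol$residual_norm < 1e-9 && !is.null(qp$c_min_norm)) {
      n_checked <- n_checked + 1
      expect_lt(abs(sqrt(sum(sol$c^2)) - sqrt(sum(qp$c_min_norm^2))), 1e-6)
    }
  }
  expect_gt(n_checked, 10)
})

test_that("one-directional clamping is never better than the QP and can be worse on under-powered systems", {
  # documented limitation: when a row's demand exceeds the total capacity of
  # its columns, the clamp-at-one-never-unclamp pass can end above the true
  # box-constrained optimum.  It must never end below it.
  set.seed(902)
  weak <- function() {
    A <- matrix(0, 4, 4)
    A[1, 1] <- runif(1, 3, 8); A[2, 2] <- -runif(1, 3, 8)
    A[3, 3] <- runif(1, 3, 8); A[4, 4] <- -runif(1, 3, 8)
    A <- cbind(A, c(runif(1, 2, 5), 0, runif(1, 3, 8), 0))
    S <- runif(1, 8, 13)
    list(A = A, x = c(S, -S, S, -S))
  }
  gaps <- vapply(1:40, function(i) {
    s <- weak()
    solve_bounded_min_norm(s)$residual_norm - solve_box_qp(s$A, s$x)$residual_norm
  }, 0)
  expect_true(all(gaps > -1e-6))   # heuristic never beats the optimum
})

test_that("torque balance holds exactly for interior solutions", {
  cal <- calib20()
  set.seed(12)
  for (i in 1:20) {
    cfg <- c(runif(1, 15, 75), runif(1, 20, 120))
    S <- sample(3:13, 1)
    sys <- build_system(cfg, S, cal)
    sol <- solve_bounded_min_norm(sys)
    if (!all(sol$status == "interior")) next
    pred <- drop(sys$A %*% sol$c)
    # flexion-side active torques sum to S - Pf, extension to -S - Pe
    expect_equal(unname(pred), unname(sys$x), tolerance = 1e-9)
  }
})

test_that("spillover iteration reproduces the worked ratio-update example", {
  sys <- fig3c_system()
  # initial parameterization: the non-reference (shoulder) entry is 50% of
  # the reference maximum, and the first minimum-norm solve lands at c = 0.9
  sol0 <- solve_bounded_min_norm(sys)
  expect_equal(unname(sol0$c), 0.9, tolerance = 1e-12)
  # at the stimulation giving 90% of the reference torque (u = 0.9), the
  # shoulder curve delivers only 20%: the next pass must use 0.2 * max_ref
  one_pass <- iterate_spillover(sys, max_iter = 2L)
  expect_equal(unname(one_pass$system$A[1, 1]), 0.2 * 10, tolerance = 1e-6)
  # run to convergence: the curve-aware residual drops across iterations
  it <- iterate_spillover(sys)
  expect_true(it$converged)
  expect_lt(it$final_residual, it$initial_residual)
})

test_that("uniform-ratio electrodes converge in one iteration with entries unchanged", {
  cal <- calib20()          # no spillover flagged on the default arm
  sys <- build_system(c(55, 80), 8, cal)
  it <- iterate_spillover(sys)
  expect_identical(it$iterations, 1L)
  expect_true(it$converged)
  expect_equal(it$system$A, sys$A)
  expect_lt(it$final_residual, 1e-6)
})

test_that("spillover iteration converges and reduces the curve-aware residual", {
  armA <- make_spillover_arm("A")
  calA <- calibrate(armA, sampling_grid(step = 20, stiffness = c(4, 8, 12)))
  n_it <- c()
  for (cfg in list(c(35, 60), c(55, 100))) {
    for (S in c(4, 8, 12)) {
      sys <- build_system(cfg, S, calA)
      it <- iterate_spillover(sys)
      expect_true(it$converged)
      expect_lte(it$final_residual, it$initial_residual + 1e-9)
      n_it <- c(n_it, it$iterations)
    }
  }
  expect_gt(max(n_it), 1)   # the ratio update is actually exercised
  # first-pass curve-aware residual is strictly positive (the motivation)
  sys <- build_system(c(55, 100), 8, calA)
  first <- residual_torques(sys, solve_bounded_min_norm(sys)$c,
                            use_curves = TRUE)
  expect_gt(first$norm, 1e-3)
})

test_that("residual_torques validates input and matches the linear prediction", {
  cal <- calib20()
  sys <- build_system(c(55, 80), 8, cal)
  sol <- solve_bounded_min_norm(sys)
  lin <- residual_torques(sys, sol$c)
  expect_lt(lin$norm, 1e-9)
  # curve-aware residual agrees for the uniform default arm
  crv <- residual_torques(sys, sol$c, use_curves = TRUE)
  expect_lt(crv$norm, 1e-6)
  expect_error(residual_torques(sys, sol$c + 2), "\\[0, 1\\]")
})

test_that("rebalancing shifts work with exact stimulation-conversion bookkeeping", {
  # closed-form: one joint, flexors (10, 10), target 8, alpha = (0.5, 1)
  # -> scaled maxima (5, 10), c = a T / sum(a^2) = (0.32, 0.64),
  # realized torques (1.6, 6.4) still summing to 8
  sys <- list(A = rbind(c(5, 10), 0, 0, 0), x = c(8, 0, 0, 0))
  sol <- solve_bounded_min_norm(sys)
  expect_equal(unname(sol$c), c(0.32, 0.64), tolerance = 1e-12)
  expect_equal(unname(sol$c * c(0.5, 1) * c(10, 10)), c(1.6, 6.4))

  cal <- calib20()
  # alpha = 1 is the identity
  t_std <- build_initial_table(cal, 8)
  t_id <- build_initial_table(rebalance(cal, rep(1, 6)), 8)
  expect_equal(t_id$u, t_std$u, tolerance = 1e-12)
  # biceps + triceps long head at 0.5: both biarticular columns halved in
  # every row they occupy
  reb <- rebalance(cal, c(Bi = 0.5, TLong = 0.5))
  sys_reb <- build_system(c(55, 80), 8, cal, adjustments = reb$adjustments)
  sys_std <- build_system(c(55, 80), 8, cal)
  expect_equal(sys_reb$A[, c("Bi", "TLong")],
               sys_std$A[, c("Bi", "TLong")] * 0.5)
  expect_equal(sys_reb$A[, 1:4], sys_std$A[, 1:4])
  expect_error(rebalance(cal, c(Bi = 0)), "\\(0, 1\\]")
  expect_error(rebalance(cal, c(nope = 0.5)), "unknown electrode")
})

test_that("rebalanced tables never undercut the minimum-norm cost", {
  cal <- calib20()
  t_std <- build_initial_table(cal, c(5, 8, 11))
  for (sc in fatigue_scenarios()[c(1, 5, 11)]) {
    fac <- stats::setNames(rep(sc$factor, length(sc$electrodes)),
                           sc$electrodes)
    t_reb <- build_initial_table(rebalance(cal, fac), c(5, 8, 11))
    # the adjusted coefficients, mapped back to the original system scale
    # (c_eff = c * alpha per electrode), can never have smaller norm than
    # the true minimum-norm solution of the original system
    n <- prod(dim(t_std$u)[1:3])
    ok <- as.vector(t_std$feasible & t_reb$feasible)
    c_std <- matrix(t_std$c, n, 6)
    adj <- t_reb$adjustments
    c_eff <- sweep(matrix(t_reb$c, n, 6), 2, adj, "*")
    expect_true(all(rowSums(c_eff[ok, ]^2) >=
                      rowSums(c_std[ok, ]^2) - 1e-9))
  }
})

test_that("the eleven fatigue scenarios mark the published muscle sets", {
  sc <- fatigue_scenarios()
  expect_length(sc, 11)
  expect_true(all(vapply(sc[1:6], function(s) length(s$muscles), 0) == 1))
  expect_true(all(vapply(sc[7:11], function(s) length(s$muscles), 0) == 2))
  expect_identical(sc[[11]]$electrodes, c("Bi", "TLong"))
  expect_identical(sc[[7]]$electrodes, c("AD", "TLat"))
  expect_true(all(vapply(sc, function(s) s$factor, 0) == 0.5))
  expect_true(all(vapply(sc, function(s) s$fatigue_rate, 0) == 0.005))
})
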