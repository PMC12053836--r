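# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_arm <- function() fixture("arm", make_default_arm)

# 20-degree calibration of the default arm, stiffness 3..13 Nm
calib20 <- function() {
  fixture("calib20", function() {
    calibrate(default_arm(), sampling_grid(step = 20, stiffness = 3:13))
  })
}

# 20-degree initial table over the full stiffness range
table20 <- function() {
  fixture("table20", function() build_initial_table(calib20(), 3:13))
}

# random torque-balance system with the structure of a plausible arm:
# one monoarticular channel per flexion/extension row (peaks 20-40 Nm),
# plus 0-2 biarticular channels (15-30 Nm, shoulder fraction 0.2-0.6)
random_system <- function() {
  A <- matrix(0, 4, 4)
  A[1, 1] <- runif(1, 20, 40); A[2, 2] <- -runif(1, 20, 40)
  A[3, 3] <- runif(1, 20, 40); A[4, 4] <- -runif(1, 20, 40)
  nb <- sample(0:2, 1)
  if (nb >= 1) {
    mag <- runif(1, 15, 30)
    A <- cbind(A, c(mag * runif(1, 0.2, 0.6), 0, mag, 0))
  }
  if (nb == 2) {
    mag <- runif(1, 15, 30)
    A <- cbind(A, c(0, -mag * runif(1, 0.2, 0.6), 0, -mag))
  }
  S <- runif(1, 3, 13)
  Pf <- runif(2, 0, 4); Pe <- -runif(2, 0, 4)
  list(A = A, x = c(S - Pf[1], -S - Pe[1], S - Pf[2], -S - Pe[2]), S = S)
}

# hand-built 4-row system around a single electrode with a known spillover
# curve: reference (elbow) torque linear 0..10 Nm in u; the other joint's
# torque passes through 50% of the reference max at u = 1 but only 20% of the
# reference torque at the stimulation giving 90% of the reference max.
fig3c_system <- function() {
  u_levels <- seq(0, 1, by = 0.05)
  ref <- 10 * u_levels                               # elbow flexion
  oth <- ifelse(u_levels <= 0.9, 2 * u_levels,       # shoulder flexion
                1.8 + 32 * (u_levels - 0.9))         # late surge to 5 Nm
  curves <- array(0, c(1, length(u_levels), 2))
  curves[1, , 1] <- oth   # shoulder
  curves[1, , 2] <- ref   # elbow
  A <- matrix(c(5, 0, 10, 0), 4, 1,
              dimnames = list(c("sho_flex", "sho_ext", "elb_flex", "elb_ext"),
                              "SP"))
  structure(list(x = c(0.9 * 5, 0, 0.9 * 10, 0), A = A, S = NA,
                 config = c(50, 75), adjustments = 1,
                 A_unadjusted = A, curves = curves, u_levels = u_levels,
                 spillover = TRUE, electrodes = "SP"),
            class = "fes_system")
}
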