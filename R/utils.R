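# Small numeric helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180

#' Minimum-norm least-squares solve via singular value decomposition
#'
#' Returns the least-squares solution of smallest Euclidean norm to
#' \code{A x = b}, discarding singular values below \code{tol} times the
#' largest singular value.  This is the unconstrained core of the bounded
#' torque-distribution solver.
#'
#' @param A numeric matrix.
#' @param b numeric right-hand side.
#' @param tol relative singular-value cutoff (default \code{1e-12}).
#' @return numeric vector of length \code{ncol(A)}.
#' @keywords internal
pinv_min_norm <- function(A, b, tol = 1e-12) {
  if (ncol(A) == 0L) return(numeric(0))
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(numeric(ncol(A)))
  dinv <- ifelse(keep, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * crossprod(sv$u, b)))
}

# Piecewise-linear interpolation with linear extrapolation beyond the ends.
# `y` may be a vector or a matrix with one row per knot.
lin_interp <- function(x, y, xout) {
  y <- as.matrix(y)
  n <- length(x)
  if (n == 1L) {
    out <- y[rep(1L, length(xout)), , drop = FALSE]
    return(if (ncol(out) == 1L) drop(out) else out)
  }
  i <- findInterval(xout, x, all.inside = TRUE)
  t <- (xout - x[i]) / (x[i + 1L] - x[i])
  out <- y[i, , drop = FALSE] * (1 - t) + y[i + 1L, , drop = FALSE] * t
  if (ncol(out) == 1L) drop(out) else out
}

# Minimum-jerk ("bell") speed profile covering distance d in time T.
minjerk_speed <- function(t, T, d) {
  tau <- clamp(t / T, 0, 1)
  (d / T) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
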