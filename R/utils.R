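# Internal numeric helpers: truncated draws, rotations, seeds.

#' @keywords internal
#' @noRd
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, pa, pb)
  stats::qnorm(u, mean, sd)
}

# Integer counts: normal draw, rounded, clipped to [lower, upper].
#' @noRd
rcount <- function(n, mean, sd, lower = 0, upper = Inf) {
  pmin(pmax(round(stats::rnorm(n, mean, sd)), lower), upper)
}

# Folded draw for unsigned in-plane angles: |N(mean, sd)|, so the measured
# unsigned angle recovers the configured mean with negligible bias.
#' @noRd
rangle <- function(n, mean, sd) {
  a <- abs(stats::rnorm(n, mean, sd))
  pmin(a, 89.9)
}

#' @noRd
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

# Rodrigues rotation matrix for axis (unit) and angle (radians).
#' @noRd
rotation_axis_angle <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Minimal rotation carrying unit vector `from` onto unit vector `to`.
#' @noRd
rotation_between <- function(from, to) {
  f <- unit(from); t <- unit(to)
  c_ <- sum(f * t)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # antipodal: rotate by pi about any axis orthogonal to `from`
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(pracma_cross(f, ref))
    return(rotation_axis_angle(ax, pi))
  }
  ax <- pracma_cross(f, t)
  rotation_axis_angle(unit(ax), acos(pmin(pmax(c_, -1), 1)))
}

#' @noRd
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# z-y-z Euler angles (radians) to rotation matrix.
#' @noRd
rotation_euler_zyz <- function(alpha, beta, gamma) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

# Geodesic angle (radians) of a rotation matrix / between two rotations.
#' @noRd
rotation_angle <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
}

#' @noRd
rotation_distance <- function(R1, R2) rotation_angle(t(R1) %*% R2)

# Deterministic child seed from a master seed and a stage index; stays
# within 32-bit integer range.
#' @noRd
child_seed <- function(master, stage) {
  as.integer((as.numeric(master) %% 65521L) * 31721 + stage * 7919) %% 2147483629L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition constructors with distinct classes for programmatic handling.
#' @noRd
azm_error <- function(msg, class) {
  stop(structure(
    class = c(class, "azm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
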