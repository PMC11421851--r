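#' Planar two-link arm parameters
#'
#' Constructs the parameter set of the planar two-jointed arm used as the
#' effector in the reaching tasks: link lengths, masses, moments of inertia,
#' the distance from the elbow to the forearm's center of mass, and a
#' symmetric joint-friction matrix. Defaults are the standard values used
#' throughout the reaching experiments.
#'
#' @param L1,L2 Link lengths in meters (upper arm, forearm).
#' @param M1,M2 Link masses in kg.
#' @param I1,I2 Moments of inertia in kg m^2.
#' @param D2 Distance from the elbow to the forearm center of mass (m).
#' @param B 2x2 symmetric positive-definite joint friction matrix (N m s).
#'
#' @return An object of class `arm_params` (a named list).
#' @export
#' @examples
#' p <- arm_params()
#' forward_kinematics(c(0, 0), p)
arm_params <- function(L1 = 0.30, L2 = 0.30,
                       M1 = 1.4, M2 = 1.0,
                       I1 = 0.025, I2 = 0.045,
                       D2 = 0.16,
                       B = matrix(c(0.05, 0.025, 0.025, 0.05), 2, 2)) {
  stopifnot(L1 > 0, L2 > 0, M1 > 0, M2 > 0, I1 > 0, I2 > 0, D2 > 0)
  B <- as.matrix(B)
  if (!isTRUE(all.equal(B, t(B))) || any(eigen(B, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("B must be symmetric positive definite")
  structure(list(L1 = L1, L2 = L2, M1 = M1, M2 = M2, I1 = I1, I2 = I2,
                 D2 = D2, B = B,
                 # inertia shorthands; a1 + 2*a2*cos(th2) etc. build M(theta)
                 a1 = I1 + I2 + M2 * L1^2,
                 a2 = M2 * L1 * D2,
                 a3 = I2),
            class = "arm_params")
}

#' @export
print.arm_params <- function(x, ...) {
  cat("Planar two-link arm:\n")
  cat(sprintf("  L1=%.2f m  L2=%.2f m  M1=%.2f kg  M2=%.2f kg\n", x$L1, x$L2, x$M1, x$M2))
  cat(sprintf("  I1=%.3f  I2=%.3f kg m^2  D2=%.2f m\n", x$I1, x$I2, x$D2))
  invisible(x)
}

#' Forward kinematics of the two-link arm
#'
#' Maps joint angles to hand and elbow positions in shoulder-centered
#' Cartesian coordinates.
#'
#' @param theta Numeric length-2 vector of joint angles (shoulder, elbow), rad.
#' @param params An [arm_params()] object.
#'
#' @return List with `hand` and `elbow`, each a length-2 numeric vector (m).
#' @export
forward_kinematics <- function(theta, params = arm_params()) {
  stopifnot(length(theta) == 2, all(is.finite(theta)))
  elbow <- c(params$L1 * cos(theta[1]), params$L1 * sin(theta[1]))
  hand <- elbow + c(params$L2 * cos(theta[1] + theta[2]),
                    params$L2 * sin(theta[1] + theta[2]))
  list(hand = hand, elbow = elbow)
}

#' Inverse kinematics of the two-link arm
#'
#' Converts a Cartesian hand target into joint angles. Two solutions exist
#' for any interior point of the annular workspace; `branch` selects the sign
#' of the elbow angle ("down" gives theta2 <= 0).
#'
#' @param hand Length-2 numeric target hand position (m).
#' @param params An [arm_params()] object.
#' @param branch `"down"` (elbow angle <= 0) or `"up"`.
#'
#' @return Length-2 numeric vector of joint angles (rad).
#' @export
inverse_kinematics <- function(hand, params = arm_params(), branch = c("down", "up")) {
  branch <- match.arg(branch)
  stopifnot(length(hand) == 2, all(is.finite(hand)))
  d2 <- sum(hand^2)
  L1 <- params$L1; L2 <- params$L2
  if (d2 == 0 || sqrt(d2) > L1 + L2 + 1e-12)
    stop("target outside the arm workspace (annulus 0 < ||p|| <= L1+L2)")
  c2 <- (d2 - L1^2 - L2^2) / (2 * L1 * L2)
  c2 <- min(1, max(-1, c2))
  th2 <- acos(c2)
  if (sqrt(d2) < abs(L1 - L2) - 1e-12)
    stop("target outside the arm workspace (annulus 0 < ||p|| <= L1+L2)")
  if (branch == "down") th2 <- -th2
  th1 <- atan2(hand[2], hand[1]) - atan2(L2 * sin(th2), L1 + L2 * cos(th2))
  c(th1, th2)
}

# Inertia matrix M(theta); depends on the elbow angle only.
arm_inertia <- function(theta2, params) {
  a1 <- params$a1; a2 <- params$a2; a3 <- params$a3
  c2 <- cos(theta2)
  matrix(c(a1 + 2 * a2 * c2, a3 + a2 * c2,
           a3 + a2 * c2, a3), 2, 2)
}

# Centripetal/Coriolis term X(theta, thetadot).
arm_coriolis <- function(theta2, dtheta, params) {
  params$a2 * sin(theta2) *
    c(-dtheta[2] * (2 * dtheta[1] + dtheta[2]), dtheta[1]^2)
}

#' Joint-space acceleration of the arm
#'
#' Solves the rigid-body equation m = M(theta) thetaddot + X(theta, thetadot)
#' + B thetadot for the angular acceleration, given joint torques.
#'
#' @param theta,dtheta Joint angles (rad) and velocities (rad/s), length 2.
#' @param torque Length-2 joint torque vector (N m).
#' @param params An [arm_params()] object.
#'
#' @return Length-2 angular acceleration (rad/s^2).
#' @export
arm_acceleration <- function(theta, dtheta, torque, params = arm_params()) {
  M <- arm_inertia(theta[2], params)
  X <- arm_coriolis(theta[2], dtheta, params)
  drop(solve(M, torque - X - params$B %*% dtheta))
}

#' Partial derivatives of the arm acceleration
#'
#' Analytic Jacobians of [arm_acceleration()] with respect to joint angles,
#' joint velocities, and torques, used to linearize the arm inside the
#' trajectory optimizer. The dynamics depend on `theta` only through the
#' elbow angle, so the first column of `dtheta` (shoulder) is zero.
#'
#' @inheritParams arm_acceleration
#' @return List with 2x2 matrices `dth` (w.r.t. theta), `ddth` (w.r.t.
#'   thetadot) and `dm` (w.r.t. torque).
#' @export
arm_jacobians <- function(theta, dtheta, torque, params = arm_params()) {
  a2 <- params$a2
  s2 <- sin(theta[2]); c2 <- cos(theta[2])
  M <- arm_inertia(theta[2], params)
  Minv <- solve(M)
  X <- arm_coriolis(theta[2], dtheta, params)
  acc <- drop(Minv %*% (torque - X - params$B %*% dtheta))

  dM_dth2 <- a2 * s2 * matrix(c(-2, -1, -1, 0), 2, 2)
  dX_dth2 <- a2 * c2 * c(-dtheta[2] * (2 * dtheta[1] + dtheta[2]), dtheta[1]^2)
  dacc_dth2 <- drop(-Minv %*% (dM_dth2 %*% acc + dX_dth2))
  dth <- cbind(c(0, 0), dacc_dth2)

  dX_ddth <- a2 * s2 * matrix(c(-2 * dtheta[2], 2 * dtheta[1],
                                -2 * (dtheta[1] + dtheta[2]), 0), 2, 2)
  ddth <- -Minv %*% (dX_ddth + params$B)

  list(dth = dth, ddth = ddth, dm = Minv)
}

#' Radial reach targets around a start point
#'
#' Places `n` targets uniformly on a circle of radius `r` around the hand's
#' start position and converts both start and targets to joint angles.
#'
#' @param n Number of targets.
#' @param r Circle radius (m). Typical values are 0.12 or 0.20.
#' @param center Hand start position (m) in shoulder coordinates.
#' @param params An [arm_params()] object.
#' @param branch Elbow branch passed to [inverse_kinematics()].
#'
#' @return List with `theta0` (start angles), `targets` (n x 2 matrix of
#'   joint-angle targets), `hand0`, and `hand_targets` (n x 2, m).
#' @export
reach_target_set <- function(n = 8, r = 0.12, center = c(0, 0.30),
                             params = arm_params(), branch = "down") {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  hand_targets <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  theta0 <- inverse_kinematics(center, params, branch)
  targets <- t(apply(hand_targets, 1, inverse_kinematics,
                     params = params, branch = branch))
  list(theta0 = theta0, targets = targets,
       hand0 = center, hand_targets = hand_targets)
}
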