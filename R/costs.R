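#' Delayed-reach control task
#'
#' Specifies one delayed center-out reach: the delay (preparation) duration,
#' the movement-epoch duration, start and target postures in joint space,
#' and the cost weights. Control inputs are allowed on the whole window
#' `[-delta_prep, T_move]`, with the go cue at t = 0. The target term
#' carries an urgency weight `(t/T)^2` that grows quadratically through the
#' movement epoch; the null term penalizes hand motion (posture deviation,
#' joint velocity, and torque) during the delay; the effort term penalizes
#' squared input magnitude throughout.
#'
#' @param delta_prep Delay duration (ms, >= 0).
#' @param T_move Movement-epoch duration (ms, > 0).
#' @param theta0 Length-2 start posture (rad).
#' @param theta_star Length-2 target posture (rad).
#' @param alpha_null Weight of the premature-movement penalty.
#' @param alpha_effort Weight of the input-energy penalty.
#'
#' @return Object of class `reach_task`.
#' @export
reach_task <- function(delta_prep = 300, T_move = 900,
                       theta0, theta_star,
                       alpha_null = 1, alpha_effort = 5e-7) {
  stopifnot(delta_prep >= 0, T_move > 0, alpha_null >= 0, alpha_effort >= 0,
            length(theta0) == 2, length(theta_star) == 2)
  structure(list(delta_prep = delta_prep, T_move = T_move,
                 theta0 = theta0, theta_star = theta_star,
                 alpha_null = alpha_null, alpha_effort = alpha_effort),
            class = "reach_task")
}

#' One-dimensional toy reach task
#'
#' The reduced task used with two-unit networks: the plant is a double
#' integrator whose acceleration is the network's 1D readout, and the
#' "hand" position y must move from 0 to `y_star`. Cost terms mirror the
#' arm task, with position/velocity/acceleration stillness penalties
#' during the delay and effort normalized by the two network units.
#'
#' @param delta_prep Delay duration (ms).
#' @param T_move Movement duration (ms).
#' @param y_star Target position (default 20).
#' @param alpha_null,alpha_effort Cost weights.
#' @return Object of class `toy_task`.
#' @export
toy_task <- function(delta_prep = 500, T_move = 900, y_star = 20,
                     alpha_null = 1, alpha_effort = 1e-5) {
  stopifnot(delta_prep >= 0, T_move > 0, alpha_null >= 0, alpha_effort >= 0)
  structure(list(delta_prep = delta_prep, T_move = T_move, y_star = y_star,
                 alpha_null = alpha_null, alpha_effort = alpha_effort),
            class = "toy_task")
}

#' Two-reach sequence task
#'
#' A sequence of two reaches: target 1 must be acquired within
#' `move1 + pause` ms of the go cue, the hand must stay still on it during
#' the pause window (`alpha_pause` on joint speed), and target 2 is then
#' acquired under a second urgency clock that starts at the end of the
#' pause. "Double" reaches use a long enforced pause (600 ms); "compound"
#' reaches use a token pause (6 ms) that merely makes the hand stop on the
#' intermediate target.
#'
#' @param delta_prep Delay duration (ms).
#' @param move1 Allotted duration of the first reach (ms).
#' @param pause Pause duration tau (ms).
#' @param T_total Total movement-epoch duration (ms), `> move1 + pause`.
#' @param theta0 Start posture (rad).
#' @param theta_star1,theta_star2 Joint-space targets of the two reaches.
#' @param alpha_null,alpha_effort,alpha_pause Cost weights.
#' @return Object of class `sequence_task`.
#' @export
sequence_task <- function(delta_prep = 500, move1 = 300, pause = 600,
                          T_total = 2000, theta0, theta_star1, theta_star2,
                          alpha_null = 10, alpha_effort = 5e-7,
                          alpha_pause = 100) {
  stopifnot(delta_prep >= 0, move1 > 0, pause >= 0, move1 + pause < T_total,
            length(theta_star1) == 2, length(theta_star2) == 2)
  structure(list(delta_prep = delta_prep, move1 = move1, pause = pause,
                 T_move = T_total, theta0 = theta0,
                 theta_star1 = theta_star1, theta_star2 = theta_star2,
                 alpha_null = alpha_null, alpha_effort = alpha_effort,
                 alpha_pause = alpha_pause),
            class = "sequence_task")
}

new_cost_breakdown <- function(J_target, J_null, J_effort, J_pause = 0) {
  structure(list(J_target = J_target, J_null = J_null, J_effort = J_effort,
                 J_pause = J_pause,
                 J_total = J_target + J_null + J_effort + J_pause),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("cost: total %.6g (target %.4g | null %.4g | effort %.4g | pause %.4g)\n",
              x$J_total, x$J_target, x$J_null, x$J_effort, x$J_pause))
  invisible(x)
}

# Left-endpoint step times on [-delta_prep, T); a step with time < 0 belongs
# to the delay epoch, time >= 0 (go-cue sample included) to movement.
step_times <- function(delta_prep, T_move, dt) {
  H <- round((delta_prep + T_move) / dt)
  seq(-delta_prep, by = dt, length.out = H)
}

#' Cost breakdown of a single delayed reach
#'
#' Evaluates the three cost terms on a discretized trajectory as Riemann
#' sums: the urgency-weighted target error `sum ||theta - theta*||^2
#' (t/T)^2 dt/T` over the movement epoch, the stillness penalty
#' `alpha_null sum (||theta - theta0||^2 + ||thetadot||^2 + ||m||^2) dt/T`
#' over the delay, and the effort `alpha_effort sum ||u||^2 dt/(N T)` over
#' the full window.
#'
#' @param traj Trajectory list with per-step (left-endpoint) rows: `time`
#'   (ms, relative to go cue), `theta`, `dtheta` (H x 2), `m` (H x 2
#'   torques), `u` (H x N inputs), and the step `dt` (ms).
#' @param task A [reach_task()].
#' @return A `cost_breakdown`.
#' @export
single_reach_cost <- function(traj, task) {
  stopifnot(inherits(task, "reach_task"))
  tt <- traj$time
  dt <- traj$dt
  Tm <- task$T_move
  if (abs(length(tt) * dt - (task$delta_prep + Tm)) > dt / 2)
    stop("trajectory window does not match the task window")
  mov <- tt >= 0
  del <- tt <= dt * 1e-9    # stillness window is closed at the go cue
  err <- sweep(traj$theta, 2, task$theta_star)
  J_target <- sum(rowSums(err[mov, , drop = FALSE]^2) *
                    (tt[mov] / Tm)^2) * dt / Tm
  dev <- sweep(traj$theta, 2, task$theta0)
  J_null <- task$alpha_null * sum(rowSums(dev[del, , drop = FALSE]^2) +
                                    rowSums(traj$dtheta[del, , drop = FALSE]^2) +
                                    rowSums(traj$m[del, , drop = FALSE]^2)) * dt / Tm
  N <- ncol(traj$u)
  J_effort <- task$alpha_effort * sum(traj$u^2) * dt / (N * Tm)
  new_cost_breakdown(J_target, J_null, J_effort)
}

#' Cost breakdown of the 1D toy reach
#'
#' As [single_reach_cost()], for the 1D output: the null term penalizes
#' position, velocity, and acceleration of the output during the delay, and
#' the effort normalizer is the number of network units (2).
#'
#' @param traj Trajectory list with `time`, `dt`, `y`, `v` (dy/dt), `ydd`
#'   (d2y/dt2, the network readout), `u` (H x 2).
#' @param task A [toy_task()].
#' @return A `cost_breakdown`.
#' @export
toy_reach_cost <- function(traj, task) {
  stopifnot(inherits(task, "toy_task"))
  tt <- traj$time
  dt <- traj$dt
  Tm <- task$T_move
  mov <- tt >= 0
  del <- tt <= dt * 1e-9    # stillness window is closed at the go cue
  J_target <- sum((traj$y[mov] - task$y_star)^2 * (tt[mov] / Tm)^2) * dt / Tm
  J_null <- task$alpha_null *
    sum(traj$y[del]^2 + traj$v[del]^2 + traj$ydd[del]^2) * dt / Tm
  N <- ncol(traj$u)
  J_effort <- task$alpha_effort * sum(traj$u^2) * dt / (N * Tm)
  new_cost_breakdown(J_target, J_null, J_effort)
}

#' Cost breakdown of a two-reach sequence
#'
#' Target 1 carries the urgency weight `(t/T)^2` on `[0, move1 + pause]`;
#' the pause term penalizes joint speed on `[move1, move1 + pause]`; target
#' 2 carries the restarted urgency weight `((t - move1 - pause)/T)^2` on
#' the remainder. Delay stillness and effort are as in the single reach,
#' and all terms use the single-reach normalization (`dt/T`,
#' `dt/(N T)`) so weights are comparable across tasks.
#'
#' @param traj Trajectory as in [single_reach_cost()].
#' @param task A [sequence_task()].
#' @return A `cost_breakdown` (with `J_target` the sum of both targets'
#'   terms and `J_pause` separate).
#' @export
sequence_cost <- function(traj, task) {
  stopifnot(inherits(task, "sequence_task"))
  tt <- traj$time
  dt <- traj$dt
  Tm <- task$T_move
  t_sw <- task$move1 + task$pause
  del <- tt <= dt * 1e-9    # stillness window is closed at the go cue
  seg1 <- tt >= 0 & tt < t_sw
  pauz <- tt >= task$move1 & tt < t_sw
  seg2 <- tt >= t_sw
  err1 <- sweep(traj$theta, 2, task$theta_star1)
  err2 <- sweep(traj$theta, 2, task$theta_star2)
  J_t1 <- sum(rowSums(err1[seg1, , drop = FALSE]^2) * (tt[seg1] / Tm)^2) * dt / Tm
  J_t2 <- sum(rowSums(err2[seg2, , drop = FALSE]^2) *
                ((tt[seg2] - t_sw) / Tm)^2) * dt / Tm
  J_pause <- task$alpha_pause *
    sum(rowSums(traj$dtheta[pauz, , drop = FALSE]^2)) * dt / Tm
  dev <- sweep(traj$theta, 2, task$theta0)
  J_null <- task$alpha_null * sum(rowSums(dev[del, , drop = FALSE]^2) +
                                    rowSums(traj$dtheta[del, , drop = FALSE]^2) +
                                    rowSums(traj$m[del, , drop = FALSE]^2)) * dt / Tm
  N <- ncol(traj$u)
  J_effort <- task$alpha_effort * sum(traj$u^2) * dt / (N * Tm)
  new_cost_breakdown(J_t1 + J_t2, J_null, J_effort, J_pause)
}
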