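# Per-step cost weight schedules shared by the problem builders and by the
# trajectory cost functions. Times are left endpoints (ms, go cue at 0).
reach_weights <- function(task, dt) {
  tt <- step_times(task$delta_prep, task$T_move, dt)
  Tm <- task$T_move
  if (inherits(task, "sequence_task")) {
    t_sw <- task$move1 + task$pause
    seg2 <- tt >= t_sw
    wtgt <- ifelse(tt < 0, 0,
                   ifelse(seg2, ((tt - t_sw) / Tm)^2, (tt / Tm)^2)) * dt / Tm
    wpause <- ifelse(tt >= task$move1 & tt < t_sw,
                     task$alpha_pause * dt / Tm, 0)
    tgt_is_second <- seg2
  } else {
    wtgt <- ifelse(tt < 0, 0, (tt / Tm)^2) * dt / Tm
    wpause <- rep(0, length(tt))
    tgt_is_second <- rep(FALSE, length(tt))
  }
  # stillness is enforced on the closed interval up to and including the go
  # cue, so the state seeded by the last delay-epoch input is itself
  # penalized if it moves the hand
  wnull <- ifelse(tt <= dt * 1e-9, task$alpha_null * dt / Tm, 0)
  list(time = tt, H = length(tt), wtgt = wtgt, wnull = wnull,
       wpause = wpause, tgt_is_second = tgt_is_second)
}

#' Build the network-plus-arm optimal control problem
#'
#' Augments the rate network with the two-link arm into a single
#' discrete-time plant (state `[x; theta; thetadot]`, Euler step `dt`) and
#' attaches the delayed-reach (or sequence) cost. Torques are read out as
#' deviations from baseline, `m = C (phi(x) - r_star)`, so that the
#' baseline firing pattern exerts no net torque and the resting arm is an
#' exact equilibrium of the coupled system.
#'
#' @param model A `network_model` with a 2-row readout and baseline set.
#' @param task A [reach_task()] or [sequence_task()].
#' @param dt Time step (ms).
#' @param params An [arm_params()] object.
#'
#' @return An [oc_problem()]; `meta` records the task, step times, and
#'   plant pieces needed to reconstruct trajectories.
#' @export
build_reach_problem <- function(model, task, dt = 10, params = arm_params()) {
  stopifnot(inherits(model, "network_model"),
            inherits(task, "reach_task") || inherits(task, "sequence_task"))
  N <- model$N
  C <- model$C
  if (is.null(C) || nrow(C) != 2)
    stop("the arm task needs a 2 x N readout")
  W <- model$W; h <- model$h; tau <- model$tau
  r0 <- model$r_star
  relu <- model$nonlinearity == "relu"
  dts <- dt / 1000                       # arm dynamics run in SI seconds
  ws <- reach_weights(task, dt)
  H <- ws$H
  weff <- task$alpha_effort * dt / (N * task$T_move)
  CtC <- crossprod(C)
  ix <- seq_len(N); ith <- N + 1:2; idth <- N + 3:4
  n <- N + 4
  fu <- rbind((dt / tau) * diag(N), matrix(0, 4, N))
  luu <- 2 * weff * diag(N)
  lux <- matrix(0, N, n)
  theta0 <- task$theta0
  tgt1 <- if (inherits(task, "sequence_task")) task$theta_star1 else task$theta_star
  tgt2 <- if (inherits(task, "sequence_task")) task$theta_star2 else task$theta_star

  dyn <- function(z, u, k) {
    x <- z[ix]; th <- z[ith]; dth <- z[idth]
    r <- if (relu) pmax(x, 0) else x
    m <- drop(C %*% (r - r0))
    acc <- arm_acceleration(th, dth, m, params)
    c(x + (dt / tau) * (-x + drop(W %*% r) + h + u),
      th + dts * dth,
      dth + dts * acc)
  }
  jac <- function(z, u, k) {
    x <- z[ix]; th <- z[ith]; dth <- z[idth]
    d <- if (relu) as.numeric(x > 0) else rep(1, N)
    r <- if (relu) pmax(x, 0) else x
    m <- drop(C %*% (r - r0))
    aj <- arm_jacobians(th, dth, m, params)
    fx <- matrix(0, n, n)
    fx[ix, ix] <- (dt / tau) * (W * rep(d, each = N))
    diag(fx)[ix] <- diag(fx)[ix] + (1 - dt / tau)
    fx[ith, ith] <- diag(2)
    fx[ith, idth] <- dts * diag(2)
    fx[idth, ix] <- dts * (aj$dm %*% (C * rep(d, each = 2)))
    fx[idth, ith] <- dts * aj$dth
    fx[idth, idth] <- diag(2) + dts * aj$ddth
    list(fx = fx, fu = fu)
  }
  cost <- function(z, u, k) {
    th <- z[ith]; dth <- z[idth]
    out <- weff * sum(u^2) + ws$wpause[k] * sum(dth^2)
    if (ws$wtgt[k] > 0) {
      tgt <- if (ws$tgt_is_second[k]) tgt2 else tgt1
      out <- out + ws$wtgt[k] * sum((th - tgt)^2)
    }
    if (ws$wnull[k] > 0) {
      x <- z[ix]
      r <- if (relu) pmax(x, 0) else x
      m <- drop(C %*% (r - r0))
      out <- out + ws$wnull[k] * (sum((th - theta0)^2) + sum(dth^2) + sum(m^2))
    }
    out
  }
  quad <- function(z, u, k) {
    th <- z[ith]; dth <- z[idth]
    wn <- ws$wnull[k]; wt <- ws$wtgt[k]; wp <- ws$wpause[k]
    lx <- rep(0, n)
    lxx <- matrix(0, n, n)
    if (wt > 0) {
      tgt <- if (ws$tgt_is_second[k]) tgt2 else tgt1
      lx[ith] <- lx[ith] + 2 * wt * (th - tgt)
    }
    lx[idth] <- 2 * (wn + wp) * dth
    diag(lxx)[idth] <- 2 * (wn + wp)
    diag(lxx)[ith] <- 2 * (wt + wn)
    if (wn > 0) {
      x <- z[ix]
      d <- if (relu) as.numeric(x > 0) else rep(1, N)
      r <- if (relu) pmax(x, 0) else x
      m <- drop(C %*% (r - r0))
      lx[ith] <- lx[ith] + 2 * wn * (th - theta0)
      lx[ix] <- 2 * wn * d * drop(crossprod(C, m))
      lxx[ix, ix] <- 2 * wn * (CtC * tcrossprod(d))
    }
    list(lx = lx, lu = 2 * weff * u, lxx = lxx, luu = luu, lux = lux)
  }
  x0 <- c(model$r_star, theta0, c(0, 0))
  oc_problem(dyn, jac, cost, quad, x0 = x0, H = H, n_input = N,
             lq = FALSE,
             meta = list(type = "arm", task = task, dt = dt, time = ws$time,
                         N = N, model = model, params = params))
}

#' Build the two-unit network + 1D double-integrator problem
#'
#' State `[x1; x2; y; v]` with linear network dynamics and output
#' acceleration equal to the 1D readout. The problem is linear-quadratic,
#' so the solver converges in a single backward/forward sweep.
#'
#' @param model A 2-unit `network_model` with a 1 x 2 readout and identity
#'   nonlinearity.
#' @param task A [toy_task()].
#' @param dt Time step (ms).
#' @return An [oc_problem()].
#' @export
build_toy_problem <- function(model, task, dt = 1) {
  stopifnot(inherits(model, "network_model"), inherits(task, "toy_task"),
            model$N == 2, model$nonlinearity == "identity",
            !is.null(model$C), nrow(model$C) == 1)
  W <- model$W; C <- model$C; tau <- model$tau
  dts <- dt / 1000
  ws <- reach_weights(task, dt)
  H <- ws$H
  weff <- task$alpha_effort * dt / (2 * task$T_move)
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- diag(2) + (dt / tau) * (-diag(2) + W)
  A[3, 3] <- 1; A[3, 4] <- dts
  A[4, 1:2] <- dts * C; A[4, 4] <- 1
  B <- rbind((dt / tau) * diag(2), matrix(0, 2, 2))
  luu <- 2 * weff * diag(2)
  lux <- matrix(0, 2, 4)
  CtC <- crossprod(C)               # 2 x 2
  ystar <- task$y_star

  dyn <- function(z, u, k) drop(A %*% z) + drop(B %*% u)
  jac <- function(z, u, k) list(fx = A, fu = B)
  cost <- function(z, u, k) {
    out <- weff * sum(u^2) + ws$wtgt[k] * (z[3] - ystar)^2
    if (ws$wnull[k] > 0) {
      ydd <- drop(C %*% z[1:2])
      out <- out + ws$wnull[k] * (z[3]^2 + z[4]^2 + ydd^2)
    }
    out
  }
  quad <- function(z, u, k) {
    wn <- ws$wnull[k]; wt <- ws$wtgt[k]
    lx <- rep(0, 4)
    lxx <- matrix(0, 4, 4)
    lx[3] <- 2 * wt * (z[3] - ystar)
    lxx[3, 3] <- 2 * wt
    if (wn > 0) {
      ydd <- drop(C %*% z[1:2])
      lx[1:2] <- 2 * wn * ydd * drop(C)
      lx[3] <- lx[3] + 2 * wn * z[3]
      lx[4] <- 2 * wn * z[4]
      lxx[1:2, 1:2] <- 2 * wn * CtC
      lxx[3, 3] <- lxx[3, 3] + 2 * wn
      lxx[4, 4] <- 2 * wn
    }
    list(lx = lx, lu = 2 * weff * u, lxx = lxx, luu = luu, lux = lux)
  }
  oc_problem(dyn, jac, cost, quad, x0 = rep(0, 4), H = H, n_input = 2,
             lq = TRUE,
             meta = list(type = "toy", task = task, dt = dt, time = ws$time,
                         N = 2, model = model))
}

#' Extract a time-indexed trajectory from an iLQR solution
#'
#' Converts the solver's state/input arrays into the per-step trajectory
#' representation the cost and metric functions consume (left-endpoint
#' convention). For the arm plant this includes joint angles/velocities,
#' baseline-referenced torques, and Cartesian hand position and speed; for
#' the toy plant, output position/velocity/acceleration.
#'
#' @param sol An `oc_solution` from [ilqr_solve()].
#' @param problem The [oc_problem()] it solved.
#' @return A list trajectory (class `reach_trajectory`).
#' @export
solution_trajectory <- function(sol, problem) {
  meta <- problem$meta
  H <- problem$H
  xs <- sol$xs[seq_len(H), , drop = FALSE]
  out <- list(time = meta$time, dt = meta$dt, u = sol$us)
  if (meta$type == "arm") {
    N <- meta$N
    model <- meta$model
    phi <- phi_fun(model$nonlinearity)
    out$x <- xs[, seq_len(N), drop = FALSE]
    out$theta <- xs[, N + 1:2, drop = FALSE]
    out$dtheta <- xs[, N + 3:4, drop = FALSE]
    r <- t(apply(out$x, 1, phi))
    out$r <- r
    out$m <- sweep(r, 2, model$r_star) %*% t(model$C)
    hand <- t(apply(out$theta, 1, function(th)
      forward_kinematics(th, meta$params)$hand))
    out$hand <- hand
    # hand velocity through the kinematic Jacobian
    p <- meta$params
    speed <- vapply(seq_len(H), function(i) {
      th <- out$theta[i, ]; dth <- out$dtheta[i, ]
      J <- matrix(c(-p$L1 * sin(th[1]) - p$L2 * sin(th[1] + th[2]),
                    p$L1 * cos(th[1]) + p$L2 * cos(th[1] + th[2]),
                    -p$L2 * sin(th[1] + th[2]),
                    p$L2 * cos(th[1] + th[2])), 2, 2)
      sqrt(sum((J %*% dth)^2))
    }, numeric(1))
    out$speed <- speed
  } else {
    out$x <- xs[, 1:2, drop = FALSE]
    out$y <- xs[, 3]
    out$v <- xs[, 4]
    out$ydd <- drop(out$x %*% t(meta$model$C))
  }
  class(out) <- "reach_trajectory"
  out
}

#' Solve one reach end to end
#'
#' Convenience wrapper: builds the problem, runs [ilqr_solve()], and
#' returns the solution together with the extracted trajectory, cost
#' breakdown, and preparation index.
#'
#' @param model A `network_model`.
#' @param task A task object (`reach_task`, `sequence_task`, `toy_task`).
#' @param dt Time step (ms).
#' @param params Arm parameters (ignored for the toy task).
#' @param options iLQR options.
#' @param u_init Optional `H x m` initial input trajectory (default zero);
#'   used by the experiment drivers to warm-start a delayed reach from the
#'   zero-padded solution of a shorter delay, which embeds feasibly at
#'   identical cost and guarantees that granting a delay can only lower
#'   the optimized cost.
#' @return List with `solution`, `trajectory`, `breakdown`, `prep_index`.
#' @export
solve_reach <- function(model, task, dt = NULL, params = arm_params(),
                        options = ilqr_options(), u_init = NULL) {
  toy <- inherits(task, "toy_task")
  if (is.null(dt)) dt <- 10
  problem <- if (toy) build_toy_problem(model, task, dt)
             else build_reach_problem(model, task, dt, params)
  sol <- ilqr_solve(problem, u_init = u_init, options = options)
  traj <- solution_trajectory(sol, problem)
  breakdown <- if (toy) toy_reach_cost(traj, task)
               else if (inherits(task, "sequence_task")) sequence_cost(traj, task)
               else single_reach_cost(traj, task)
  pi_val <- tryCatch(preparation_index(traj), error = function(e) NA_real_)
  list(solution = sol, trajectory = traj, breakdown = breakdown,
       prep_index = pi_val, problem = problem)
}
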