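# Build a frozen (hand-specified) arm-task trajectory on the task's grid.
frozen_traj <- function(task, dt, theta, dtheta = c(0, 0), m = c(0, 0),
                        u_const = 0, n_inputs = 50) {
  tt <- motorprep:::step_times(task$delta_prep, task$T_move, dt)
  H <- length(tt)
  list(time = tt, dt = dt,
       theta = matrix(theta, H, 2, byrow = TRUE),
       dtheta = matrix(dtheta, H, 2, byrow = TRUE),
       m = matrix(m, H, 2, byrow = TRUE),
       u = matrix(u_const, H, n_inputs))
}

test_that("single-reach cost matches closed-form integrals", {
  th0 <- c(0.5, 1.0); ths <- c(0.9, 0.4)
  # at the target with no input: zero everywhere
  tk0 <- reach_task(300, 900, theta0 = ths, theta_star = ths)
  b0 <- single_reach_cost(frozen_traj(tk0, 1, ths), tk0)
  expect_equal(b0$J_total, 0)
  # hand frozen at theta0, no delay: J = ||dtheta||^2 * int t^2/T^3 = /3
  tk <- reach_task(0, 900, theta0 = th0, theta_star = ths)
  b <- single_reach_cost(frozen_traj(tk, 1, th0), tk)
  expect_equal(b$J_null, 0)
  expect_equal(b$J_effort, 0)
  expect_equal(b$J_target, sum((th0 - ths)^2) / 3, tolerance = 2e-3)
  # constant input c: J_effort = a_eff ||c||^2 (T + dprep)/(N T)
  tk2 <- reach_task(300, 900, theta0 = ths, theta_star = ths,
                    alpha_effort = 2)
  b2 <- single_reach_cost(frozen_traj(tk2, 1, ths, u_const = 0.3), tk2)
  N <- 50
  expect_equal(b2$J_effort, 2 * N * 0.3^2 * (900 + 300) / (N * 900),
               tolerance = 1e-9)
  # breakdown always sums to the total
  expect_equal(b2$J_total, b2$J_target + b2$J_null + b2$J_effort + b2$J_pause)
})

test_that("toy cost reproduces the 1/3 integral and weight linearity", {
  tk <- toy_task(delta_prep = 0, T_move = 900, y_star = 20)
  tt <- motorprep:::step_times(0, 900, 1)
  H <- length(tt)
  traj <- list(time = tt, dt = 1, y = rep(0, H), v = rep(0, H),
               ydd = rep(0, H), u = matrix(0, H, 2))
  b <- toy_reach_cost(traj, tk)
  expect_equal(b$J_target, 400 / 3, tolerance = 2e-3)
  expect_equal(b$J_null + b$J_effort, 0)
  # degenerate target at the start position costs nothing
  tk0 <- toy_task(delta_prep = 100, T_move = 500, y_star = 0)
  tt0 <- motorprep:::step_times(100, 500, 1)
  traj0 <- list(time = tt0, dt = 1, y = rep(0, length(tt0)),
                v = rep(0, length(tt0)), ydd = rep(0, length(tt0)),
                u = matrix(0, length(tt0), 2))
  expect_equal(toy_reach_cost(traj0, tk0)$J_total, 0)
  # doubling alpha_effort doubles J_effort only
  set.seed(20)
  trajr <- list(time = tt, dt = 1, y = rnorm(H), v = rnorm(H),
                ydd = rnorm(H), u = matrix(rnorm(2 * H), H, 2))
  b1 <- toy_reach_cost(trajr, toy_task(0, 900, 20, alpha_effort = 1e-5))
  b2 <- toy_reach_cost(trajr, toy_task(0, 900, 20, alpha_effort = 2e-5))
  expect_equal(b2$J_effort, 2 * b1$J_effort)
  expect_equal(b2$J_target, b1$J_target)
  expect_equal(b2$J_null, b1$J_null)
})

test_that("sequence cost degenerates toward the single-reach cost", {
  th0 <- c(0.4, 0.9); ths <- c(0.8, 0.5)
  # same target twice, no pause, no pause weight: the delay and effort terms
  # coincide with the single reach exactly; the target term keeps the
  # sequence's restarted urgency clock, checked against a direct sum here
  sq <- sequence_task(delta_prep = 200, move1 = 300, pause = 0,
                      T_total = 900, theta0 = th0, theta_star1 = ths,
                      theta_star2 = ths, alpha_null = 1, alpha_pause = 0)
  sg <- reach_task(200, 900, theta0 = th0, theta_star = ths, alpha_null = 1)
  set.seed(21)
  tt <- motorprep:::step_times(200, 900, 2)
  H <- length(tt)
  traj <- list(time = tt, dt = 2,
               theta = matrix(rnorm(2 * H), H, 2),
               dtheta = matrix(rnorm(2 * H), H, 2),
               m = matrix(rnorm(2 * H), H, 2),
               u = matrix(rnorm(10 * H), H, 10))
  bs <- sequence_cost(traj, sq)
  bg <- single_reach_cost(traj, sg)
  expect_equal(bs$J_null, bg$J_null, tolerance = 1e-12)
  expect_equal(bs$J_effort, bg$J_effort, tolerance = 1e-12)
  expect_equal(bs$J_pause, 0)
  err <- rowSums(sweep(traj$theta, 2, ths)^2)
  clock <- ifelse(tt < 0, 0, ifelse(tt < 300, tt, tt - 300))
  expect_equal(bs$J_target,
               sum(err * clock^2 / 900^2 * ifelse(tt >= 0, 1, 0)) * 2 / 900,
               tolerance = 1e-12)
})

test_that("sequence-specific terms behave as specified", {
  th0 <- c(0.4, 0.9); th1 <- c(0.8, 0.5); th2 <- c(0.2, 0.7)
  sq <- sequence_task(delta_prep = 100, move1 = 300, pause = 600,
                      T_total = 2000, theta0 = th0, theta_star1 = th1,
                      theta_star2 = th2)
  tt <- motorprep:::step_times(100, 2000, 10)
  H <- length(tt)
  # hand resting on target 1 through the pause: no pause cost
  traj <- list(time = tt, dt = 10,
               theta = matrix(th1, H, 2, byrow = TRUE),
               dtheta = matrix(0, H, 2),
               m = matrix(0, H, 2), u = matrix(0, H, 10))
  b <- sequence_cost(traj, sq)
  expect_equal(b$J_pause, 0)
  # the second urgency weight vanishes at the pause end
  w <- motorprep:::reach_weights(sq, 10)
  k_sw <- which(w$time >= 900)[1]
  expect_equal(w$wtgt[k_sw], 0, tolerance = 1e-15)
  expect_true(w$tgt_is_second[k_sw])
  expect_false(w$tgt_is_second[k_sw - 1])
})

test_that("urgency weighting penalizes late errors more than early ones", {
  tk <- reach_task(0, 900, theta0 = c(0, 0), theta_star = c(0, 0))
  tt <- motorprep:::step_times(0, 900, 1)
  H <- length(tt)
  prof <- seq(1, 0, length.out = H)   # error decays: early errors
  early <- frozen_traj(tk, 1, c(0, 0))
  early$theta <- cbind(prof, 0)
  late <- early
  late$theta <- cbind(rev(prof), 0)
  expect_gt(single_reach_cost(late, tk)$J_target,
            single_reach_cost(early, tk)$J_target)
})

test_that("costs are stable under dt refinement", {
  th0 <- c(0.5, 1.0); ths <- c(0.9, 0.4)
  tk <- reach_task(300, 900, theta0 = th0, theta_star = ths)
  smooth <- function(dt) {
    tt <- motorprep:::step_times(300, 900, dt)
    H <- length(tt)
    ph <- (tt + 300) / 1200
    list(time = tt, dt = dt,
         theta = cbind(th0[1] + (ths[1] - th0[1]) * ph^2,
                       th0[2] + (ths[2] - th0[2]) * ph^2),
         dtheta = cbind(sin(pi * ph), cos(pi * ph)),
         m = cbind(ph, ph^3), u = matrix(0.2 * sin(2 * pi * ph), H, 20))
  }
  b1 <- single_reach_cost(smooth(10), tk)
  b2 <- single_reach_cost(smooth(5), tk)
  expect_equal(b1$J_total, b2$J_total, tolerance = 0.02)
  expect_equal(b1$J_null, b2$J_null, tolerance = 0.02)
})

test_that("cost terms are nonnegative for arbitrary trajectories", {
  set.seed(22)
  tk <- reach_task(200, 700, theta0 = rnorm(2), theta_star = rnorm(2))
  for (i in 1:20) {
    tt <- motorprep:::step_times(200, 700, 10)
    H <- length(tt)
    traj <- list(time = tt, dt = 10,
                 theta = matrix(rnorm(2 * H), H, 2),
                 dtheta = matrix(rnorm(2 * H), H, 2),
                 m = matrix(rnorm(2 * H), H, 2),
                 u = matrix(rnorm(6 * H), H, 6))
    b <- single_reach_cost(traj, tk)
    expect_true(all(c(b$J_target, b$J_null, b$J_effort) >= 0))
  }
})

test_that("quadratic expansions match finite differences of the running cost", {
  m <- small_plant()
  tg <- reach_target_set(4, r = 0.12)
  task <- reach_task(200, 700, theta0 = tg$theta0,
                     theta_star = tg$targets[2, ])
  pr <- build_reach_problem(m, task, dt = 10)
  set.seed(23)
  n <- pr$n_state
  for (k in c(3, 15, round(pr$H / 2), pr$H)) {
    # keep x away from rectification kinks for clean finite differences
    z <- c(m$r_star + runif(m$N, 0.05, 1), tg$theta0 + rnorm(2, sd = 0.1),
           rnorm(2, sd = 0.3))
    u <- rnorm(m$N, sd = 0.5)
    qd <- pr$quad(z, u, k)
    gx <- fd_grad(function(v) pr$cost(v, u, k), z, eps = 1e-5)
    gu <- fd_grad(function(v) pr$cost(z, v, k), u, eps = 1e-5)
    scale <- max(1e-8, max(abs(gx)))
    expect_lt(max(abs(qd$lx - gx)) / scale, 1e-3)
    expect_lt(max(abs(qd$lu - gu)) / max(1e-8, max(abs(gu))), 1e-3)
    # effort Hessian is exactly 2 a_eff dt/(N T) I
    expect_equal(qd$luu,
                 2 * task$alpha_effort * 10 / (m$N * 900) * diag(m$N))
  }
  # target-term gradient vanishes at the target posture
  kmov <- pr$H  # movement epoch
  z_at <- c(m$r_star, tg$targets[2, ], c(0, 0))
  qd2 <- pr$quad(z_at, rep(0, m$N), kmov)
  expect_equal(qd2$lx[m$N + 1:2], c(0, 0))
})
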