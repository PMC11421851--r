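# Independent finite-horizon LQR oracle: backward Riccati recursion for
# x+ = A x + B u, cost sum(x'Qx + u'Ru) over steps 1..H plus x'Qf x at H+1.
riccati_lqr <- function(A, B, Q, R, Qf, x0, H) {
  n <- length(x0)
  S <- Qf
  Ks <- vector("list", H)
  for (k in H:1) {
    G <- R + t(B) %*% S %*% B
    Ks[[k]] <- solve(G, t(B) %*% S %*% A)
    S <- Q + t(A) %*% S %*% A - t(A) %*% S %*% B %*% Ks[[k]]
    S <- (S + t(S)) / 2
  }
  x <- x0
  cost <- 0
  us <- matrix(0, H, ncol(B))
  for (k in 1:H) {
    u <- -drop(Ks[[k]] %*% x)
    us[k, ] <- u
    cost <- cost + drop(t(x) %*% Q %*% x) + drop(t(u) %*% R %*% u)
    x <- drop(A %*% x + B %*% u)
  }
  cost <- cost + drop(t(x) %*% Qf %*% x)
  list(cost = cost, us = us)
}

lq_problem <- function(A, B, Q, R, Qf, x0, H) {
  oc_problem(
    dyn = function(x, u, k) drop(A %*% x + B %*% u),
    jac = function(x, u, k) list(fx = A, fu = B),
    cost = function(x, u, k) drop(t(x) %*% Q %*% x) + drop(t(u) %*% R %*% u),
    quad = function(x, u, k) list(lx = 2 * drop(Q %*% x),
                                  lu = 2 * drop(R %*% u),
                                  lxx = 2 * Q, luu = 2 * R,
                                  lux = matrix(0, ncol(B), length(x0))),
    term_cost = function(x) drop(t(x) %*% Qf %*% x),
    term_quad = function(x) list(lx = 2 * drop(Qf %*% x), lxx = 2 * Qf),
    x0 = x0, H = H, n_input = ncol(B), lq = TRUE)
}

test_that("iLQR reproduces the Riccati optimum on random LQ problems", {
  set.seed(30)
  for (trial in 1:3) {
    n <- 6; m <- 2; H <- 50
    A <- diag(n) + 0.1 * matrix(rnorm(n * n), n) / sqrt(n)
    B <- matrix(rnorm(n * m), n, m) * 0.2
    Q <- crossprod(matrix(rnorm(n * n), n)) / n * 0.1
    R <- crossprod(matrix(rnorm(m * m), m)) / m + diag(m)
    Qf <- crossprod(matrix(rnorm(n * n), n)) / n
    x0 <- rnorm(n)
    oracle <- riccati_lqr(A, B, Q, R, Qf, x0, H)
    sol <- ilqr_solve(lq_problem(A, B, Q, R, Qf, x0, H))
    expect_true(sol$converged)
    expect_lt(abs(sol$cost - oracle$cost) / oracle$cost, 1e-8)
    expect_lt(max(abs(sol$us - oracle$us)), 1e-6)
  }
})

test_that("an already-optimal start is returned unchanged", {
  # start at the origin of a target-free quadratic: u = 0 is optimal
  A <- matrix(c(0.9, 0, 0.1, 0.8), 2, 2)
  B <- diag(2)
  pr <- lq_problem(A, B, Q = diag(2), R = diag(2), Qf = diag(2),
                   x0 = c(0, 0), H = 20)
  sol <- ilqr_solve(pr)
  expect_true(sol$converged)
  expect_equal(nrow(sol$log), 0)
  expect_equal(sol$us, matrix(0, 20, 2))
  expect_equal(sol$cost, 0)
})

test_that("one-step backward pass reproduces the closed-form gain", {
  # scalar system, horizon 1: K = -(R + B V B)^{-1} B V A (V = terminal Hess)
  A <- matrix(1.3); B <- matrix(0.7); R <- matrix(0.5); V <- matrix(2.0)
  pr <- oc_problem(
    dyn = function(x, u, k) drop(A %*% x + B %*% u),
    jac = function(x, u, k) list(fx = A, fu = B),
    cost = function(x, u, k) drop(t(u) %*% R %*% u),
    quad = function(x, u, k) list(lx = 0, lu = 2 * drop(R %*% u),
                                  lxx = matrix(0, 1, 1), luu = 2 * R,
                                  lux = matrix(0, 1, 1)),
    term_cost = function(x) drop(t(x) %*% V %*% x),
    term_quad = function(x) list(lx = 2 * drop(V %*% x), lxx = 2 * V),
    x0 = 1, H = 1, n_input = 1)
  bp <- ilqr_backward_pass(pr, xs = matrix(c(1, 1.3), 2, 1),
                           us = matrix(0, 1, 1), mu = 0)
  K_closed <- -drop(solve(R + t(B) %*% V %*% B, t(B) %*% V %*% A))
  expect_equal(drop(bp$K[[1]]), K_closed, tolerance = 1e-12)
})

test_that("zero cost yields zero gains and zero expected improvement", {
  A <- diag(2); B <- diag(2)
  pr <- lq_problem(A, B, Q = matrix(0, 2, 2), R = diag(2) * 0,
                   Qf = matrix(0, 2, 2), x0 = c(1, 1), H = 5)
  # R = 0 makes Quu singular; regularization must still return zero steps
  bp <- ilqr_backward_pass(pr, rollout_states(pr, matrix(0, 5, 2)),
                           matrix(0, 5, 2), mu = 1e-6)
  expect_true(bp$ok)
  expect_equal(bp$dV1, 0)
  expect_equal(bp$dV2, 0)
  expect_lt(max(abs(unlist(bp$kff))), 1e-12)
})

test_that("expected improvement predicts realized decrease near convergence", {
  m <- generate_2d("feedforward", w = 2, readout_angle = pi / 2)
  pr <- build_toy_problem(m, toy_task(delta_prep = 200, T_move = 500), dt = 5)
  sol <- ilqr_solve(pr)
  lg <- sol$log
  expect_gt(nrow(lg), 0)
  ratio <- lg$decrease / lg$expected
  expect_true(all(ratio[lg$alpha == 1] > 0.5 & ratio[lg$alpha == 1] < 1.5))
})

test_that("cost is monotone over accepted iterations on the reach problem", {
  m <- small_plant()
  tg <- reach_target_set(4, r = 0.12)
  task <- reach_task(delta_prep = 200, T_move = 600, theta0 = tg$theta0,
                     theta_star = tg$targets[1, ])
  pr <- build_reach_problem(m, task, dt = 10)
  sol <- ilqr_solve(pr, options = ilqr_options(max_iter = 25, tol = 1e-8,
                                               mu_up = 10))
  expect_gt(nrow(sol$log), 3)
  expect_true(all(diff(sol$log$cost) <= 0))
  # the returned states are the exact rollout of the returned inputs
  roll <- rollout_states(pr, sol$us)
  expect_equal(roll, sol$xs, tolerance = 1e-12)
})

test_that("solver is deterministic and robust to tiny u_init perturbations", {
  m <- generate_2d("oscillatory", w = 1.5, readout_angle = 0)
  task <- toy_task(delta_prep = 300, T_move = 600)
  pr <- build_toy_problem(m, task, dt = 2)
  s1 <- ilqr_solve(pr)
  s2 <- ilqr_solve(pr)
  expect_identical(s1$us, s2$us)
  set.seed(31)
  u0 <- matrix(rnorm(pr$H * 2, sd = 1e-3), pr$H, 2)
  s3 <- ilqr_solve(pr, u_init = u0,
                   options = ilqr_options(max_iter = 50, tol = 1e-10))
  expect_lt(abs(s3$cost - s1$cost) / s1$cost, 1e-3)
})

test_that("reach-problem dynamics Jacobians match finite differences", {
  m <- small_plant()
  tg <- reach_target_set(4, r = 0.12)
  task <- reach_task(200, 600, theta0 = tg$theta0,
                     theta_star = tg$targets[3, ])
  pr <- build_reach_problem(m, task, dt = 10)
  set.seed(32)
  for (i in 1:20) {
    # sample away from rectification kinks
    z <- c(m$r_star + runif(m$N, 0.05, 0.8) * sign(rnorm(m$N)),
           tg$theta0 + rnorm(2, sd = 0.2), rnorm(2, sd = 0.5))
    z[seq_len(m$N)] <- ifelse(abs(z[seq_len(m$N)]) < 0.02,
                              z[seq_len(m$N)] + 0.05, z[seq_len(m$N)])
    u <- rnorm(m$N, sd = 0.3)
    J <- pr$jac(z, u, 5)
    fd <- fd_jac(function(v) pr$dyn(v, u, 5), z, eps = 1e-6)
    expect_lt(max(abs(J$fx - fd)) / max(1, max(abs(fd))), 1e-5)
    fdu <- fd_jac(function(v) pr$dyn(z, v, 5), u, eps = 1e-6)
    expect_lt(max(abs(J$fu - fdu)), 1e-8)
  }
  # toy problem dimensions: 2 network units + position + velocity
  prt <- build_toy_problem(generate_2d("feedforward", 1), toy_task(), dt = 1)
  expect_equal(prt$n_state, 4)
  expect_equal(pr$n_state, m$N + 4)
})

test_that("adjoint gradient vanishes at convergence", {
  m <- generate_2d("feedforward", w = 3, readout_angle = pi / 2)
  pr <- build_toy_problem(m, toy_task(delta_prep = 300, T_move = 600), dt = 5)
  sol <- ilqr_solve(pr)
  # gradient of the total cost w.r.t. u via first-order perturbation of the
  # rollout cost, sampled at a few steps/channels
  base <- rollout_cost(pr, sol$us)
  g0 <- rollout_cost(pr, matrix(0, pr$H, 2))
  eps <- 1e-5
  set.seed(33)
  picks <- cbind(sample(pr$H, 12), sample(2, 12, replace = TRUE))
  grads <- apply(picks, 1, function(ij) {
    up <- sol$us; up[ij[1], ij[2]] <- up[ij[1], ij[2]] + eps
    (rollout_cost(pr, up) - base) / eps
  })
  grads0 <- apply(picks, 1, function(ij) {
    up <- matrix(0, pr$H, 2); up[ij[1], ij[2]] <- eps
    (rollout_cost(pr, up) - g0) / eps
  })
  expect_lt(max(abs(grads)), 1e-3 * max(abs(grads0)))
})
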