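#' Discrete-time optimal-control problem
#'
#' Bundles everything the iLQR solver needs: a discrete dynamics map with
#' Jacobians, per-step running costs with quadratic expansions, an optional
#' terminal cost, the horizon, and the initial state.
#'
#' @param dyn Function `(x, u, k) -> x_next`.
#' @param jac Function `(x, u, k) -> list(fx, fu)` of dynamics Jacobians.
#' @param cost Function `(x, u, k) -> scalar` running cost.
#' @param quad Function `(x, u, k) -> list(lx, lu, lxx, luu, lux)` with the
#'   gradient and Hessian blocks of the running cost (`lux` is the m x n
#'   cross term, d2l/du dx).
#' @param x0 Initial state vector.
#' @param H Horizon (number of steps, >= 1).
#' @param n_input Input dimension.
#' @param term_cost Optional terminal cost `x -> scalar` (default 0).
#' @param term_quad Optional `x -> list(lx, lxx)` for the terminal cost.
#' @param lq Set `TRUE` for linear dynamics + quadratic cost; the solver
#'   then expects convergence in a single accepted iteration.
#' @param meta Optional list of problem metadata (dims, epoch times, ...).
#'
#' @return An object of class `oc_problem`.
#' @export
oc_problem <- function(dyn, jac, cost, quad, x0, H, n_input,
                       term_cost = NULL, term_quad = NULL, lq = FALSE,
                       meta = list()) {
  stopifnot(H >= 1, is.function(dyn), is.function(jac), is.function(cost),
            is.function(quad))
  n <- length(x0)
  if (is.null(term_cost)) term_cost <- function(x) 0
  if (is.null(term_quad))
    term_quad <- function(x) list(lx = rep(0, n), lxx = matrix(0, n, n))
  structure(list(dyn = dyn, jac = jac, cost = cost, quad = quad,
                 x0 = x0, H = H, n_state = n, n_input = n_input,
                 term_cost = term_cost, term_quad = term_quad, lq = lq,
                 meta = meta),
            class = "oc_problem")
}

#' iLQR solver options
#'
#' @param max_iter Maximum number of iLQR iterations.
#' @param tol Relative cost-decrease convergence tolerance.
#' @param mu_init,mu_min,mu_max Initial value and bounds of the curvature
#'   regularizer added to the value Hessian in the backward pass.
#' @param mu_up,mu_down Multiplicative factors for raising/lowering the
#'   regularizer (raise on failure, lower on success).
#' @param alphas Backtracking line-search step sizes (decreasing from 1).
#' @param alpha_good,alpha_poor Accepted-step thresholds steering the
#'   regularizer: steps at or above `alpha_good` relax it, steps below
#'   `alpha_poor` stiffen it.
#' @param verbose Print per-iteration progress.
#' @return List of options.
#' @export
ilqr_options <- function(max_iter = 100, tol = 1e-7,
                         mu_init = 0, mu_min = 1e-9, mu_max = 1e9,
                         mu_up = 2, mu_down = 1.6,
                         alphas = 1.1^(-(0:9)^2),
                         alpha_good = 0.3, alpha_poor = 0.05,
                         verbose = FALSE) {
  list(max_iter = max_iter, tol = tol, mu_init = mu_init, mu_min = mu_min,
       mu_max = mu_max, mu_up = mu_up, mu_down = mu_down, alphas = alphas,
       alpha_good = alpha_good, alpha_poor = alpha_poor, verbose = verbose)
}

#' Open-loop rollout of an input sequence
#'
#' Integrates the problem dynamics under the given inputs and returns the
#' state trajectory (`rollout_states`) or the accumulated cost
#' (`rollout_cost`).
#'
#' @param problem An [oc_problem()].
#' @param us `H x m` input matrix.
#' @return `(H+1) x n` state matrix, or a scalar cost.
#' @export
rollout_states <- function(problem, us) {
  roll <- ilqr_rollout(problem, as.matrix(us))
  if (!roll$ok) stop("rollout diverged at step ", roll$k)
  roll$xs
}

#' @rdname rollout_states
#' @export
rollout_cost <- function(problem, us) {
  roll <- ilqr_rollout(problem, as.matrix(us))
  if (!roll$ok) stop("rollout diverged at step ", roll$k)
  roll$cost
}

# Roll the dynamics forward under an open-loop input sequence.
ilqr_rollout <- function(problem, us) {
  H <- problem$H
  xs <- matrix(0, H + 1, problem$n_state)
  xs[1, ] <- problem$x0
  cost <- 0
  x <- problem$x0
  for (k in seq_len(H)) {
    u <- us[k, ]
    cost <- cost + problem$cost(x, u, k)
    x <- problem$dyn(x, u, k)
    if (any(!is.finite(x))) return(list(ok = FALSE, k = k))
    xs[k + 1, ] <- x
  }
  cost <- cost + problem$term_cost(x)
  list(ok = TRUE, xs = xs, cost = cost)
}

#' iLQR backward pass
#'
#' Computes the time-indexed affine control law (feedback gains and
#' feedforward steps) by dynamic programming along the current trajectory,
#' with Levenberg-style regularization `mu` added to the value Hessian
#' before forming the control Hessian. A non-positive-definite control
#' Hessian is reported as failure so the caller can raise `mu` and retry.
#'
#' @param problem An [oc_problem()].
#' @param xs `(H+1) x n` state trajectory (exact rollout of `us`).
#' @param us `H x m` input trajectory.
#' @param mu Nonnegative regularization.
#'
#' @return List with `ok`, gain list `K` (each m x n), feedforward list
#'   `kff`, expected-improvement coefficients `dV1`, `dV2` (expected cost
#'   change for step length a is `a*dV1 + a^2*dV2`), and `grad_norm` (mean
#'   absolute feedforward step, a stationarity measure).
#' @export
ilqr_backward_pass <- function(problem, xs, us, mu = 0) {
  H <- problem$H
  n <- problem$n_state
  m <- problem$n_input
  tq <- problem$term_quad(xs[H + 1, ])
  Vx <- tq$lx
  Vxx <- tq$lxx
  K <- vector("list", H)
  kff <- vector("list", H)
  dV1 <- 0; dV2 <- 0
  for (k in H:1) {
    x <- xs[k, ]; u <- us[k, ]
    fj <- problem$jac(x, u, k)
    lq <- problem$quad(x, u, k)
    fx <- fj$fx; fu <- fj$fu
    Qx <- lq$lx + drop(crossprod(fx, Vx))
    Qu <- lq$lu + drop(crossprod(fu, Vx))
    VxxFx <- Vxx %*% fx
    Qxx <- lq$lxx + crossprod(fx, VxxFx)
    VxxFu <- Vxx %*% fu
    Quu <- lq$luu + crossprod(fu, VxxFu)
    Qux <- lq$lux + crossprod(fu, VxxFx)
    if (mu > 0) {
      # value-Hessian regularization (adds mu * fu' fu / fu' fx terms)
      Quu_r <- Quu + mu * crossprod(fu)
      Qux_r <- Qux + mu * crossprod(fu, fx)
    } else {
      Quu_r <- Quu
      Qux_r <- Qux
    }
    Quu_r <- (Quu_r + t(Quu_r)) / 2
    ch <- tryCatch(chol(Quu_r), error = function(e) NULL)
    if (is.null(ch)) return(list(ok = FALSE, k = k))
    kf <- -backsolve(ch, backsolve(ch, Qu, transpose = TRUE))
    Kk <- -backsolve(ch, backsolve(ch, Qux_r, transpose = TRUE))
    kff[[k]] <- kf
    K[[k]] <- Kk
    dV1 <- dV1 + sum(kf * Qu)
    dV2 <- dV2 + 0.5 * sum(kf * drop(Quu %*% kf))
    Vx <- Qx + drop(crossprod(Kk, drop(Quu %*% kf))) +
      drop(crossprod(Kk, Qu)) + drop(crossprod(Qux, kf))
    Vxx <- Qxx + crossprod(Kk, Quu %*% Kk) + crossprod(Kk, Qux) +
      crossprod(Qux, Kk)
    Vxx <- (Vxx + t(Vxx)) / 2
  }
  grad_norm <- mean(abs(unlist(kff)))
  list(ok = TRUE, K = K, kff = kff, dV1 = dV1, dV2 = dV2,
       grad_norm = grad_norm)
}

# Closed-loop forward pass: rollout with feedback on the deviation from the
# previous trajectory and a scaled feedforward step.
ilqr_forward_pass <- function(problem, xs, us, bp, alpha) {
  H <- problem$H
  xs_new <- matrix(0, H + 1, problem$n_state)
  us_new <- matrix(0, H, problem$n_input)
  x <- problem$x0
  xs_new[1, ] <- x
  cost <- 0
  for (k in seq_len(H)) {
    u <- us[k, ] + alpha * bp$kff[[k]] + drop(bp$K[[k]] %*% (x - xs[k, ]))
    us_new[k, ] <- u
    cost <- cost + problem$cost(x, u, k)
    x <- problem$dyn(x, u, k)
    if (any(!is.finite(x))) return(list(ok = FALSE))
    xs_new[k + 1, ] <- x
  }
  cost <- cost + problem$term_cost(x)
  if (!is.finite(cost)) return(list(ok = FALSE))
  list(ok = TRUE, xs = xs_new, us = us_new, cost = cost)
}

#' Solve an optimal-control problem with iLQR
#'
#' Iterates linearization of the dynamics and quadratic expansion of the
#' cost around the current trajectory, solves the local linear-quadratic
#' problem by dynamic programming ([ilqr_backward_pass()]), and updates the
#' trajectory with a backtracking line search on the feedback-controlled
#' rollout. The curvature regularizer is raised multiplicatively whenever
#' the backward pass meets an indefinite control Hessian or the line search
#' fails, and lowered after successful steps. The cost over accepted
#' iterations is non-increasing by construction.
#'
#' @param problem An [oc_problem()].
#' @param u_init `H x m` matrix of initial inputs (default all zero).
#' @param options See [ilqr_options()].
#'
#' @return Object of class `oc_solution`: `us`, `xs` (exact rollout of
#'   `us`), `cost`, `converged`, `stalled`, and a per-iteration `log`
#'   data frame (cost, regularization, step length, expected/actual
#'   improvement, gradient norm).
#' @export
ilqr_solve <- function(problem, u_init = NULL, options = ilqr_options()) {
  stopifnot(inherits(problem, "oc_problem"))
  H <- problem$H; m <- problem$n_input
  if (is.null(u_init)) u_init <- matrix(0, H, m)
  us <- as.matrix(u_init)
  stopifnot(nrow(us) == H, ncol(us) == m, all(is.finite(us)))
  roll <- ilqr_rollout(problem, us)
  if (!roll$ok) stop("initial rollout diverged at step ", roll$k)
  xs <- roll$xs
  cost <- roll$cost
  mu <- options$mu_init
  logs <- list()
  converged <- FALSE
  stalled <- FALSE
  for (it in seq_len(options$max_iter)) {
    bp <- NULL
    repeat {
      bp <- ilqr_backward_pass(problem, xs, us, mu)
      if (bp$ok) break
      mu <- max(mu * options$mu_up, options$mu_min * options$mu_up)
      if (mu > options$mu_max) {
        stalled <- TRUE
        break
      }
    }
    if (stalled) break
    # stationarity: with the regularizer at rest, the local model predicts
    # no attainable improvement
    if (mu <= max(options$mu_init, 10 * options$mu_min) &&
        -(bp$dV1 + bp$dV2) <= options$tol * (1 + abs(cost)) &&
        -(bp$dV1 + bp$dV2) >= 0) {
      converged <- TRUE
      break
    }
    accepted <- FALSE
    new <- NULL; alpha_used <- NA_real_
    for (alpha in options$alphas) {
      fp <- ilqr_forward_pass(problem, xs, us, bp, alpha)
      if (!fp$ok) next
      expected <- -(alpha * bp$dV1 + alpha^2 * bp$dV2)
      decrease <- cost - fp$cost
      if ((expected > 0 && decrease > 1e-4 * expected) ||
          (expected <= 0 && decrease > 0)) {
        accepted <- TRUE
        new <- fp
        alpha_used <- alpha
        break
      }
    }
    if (accepted) {
      decrease <- cost - new$cost
      logs[[length(logs) + 1]] <- data.frame(
        iter = it, cost = new$cost, mu = mu, alpha = alpha_used,
        expected = -(alpha_used * bp$dV1 + alpha_used^2 * bp$dV2),
        decrease = decrease, grad_norm = bp$grad_norm)
      us <- new$us
      xs <- new$xs
      old_cost <- cost
      cost <- new$cost
      # trust-region flavor: near-full steps relax the regularizer, steps
      # only accepted when heavily shrunk mean the local model overreaches,
      # so stiffen it instead
      if (alpha_used >= options$alpha_good) {
        mu <- if (mu / options$mu_down < options$mu_min) 0 else mu / options$mu_down
      } else if (alpha_used < options$alpha_poor) {
        mu <- max(mu, options$mu_min) * options$mu_up
      }
      if (decrease <= options$tol * (1 + abs(old_cost)) ||
          (problem$lq && it >= 1)) {
        converged <- TRUE
        break
      }
    } else {
      mu <- max(mu, options$mu_min) * options$mu_up
      if (mu > options$mu_max) {
        stalled <- TRUE
        break
      }
    }
    if (options$verbose)
      cat(sprintf("iter %3d  cost %.8g  mu %.1e\n", it, cost, mu))
  }
  if (length(logs) == 0 && !stalled) {
    # u_init was already (locally) optimal: nothing to accept
    converged <- TRUE
  }
  structure(list(us = us, xs = xs, cost = cost, converged = converged,
                 stalled = stalled,
                 log = if (length(logs)) do.call(rbind, logs) else
                   data.frame(iter = integer(), cost = numeric(),
                              mu = numeric(), alpha = numeric(),
                              expected = numeric(), decrease = numeric(),
                              grad_norm = numeric()),
                 problem_meta = problem$meta),
            class = "oc_solution")
}

#' @export
print.oc_solution <- function(x, ...) {
  cat(sprintf("iLQR solution: cost %.6g after %d accepted iterations (%s)\n",
              x$cost, nrow(x$log),
              if (x$converged) "converged" else if (x$stalled) "stalled"
              else "budget exhausted"))
  invisible(x)
}
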