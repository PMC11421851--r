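#' Recurrent rate-network model
#'
#' Container for the neural half of the controlled plant: recurrent weights
#' `W`, a linear readout `C` mapping firing rates to torques (or to a 1D
#' hand acceleration for the toy task), a constant baseline input `h`, the
#' single-neuron time constant `tau`, and the firing-rate nonlinearity.
#' Dynamics follow `tau dx/dt = -x + W phi(x) + h + u`, with rates
#' `r = phi(x)`.
#'
#' @param W Square recurrent weight matrix.
#' @param C Readout matrix (k x N), or `NULL`.
#' @param h Baseline input vector (recycled to length N).
#' @param tau Single-neuron time constant in ms.
#' @param nonlinearity `"relu"` (rectified linear) or `"identity"`.
#' @param r_star Baseline firing-rate vector (fixed point with `u = 0`);
#'   defaults to zeros.
#' @param family Optional tag recording how the network was generated.
#' @param meta Optional list of generation metadata.
#'
#' @return An object of class `network_model`.
#' @export
network_model <- function(W, C = NULL, h = 0, tau = 150,
                          nonlinearity = c("relu", "identity"),
                          r_star = NULL, family = "custom", meta = list()) {
  nonlinearity <- match.arg(nonlinearity)
  W <- as.matrix(W)
  N <- nrow(W)
  stopifnot(ncol(W) == N, all(is.finite(W)), tau > 0)
  if (!is.null(C)) {
    C <- matrix(C, ncol = N)
    stopifnot(all(is.finite(C)))
  }
  h <- rep_len(h, N)
  if (is.null(r_star)) r_star <- rep(0, N)
  structure(list(W = W, C = C, h = h, tau = tau,
                 nonlinearity = nonlinearity, r_star = r_star,
                 family = family, meta = meta, N = N),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("Rate network (%s): N=%d, tau=%g ms, phi=%s\n",
              x$family, x$N, x$tau, x$nonlinearity))
  cat(sprintf("  spectral abscissa of W: %.3f\n", spectral_abscissa(x$W)))
  if (!is.null(x$C)) cat(sprintf("  readout: %d x %d\n", nrow(x$C), ncol(x$C)))
  invisible(x)
}

phi_fun <- function(nonlinearity) {
  if (nonlinearity == "relu") function(x) pmax(x, 0) else identity
}

# Subgradient convention at the kink: phi'(0) = 0 (inactive side).
phi_prime_fun <- function(nonlinearity) {
  if (nonlinearity == "relu") function(x) as.numeric(x > 0) else function(x) rep(1, length(x))
}

#' Spectral abscissa (largest eigenvalue real part)
#'
#' @param W Square matrix.
#' @return Scalar, `max(Re(eig(W)))`.
#' @export
spectral_abscissa <- function(W) {
  max(Re(eigen(as.matrix(W), only.values = TRUE)$values))
}

#' Generate an inhibition-stabilized network (ISN)
#'
#' Builds a strongly connected excitatory/inhibitory network and stabilizes
#' it by adjusting the inhibitory weights. Excitatory neurons (fraction
#' `frac_exc`) project sparse, log-normally distributed nonnegative weights
#' at connection probability `p_con`; inhibitory columns are nonpositive
#' (Dale's law). Stabilization performs projected gradient descent on the
#' squared H2 norm of the shifted linear system `W - s I` (with identity
#' input and output), restricted to inhibitory entries; the gradient is
#' `2 Q P` with `P` and `Q` the controllability and observability Gramians
#' of the shifted system. Descent steps are backtracked so the objective
#' decreases at every accepted step, and the loop stops once the spectral
#' abscissa of `W` falls below `target_abscissa`.
#'
#' @param N Number of neurons (>= 10).
#' @param exc_scale Scale of excitatory weights; the excitatory submatrix has
#'   spectral radius of roughly this value before inhibition is added.
#' @param target_abscissa Stop once `max Re eig(W)` is below this (< 1 keeps
#'   the continuous-time dynamics stable).
#' @param seed Integer seed; the generator is fully reproducible.
#' @param tau Time constant (ms) stored in the model.
#' @param p_con Excitatory connection probability.
#' @param frac_exc Fraction of excitatory neurons.
#' @param max_iter Iteration budget for the stabilization loop.
#'
#' @return A `network_model` with `meta$log` holding the optimization log
#'   (one row per iteration: shift, objective before/after, abscissa,
#'   accepted flag) and `meta$exc` the excitatory-neuron indicator.
#' @export
generate_isn <- function(N = 200, exc_scale = 5, target_abscissa = 0.8,
                         seed = 1, tau = 150, p_con = 0.2, frac_exc = 0.8,
                         max_iter = 2000) {
  stopifnot(N >= 10, target_abscissa < 1, exc_scale >= 0)
  set.seed(seed)
  nE <- round(frac_exc * N)
  nI <- N - nE
  is_exc <- c(rep(TRUE, nE), rep(FALSE, nI))

  W <- matrix(0, N, N)
  # Excitatory columns: sparse log-normal, E[w^2] = 1 before scaling, so the
  # E-submatrix bulk radius is ~ exc_scale.
  maskE <- matrix(stats::runif(N * nE) < p_con, N, nE)
  wE <- matrix(stats::rlnorm(N * nE, meanlog = -1, sdlog = 1), N, nE)
  W[, seq_len(nE)] <- (exc_scale / sqrt(N * p_con)) * wE * maskE
  W[cbind(seq_len(nE), seq_len(nE))] <- 0
  # Inhibitory columns: dense, initialized to roughly balance excitatory
  # row sums; the stabilization loop is free to reshape them (kept <= 0).
  rowE <- rowSums(W[, seq_len(nE), drop = FALSE])
  base_inh <- -rowE / nI
  W[, nE + seq_len(nI)] <- base_inh *
    matrix(stats::rlnorm(N * nI, meanlog = -0.125, sdlog = 0.5), N, nI)
  W[cbind(nE + seq_len(nI), nE + seq_len(nI))] <- 0

  # One eigendecomposition of the shifted system per evaluation yields the
  # spectral abscissa, both Gramians (P ctrl, Q obs, B = C = I), the H2^2
  # objective Tr(P), and hence the gradient 2 Q P.
  lyap_pair <- function(W, s) {
    e <- eigen(W - s * diag(N))
    amax <- max(Re(e$values)) + s
    if (amax >= s) return(list(ok = FALSE, abscissa = amax))
    V <- e$vectors
    Vi <- solve(V)
    denom <- outer(e$values, e$values, `+`)
    Pt <- -(Vi %*% t(Vi)) / denom
    P <- Re(V %*% Pt %*% t(V))
    Qt <- -(t(V) %*% V) / denom
    Q <- Re(t(Vi) %*% Qt %*% Vi)
    list(ok = TRUE, abscissa = amax, P = P, Q = Q, J = sum(diag(P)))
  }

  log_rows <- list()
  eta <- 0.05
  a0 <- spectral_abscissa(W)
  a <- a0
  s <- a0 + max(0.05, 0.02 * abs(a0))
  cur <- lyap_pair(W, s)
  iter <- 0
  fails <- 0
  while (a >= target_abscissa && iter < max_iter) {
    iter <- iter + 1
    # keep the shift tracking the abscissa: close enough that the Gramians
    # weight the rightmost modes, far enough to stay well conditioned
    s_want <- a + max(0.05, 0.02 * abs(a))
    if (s > s_want + 0.2 || s < a + 0.02) {
      s <- s_want
      cur <- lyap_pair(W, s)
    }
    G <- 2 * (cur$Q %*% cur$P)
    G[, is_exc] <- 0           # only inhibitory weights are optimized
    G[cbind(seq_len(N), seq_len(N))] <- 0
    accepted <- FALSE
    trial <- cur
    for (k in 1:30) {
      Wnew <- W - eta * G
      Wnew[, !is_exc] <- pmin(Wnew[, !is_exc, drop = FALSE], 0)  # Dale
      diag(Wnew) <- 0
      trial <- lyap_pair(Wnew, s)
      if (trial$ok && trial$J < cur$J) {
        accepted <- TRUE
        break
      }
      eta <- eta / 2
      if (eta < 1e-14) break
    }
    log_rows[[iter]] <- data.frame(iter = iter, shift = s,
                                   obj_before = cur$J,
                                   obj_after = if (accepted) trial$J else cur$J,
                                   abscissa = if (accepted) trial$abscissa else a,
                                   accepted = accepted, step = eta)
    if (accepted) {
      W <- Wnew
      cur <- trial
      a <- trial$abscissa
      eta <- eta * 1.4
      fails <- 0
    } else {
      # stalled line search: re-anchor the shift and retry from a fresh step
      fails <- fails + 1
      if (fails > 3) break
      s <- a + max(0.05, 0.02 * abs(a))
      cur <- lyap_pair(W, s)
      eta <- 0.05
    }
  }
  if (a >= target_abscissa)
    stop("ISN stabilization did not converge: final spectral abscissa ",
         signif(a, 4), " >= target ", target_abscissa)
  network_model(W, tau = tau, nonlinearity = "relu", family = "isn",
                meta = list(seed = seed, exc = is_exc, exc_scale = exc_scale,
                            p_con = p_con, target_abscissa = target_abscissa,
                            log = do.call(rbind, log_rows)))
}

#' Generate a two-unit motif network
#'
#' The two canonical motifs of E/I dynamics: a feedforward ("nonnormal")
#' network in which a source unit drives a sink unit, `W = [[0,0],[w,0]]`,
#' and an oscillatory network with antisymmetric connectivity
#' `W = [[0,-w],[w,0]]`. Both use linear (identity) dynamics.
#'
#' @param kind `"feedforward"` or `"oscillatory"`.
#' @param w Nonnegative connectivity scale.
#' @param tau Time constant (ms).
#' @param readout_angle Angle (rad) of the 1D readout from the first unit;
#'   0 reads the source/first unit, `pi/2` the sink/second unit.
#'
#' @return A `network_model` with a 1 x 2 readout.
#' @export
generate_2d <- function(kind = c("feedforward", "oscillatory"), w = 1,
                        tau = 150, readout_angle = pi / 2) {
  kind <- match.arg(kind)
  stopifnot(w >= 0)
  W <- if (kind == "feedforward") matrix(c(0, w, 0, 0), 2, 2)
       else matrix(c(0, w, -w, 0), 2, 2)
  C <- matrix(c(cos(readout_angle), sin(readout_angle)), 1, 2)
  network_model(W, C = C, tau = tau, nonlinearity = "identity",
                family = paste0("2d-", kind),
                meta = list(w = w, readout_angle = readout_angle))
}

#' Specification of a random-network ensemble member
#'
#' @param family One of `"random"`, `"skew"`, `"shifted_skew"`.
#' @param scale Family scale: target spectral radius `R` for `"random"`
#'   (in \[0, 0.99\]) and `"skew"` (in \[0, 5\]); eigenvalue real part
#'   `lambda` for `"shifted_skew"` (in \[0, 0.8\]).
#' @param N Network size.
#' @param seed Integer seed.
#' @param tau Time constant (ms).
#' @param skew_radius Radius of the raw matrix `S` used by
#'   `"shifted_skew"`.
#'
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(family = c("random", "skew", "shifted_skew"),
                          scale = 0.5, N = 200, seed = 1, tau = 150,
                          skew_radius = 1) {
  family <- match.arg(family)
  rng <- switch(family, random = c(0, 0.99), skew = c(0, 5),
                shifted_skew = c(0, 0.8))
  if (scale < rng[1] || scale > rng[2])
    stop(sprintf("scale %g outside the %s family range [%g, %g]",
                 scale, family, rng[1], rng[2]))
  structure(list(family = family, scale = scale, N = N, seed = seed,
                 tau = tau, skew_radius = skew_radius),
            class = "ensemble_spec")
}

#' Generate a network from a random ensemble
#'
#' `"random"`: i.i.d. Gaussian entries with standard deviation
#' `R/sqrt(N)`, so the circular-law spectral radius is approximately `R`.
#' `"skew"`: `W = (S - S')/2` for such an `S` (purely imaginary spectrum).
#' `"shifted_skew"`: `W = (S - S')/2 + lambda I`, giving every eigenvalue
#' real part `lambda`.
#'
#' @param spec An [ensemble_spec()].
#' @return A `network_model` with identity nonlinearity.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  N <- spec$N
  draw <- function(R) matrix(stats::rnorm(N * N, sd = R / sqrt(N)), N, N)
  W <- switch(spec$family,
    random = draw(spec$scale),
    skew = { S <- draw(spec$scale); (S - t(S)) / 2 },
    shifted_skew = {
      S <- draw(spec$skew_radius)
      (S - t(S)) / 2 + spec$scale * diag(N)
    })
  network_model(W, tau = spec$tau, nonlinearity = "identity",
                family = spec$family,
                meta = list(seed = spec$seed, scale = spec$scale))
}

#' Generate a random readout matrix
#'
#' Entries are i.i.d. zero-mean Gaussian. The default scale
#' `0.05/sqrt(N)` calibrates the readout so that firing-rate fluctuations
#' with a standard deviation of ~30 Hz are decoded into torques with a
#' standard deviation of ~1.5 N m, the natural range for the reaches
#' considered here. The alternative `"N"` scaling (`0.05/N`) is provided
#' for comparison.
#'
#' @param N Number of neurons.
#' @param n_outputs Number of readout channels (2 for the arm's torques).
#' @param seed Integer seed.
#' @param sigma0 Numerator of the scale.
#' @param scaling `"sqrtN"` (default) or `"N"`.
#'
#' @return `n_outputs x N` readout matrix.
#' @export
generate_readout <- function(N, n_outputs = 2, seed = 1, sigma0 = 0.05,
                             scaling = c("sqrtN", "N")) {
  scaling <- match.arg(scaling)
  stopifnot(n_outputs < N)
  set.seed(seed)
  sd <- if (scaling == "sqrtN") sigma0 / sqrt(N) else sigma0 / N
  matrix(stats::rnorm(n_outputs * N, sd = sd), n_outputs, N)
}

#' Set the network baseline from target resting rates
#'
#' Draws nonnegative target baseline rates with the requested mean and
#' standard deviation across neurons (Gaussian draws, rectified at zero,
#' with a few moment-restoring passes), then sets the constant input
#' `h = (I - W) r_star` so that `x = r_star` is an exact fixed point of the
#' rate dynamics with `u = 0` under the rectified-linear nonlinearity.
#'
#' @param model A `network_model`.
#' @param mean_rate,sd_rate Target mean and s.d. of baseline rates (Hz).
#' @param seed Integer seed.
#'
#' @return The model with `h` and `r_star` set.
#' @export
set_baseline <- function(model, mean_rate = 5, sd_rate = 5, seed = 1) {
  stopifnot(inherits(model, "network_model"), mean_rate >= 0, sd_rate >= 0)
  set.seed(seed)
  N <- model$N
  r <- pmax(stats::rnorm(N, mean_rate, sd_rate), 0)
  if (sd_rate > 0) {
    for (k in 1:40) {
      r <- r - mean(r)
      s <- stats::sd(r)
      if (s > 0) r <- r * (sd_rate / s)
      r <- pmax(r + mean_rate, 0)
    }
  } else {
    r <- rep(mean_rate, N)
  }
  model$r_star <- r
  model$h <- drop((diag(N) - model$W) %*% r)
  model
}

#' Euler simulation of the rate network
#'
#' Integrates `tau dx/dt = -x + W phi(x) + h + u(t)` with the explicit
#' Euler scheme at step `dt`, and reports rates `r = phi(x)` and the raw
#' readout `m = C r` (when the model has a readout).
#'
#' @param model A `network_model`.
#' @param u Input trajectory: `n_steps x N` matrix, or `NULL` for zero input.
#' @param x0 Initial state; defaults to the baseline fixed point `r_star`.
#' @param dt Time step (ms); must satisfy `dt <= tau/10`.
#' @param T_ms Duration (ms); used when `u` is `NULL`.
#'
#' @return List with time vector `time` (ms), state matrix `x`
#'   (`n_steps+1` rows), rates `r`, and `m` (readout of rates) or `NULL`.
#' @export
simulate_network <- function(model, u = NULL, x0 = NULL, dt = 1, T_ms = NULL) {
  stopifnot(inherits(model, "network_model"), dt <= model$tau / 10)
  N <- model$N
  if (is.null(u)) {
    stopifnot(!is.null(T_ms))
    H <- round(T_ms / dt)
    u <- matrix(0, H, N)
  } else {
    u <- as.matrix(u)
    stopifnot(ncol(u) == N)
    H <- nrow(u)
  }
  if (is.null(x0)) x0 <- model$r_star
  phi <- phi_fun(model$nonlinearity)
  x <- matrix(0, H + 1, N)
  x[1, ] <- x0
  cur <- x0
  for (k in seq_len(H)) {
    cur <- cur + (dt / model$tau) * (-cur + drop(model$W %*% phi(cur)) +
                                       model$h + u[k, ])
    if (any(!is.finite(cur)))
      stop("network state diverged (non-finite) at step ", k)
    x[k + 1, ] <- cur
  }
  r <- t(apply(x, 1, phi))
  m <- if (!is.null(model$C)) r %*% t(model$C) else NULL
  list(time = seq(0, by = dt, length.out = H + 1), x = x, r = r, m = m)
}
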