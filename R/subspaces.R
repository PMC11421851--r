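#' Soft-normalize and center firing-rate traces
#'
#' Applies the standard soft normalization `r / (range(r) + 5)` per neuron
#' (range taken over all times and conditions) followed by mean-centering
#' across conditions at each time point, so that each neuron contributes
#' comparably to population analyses regardless of its firing-rate range.
#'
#' @param rates `N x M x T` array of nonnegative trial-averaged rates
#'   (neurons x conditions x time bins).
#' @param soft Softening constant added to the range (default 5 Hz).
#' @param center Mean-center across conditions at each time (default TRUE).
#' @return Array of the same shape.
#' @export
normalize_rates <- function(rates, soft = 5, center = TRUE) {
  stopifnot(length(dim(rates)) == 3)
  N <- dim(rates)[1]
  rng <- apply(rates, 1, function(v) diff(range(v)))
  out <- rates / (rng + soft)            # recycles over the first margin
  if (center) {
    cm <- apply(out, c(1, 3), mean)      # N x T condition means
    out <- out - aperm(replicate(dim(rates)[2], cm), c(1, 3, 2))
  }
  out
}

# Covariance of an N x (M*T) epoch matrix (rows = neurons), centering rows.
epoch_covariance <- function(X) {
  Xc <- X - rowMeans(X)
  tcrossprod(Xc) / (ncol(X) - 1)
}

#' Collect epoch activity matrices for subspace identification
#'
#' Slices normalized activity into the preparatory epoch (a window before
#' the end of the delay) and the movement epoch (a window starting after
#' the go cue), concatenating conditions along columns.
#'
#' @param rates `N x M x T` normalized activity array.
#' @param time Time vector (ms, go cue at 0) of length `T`.
#' @param prep_window Window (ms) before the go cue, default
#'   `c(-300, 0)`.
#' @param move_window Window (ms) after the go cue, default
#'   `c(50, 350)`.
#' @return List with `prep` and `move` (`N x (M*bins)` matrices) and the
#'   bin masks.
#' @export
epoch_activity <- function(rates, time, prep_window = c(-300, 0),
                           move_window = c(50, 350)) {
  stopifnot(length(time) == dim(rates)[3])
  sel <- function(w) time >= w[1] & time < w[2]
  pick <- function(mask) {
    sub <- rates[, , mask, drop = FALSE]
    matrix(sub, nrow = dim(rates)[1])
  }
  list(prep = pick(sel(prep_window)), move = pick(sel(move_window)),
       prep_mask = sel(prep_window), move_mask = sel(move_window))
}

# Project the combined frame's gradient onto the Stiefel tangent space and
# retract via the polar factor (closest orthonormal frame).
stiefel_retract <- function(Wf) {
  sv <- svd(Wf)
  sv$u %*% t(sv$v)
}

#' Identify orthogonal preparatory and movement subspaces
#'
#' Finds orthonormal bases `W_prep` (N x d_prep) and `W_mov` (N x d_mov),
#' mutually orthogonal, maximizing the mean normalized captured variance
#' `0.5 * (tr(W_prep' C_prep W_prep)/Z_prep + tr(W_mov' C_mov W_mov)/Z_mov)`
#' where `Z_d` is the variance captured by the best unconstrained
#' d-dimensional subspace (top-d eigenvalue sum). Optimization is gradient
#' ascent on the combined `N x (d_prep + d_mov)` orthonormal frame with
#' polar retraction, from an eigenvector-based initialization plus random
#' restarts; the best objective is kept.
#'
#' @param prep,move `N x samples` epoch activity matrices (or covariance
#'   matrices if `are_cov = TRUE`).
#' @param d_prep,d_mov Subspace dimensions (default 6).
#' @param are_cov Set `TRUE` when `prep`/`move` already are N x N
#'   covariances.
#' @param n_restarts Number of random restarts (plus the spectral start).
#' @param max_iter,tol Ascent iteration budget and relative-improvement
#'   stopping tolerance.
#' @param seed Seed for the random restarts.
#' @return Object of class `subspace_pair`: `W_prep`, `W_mov`,
#'   normalizers `Z_prep`, `Z_mov`, captured-variance fractions
#'   `frac_prep`, `frac_mov` (captured / best-possible), absolute captured
#'   variances, the objective, and a convergence flag.
#' @export
identify_subspaces <- function(prep, move, d_prep = 6, d_mov = 6,
                               are_cov = FALSE, n_restarts = 10,
                               max_iter = 2000, tol = 1e-12, seed = 1) {
  Cp <- if (are_cov) (prep + t(prep)) / 2 else epoch_covariance(prep)
  Cm <- if (are_cov) (move + t(move)) / 2 else epoch_covariance(move)
  N <- nrow(Cp)
  stopifnot(d_prep + d_mov <= N)
  ep <- eigen(Cp, symmetric = TRUE)
  em <- eigen(Cm, symmetric = TRUE)
  Zp <- sum(ep$values[seq_len(d_prep)])
  Zm <- sum(em$values[seq_len(d_mov)])
  if (Zp <= 0 || Zm <= 0) stop("epoch covariance has no variance to capture")
  i1 <- seq_len(d_prep)
  i2 <- d_prep + seq_len(d_mov)

  objective <- function(Wf) {
    W1 <- Wf[, i1, drop = FALSE]; W2 <- Wf[, i2, drop = FALSE]
    0.5 * (sum(W1 * (Cp %*% W1)) / Zp + sum(W2 * (Cm %*% W2)) / Zm)
  }
  egrad <- function(Wf) {
    cbind(Cp %*% Wf[, i1, drop = FALSE] / Zp,
          Cm %*% Wf[, i2, drop = FALSE] / Zm)
  }
  ascend <- function(Wf) {
    f <- objective(Wf)
    step <- 0.5
    for (it in seq_len(max_iter)) {
      G <- egrad(Wf)
      # Riemannian gradient: project onto the Stiefel tangent space
      WtG <- crossprod(Wf, G)
      R <- G - Wf %*% (WtG + t(WtG)) / 2
      gnorm <- sqrt(sum(R^2))
      if (gnorm < 1e-14) break
      improved <- FALSE
      for (ls in 1:40) {
        Wnew <- stiefel_retract(Wf + step * R)
        fnew <- objective(Wnew)
        if (fnew > f) {
          improved <- fnew - f > tol * max(1, abs(f))
          Wf <- Wnew
          f <- fnew
          step <- step * 1.5
          break
        }
        step <- step / 2
      }
      if (!improved) break
    }
    list(W = Wf, f = f, iters = it)
  }

  # spectral start: top prep eigenvectors, then top movement eigenvectors of
  # the covariance deflated against them
  W1 <- ep$vectors[, seq_len(d_prep), drop = FALSE]
  proj <- diag(N) - tcrossprod(W1)
  em2 <- eigen(proj %*% Cm %*% proj, symmetric = TRUE)
  starts <- list(cbind(W1, em2$vectors[, seq_len(d_mov), drop = FALSE]))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    M <- matrix(stats::rnorm(N * (d_prep + d_mov)), N)
    starts[[r + 1]] <- qr.Q(qr(M))
  }
  best <- NULL
  for (st in starts) {
    res <- ascend(stiefel_retract(st))
    if (is.null(best) || res$f > best$f) best <- res
  }
  Wf <- best$W
  W1 <- Wf[, i1, drop = FALSE]; W2 <- Wf[, i2, drop = FALSE]
  var_p <- sum(W1 * (Cp %*% W1))
  var_m <- sum(W2 * (Cm %*% W2))
  structure(list(W_prep = W1, W_mov = W2, Z_prep = Zp, Z_mov = Zm,
                 var_prep = var_p, var_mov = var_m,
                 frac_prep = var_p / Zp, frac_mov = var_m / Zm,
                 total_var_prep = sum(pmax(ep$values, 0)),
                 total_var_mov = sum(pmax(em$values, 0)),
                 objective = best$f,
                 converged = best$iters < max_iter),
            class = "subspace_pair")
}

#' @export
print.subspace_pair <- function(x, ...) {
  cat(sprintf("orthogonal subspaces: d_prep=%d, d_mov=%d, objective %.4f\n",
              ncol(x$W_prep), ncol(x$W_mov), x$objective))
  cat(sprintf("  captured variance: prep %.1f%% of total (%.1f%% of best-d), mov %.1f%% (%.1f%%)\n",
              100 * x$var_prep / x$total_var_prep, 100 * x$frac_prep,
              100 * x$var_mov / x$total_var_mov, 100 * x$frac_mov))
  invisible(x)
}

#' Subspace occupancy time course
#'
#' Projects activity onto a basis and sums the across-condition variance
#' over basis dimensions at each time bin. With a single condition the
#' occupancy is identically zero.
#'
#' @param rates `N x M x T` (normalized) activity array.
#' @param basis `N x d` orthonormal basis.
#' @param normalize If `TRUE`, scale the curve to a maximum of 1.
#' @return Numeric vector of length `T`.
#' @export
occupancy <- function(rates, basis, normalize = FALSE) {
  stopifnot(length(dim(rates)) == 3, nrow(basis) == dim(rates)[1])
  M <- dim(rates)[2]; Tb <- dim(rates)[3]
  if (M < 2) return(rep(0, Tb))
  occ <- vapply(seq_len(Tb), function(t) {
    proj <- crossprod(basis, rates[, , t])      # d x M
    sum(apply(proj, 1, stats::var))
  }, numeric(1))
  if (normalize && max(occ) > 0) occ <- occ / max(occ)
  occ
}

#' Movement onset from a hand-speed profile
#'
#' Defines movement onset as the first time the hand speed crosses a
#' threshold, plus a fixed lag (accounting for conduction delays and
#' muscle inertia when comparing with recorded behavior).
#'
#' @param speed Hand-speed trajectory.
#' @param time Time vector (same length).
#' @param threshold Speed threshold; default 5% of the profile's peak.
#' @param lag Added lag (ms, default 120).
#' @return Onset time (ms).
#' @export
movement_onset <- function(speed, time, threshold = NULL, lag = 120) {
  stopifnot(length(speed) == length(time))
  if (is.null(threshold)) threshold <- 0.05 * max(speed)
  idx <- which(speed >= threshold)
  if (length(idx) == 0) stop("speed never crosses the threshold")
  time[idx[1]] + lag
}
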