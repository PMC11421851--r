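#' Preparation index of a controlled reach
#'
#' Ratio of the integrated squared input norm during the delay epoch to
#' that during the movement epoch: delay steps are those strictly before
#' the go cue (`t < 0`); the go-cue sample belongs to the movement epoch.
#' The index is invariant to rescaling the inputs.
#'
#' @param traj A `reach_trajectory` (needs `time`, `dt` and `u`), or an
#'   `H x m` input matrix if `time` is supplied.
#' @param time Optional vector of left-endpoint times (ms, go cue at 0)
#'   when `traj` is a bare matrix.
#' @param dt Optional step (ms); inferred from `time` when missing.
#' @return Scalar preparation index.
#' @export
preparation_index <- function(traj, time = NULL, dt = NULL) {
  if (is.list(traj)) {
    u <- traj$u
    time <- traj$time
    dt <- traj$dt
  } else {
    u <- as.matrix(traj)
  }
  stopifnot(!is.null(time), nrow(u) == length(time))
  if (is.null(dt)) dt <- if (length(time) > 1) time[2] - time[1] else 0
  prep <- time < -abs(dt) * 1e-9
  e_prep <- sum(u[prep, , drop = FALSE]^2)
  e_move <- sum(u[!prep, , drop = FALSE]^2)
  if (e_move <= 0)
    stop("preparation index undefined: no input energy in the movement epoch")
  e_prep / e_move
}

#' Observability Gramian of a stable linear system
#'
#' Solves `A' Q + Q A + C' C = 0` for Hurwitz `A`.
#'
#' @param A Hurwitz state matrix.
#' @param C Readout matrix (k x N).
#' @return Symmetric positive-semidefinite `Q`.
#' @export
observability_gramian <- function(A, C) {
  C <- matrix(C, ncol = ncol(as.matrix(A)))
  lyapunov_solve(A, crossprod(C), form = "obs")
}

#' Controllability Gramian of a stable linear system
#'
#' Solves `A P + P A' + B B' = 0`; inputs drive every state direction
#' (`B = I`) unless a `B` is given.
#'
#' @param A Hurwitz state matrix.
#' @param B Input matrix (defaults to identity).
#' @return Symmetric positive-semidefinite `P`.
#' @export
controllability_gramian <- function(A, B = NULL) {
  A <- as.matrix(A)
  BBt <- if (is.null(B)) diag(nrow(A)) else tcrossprod(as.matrix(B))
  lyapunov_solve(A, BBt, form = "ctrl")
}

#' Orthonormal basis of the readout nullspace
#'
#' Returns a `(N-k) x N` matrix whose rows form an orthonormal basis of
#' the nullspace of the full-row-rank readout `C` (activity patterns that
#' produce no instantaneous output).
#'
#' @param C Readout matrix (k x N), full row rank.
#' @return `(N-k) x N` matrix `Cperp` with `Cperp %*% t(C) = 0` and
#'   `Cperp %*% t(Cperp) = I`.
#' @export
nullspace_basis <- function(C) {
  C <- as.matrix(C)
  k <- nrow(C); N <- ncol(C)
  sv <- svd(C, nu = 0, nv = N)
  if (k >= N || min(sv$d) < 1e-12 * max(sv$d))
    stop("C must have full row rank k < N")
  t(sv$v[, (k + 1):N, drop = FALSE])
}

# Linearized dynamics used for all Gramian summaries: identity nonlinearity,
# A = (-I + W)/tau.
linearized_dynamics <- function(model) {
  (-diag(model$N) + model$W) / model$tau
}

#' Nullspace observability (alpha)
#'
#' Prospective potency of the readout nullspace: the trace of the
#' observability Gramian restricted to the nullspace of `C`, normalized by
#' the nullspace dimension. Large alpha means output-null activity
#' patterns seed large subsequent output transients. Invariant to the
#' choice of nullspace basis and to orthogonal state re-coordinations.
#'
#' @param A Hurwitz dynamics matrix (e.g. `(-I + W)/tau`).
#' @param C Readout matrix, full row rank.
#' @return Scalar `alpha >= 0`.
#' @export
alpha_metric <- function(A, C) {
  C <- matrix(C, ncol = ncol(as.matrix(A)))
  Q <- observability_gramian(A, C)
  Cperp <- nullspace_basis(C)
  sum(diag(Cperp %*% Q %*% t(Cperp))) / nrow(Cperp)
}

#' Readout controllability (beta)
#'
#' Trace of the controllability Gramian (isotropic input, `B = I`)
#' restricted to the readout rows, normalized by the number of readout
#' dimensions. Large beta means the network state is easily steered along
#' the readout, so movement can be produced by late inputs alone.
#'
#' @inheritParams alpha_metric
#' @return Scalar `beta >= 0`.
#' @export
beta_metric <- function(A, C) {
  C <- matrix(C, ncol = ncol(as.matrix(A)))
  P <- controllability_gramian(A)
  sum(diag(C %*% P %*% t(C))) / nrow(C)
}

#' Gramian summary of a network
#'
#' Computes alpha and beta for a `network_model` at its linearization
#' `A = (-I + W)/tau` (identity nonlinearity), with the model's readout.
#'
#' @param model A `network_model` with a readout.
#' @param C Optional readout override.
#' @return List with `alpha`, `beta`, `A`, `C`, `N` (class
#'   `gramian_summary`).
#' @export
gramian_summary <- function(model, C = NULL) {
  if (is.null(C)) C <- model$C
  stopifnot(!is.null(C))
  A <- linearized_dynamics(model)
  structure(list(alpha = alpha_metric(A, C), beta = beta_metric(A, C),
                 A = A, C = C, N = model$N),
            class = "gramian_summary")
}

#' Fit the linear preparation-index predictor
#'
#' Ordinary least squares of the preparation index on z-scored alpha and
#' beta, with k-fold cross-validated R^2 (folds split at random but
#' reproducibly), plus single-predictor cross-validated R^2 values for the
#' ablation comparison.
#'
#' @param records Data frame with columns `alpha`, `beta`, `prep_index`.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return Object of class `prep_prediction`: coefficients `k0`,
#'   `k_alpha`, `k_beta` (on the z-scored predictors), `r2_cv`,
#'   `r2_alpha_only`, `r2_beta_only`, the z-scoring parameters, and the
#'   fitted `lm`.
#' @export
fit_prep_predictor <- function(records, folds = 5, seed = 1) {
  stopifnot(all(c("alpha", "beta", "prep_index") %in% names(records)),
            nrow(records) >= 2 * folds)
  if (stats::sd(records$alpha) == 0 || stats::sd(records$beta) == 0)
    stop("degenerate (constant) predictor")
  z <- function(v) (v - mean(v)) / stats::sd(v)
  d <- data.frame(a = z(records$alpha), b = z(records$beta),
                  y = records$prep_index)
  fit <- stats::lm(y ~ a + b, data = d)

  cv_r2 <- function(formula) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(folds), nrow(d)))
    pred <- numeric(nrow(d))
    for (f in seq_len(folds)) {
      hold <- fold == f
      m <- stats::lm(formula, data = d[!hold, , drop = FALSE])
      pred[hold] <- stats::predict(m, newdata = d[hold, , drop = FALSE])
    }
    1 - sum((d$y - pred)^2) / sum((d$y - mean(d$y))^2)
  }
  structure(list(k0 = unname(stats::coef(fit)[1]),
                 k_alpha = unname(stats::coef(fit)[2]),
                 k_beta = unname(stats::coef(fit)[3]),
                 r2_cv = cv_r2(y ~ a + b),
                 r2_alpha_only = cv_r2(y ~ a),
                 r2_beta_only = cv_r2(y ~ b),
                 scale = list(alpha = c(mean = mean(records$alpha),
                                        sd = stats::sd(records$alpha)),
                              beta = c(mean = mean(records$beta),
                                       sd = stats::sd(records$beta))),
                 fit = fit, records = records),
            class = "prep_prediction")
}

#' Predict preparation indices from a fitted predictor
#'
#' Applies the stored z-scoring and linear coefficients to new networks'
#' alpha/beta records and returns predicted preparation indices and, if
#' `prep_index` is present, the transfer R^2.
#'
#' @param object A `prep_prediction`.
#' @param newdata Data frame with `alpha` and `beta` (and optionally
#'   `prep_index`).
#' @param ... Unused.
#' @return List with `predicted` and (when available) `r2`.
#' @export
predict.prep_prediction <- function(object, newdata, ...) {
  a <- (newdata$alpha - object$scale$alpha["mean"]) / object$scale$alpha["sd"]
  b <- (newdata$beta - object$scale$beta["mean"]) / object$scale$beta["sd"]
  pred <- object$k0 + object$k_alpha * a + object$k_beta * b
  out <- list(predicted = pred)
  if (!is.null(newdata$prep_index)) {
    y <- newdata$prep_index
    out$r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  out
}

#' @export
print.prep_prediction <- function(x, ...) {
  cat(sprintf("prep index ~ %.3g %+.3g alpha_z %+.3g beta_z  (CV R2 = %.3f)\n",
              x$k0, x$k_alpha, x$k_beta, x$r2_cv))
  cat(sprintf("  single-predictor CV R2: alpha %.3f, beta %.3f\n",
              x$r2_alpha_only, x$r2_beta_only))
  invisible(x)
}
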