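#' Solve a continuous-time Lyapunov equation
#'
#' Computes the solution `X` of `A' X + X A + M = 0` (form `"obs"`) or of
#' `A X + X A' + M = 0` (form `"ctrl"`) for a Hurwitz matrix `A` and a
#' symmetric right-hand side `M`, via the eigendecomposition of `A`
#' (diagonalize, divide by eigenvalue sums, transform back). The result is
#' symmetrized and checked against the equation residual.
#'
#' @param A Square Hurwitz matrix (all eigenvalue real parts < 0).
#' @param M Symmetric matrix of the same dimension.
#' @param form `"obs"` or `"ctrl"`, see above.
#' @param check If `TRUE`, error when the relative Frobenius residual of the
#'   equation exceeds `tol`.
#' @param tol Relative residual tolerance.
#'
#' @return Symmetric solution matrix.
#' @export
lyapunov_solve <- function(A, M, form = c("obs", "ctrl"), check = TRUE, tol = 1e-8) {
  form <- match.arg(form)
  A <- as.matrix(A); M <- as.matrix(M)
  n <- nrow(A)
  stopifnot(ncol(A) == n, all(dim(M) == n))
  if (form == "ctrl") A <- t(A)
  e <- eigen(A)
  if (max(Re(e$values)) >= 0)
    stop("A is not Hurwitz (max Re eig = ", signif(max(Re(e$values)), 4), ")")
  V <- e$vectors
  # A' X + X A = -M  with A = V L V^{-1}:
  # let Xt = V' X V, Mt = V' M V; then L Xt + Xt L = -Mt.
  X <- tryCatch({
    Vi <- solve(V)
    Mt <- t(V) %*% M %*% V
    denom <- outer(e$values, e$values, `+`)
    Xt <- -Mt / denom
    Xe <- Re(t(Vi) %*% Xt %*% Vi)
    Xe <- (Xe + t(Xe)) / 2
    res <- t(A) %*% Xe + Xe %*% A + M
    if (norm(res, "F") / max(norm(M, "F"), .Machine$double.eps) > tol) NULL
    else Xe
  }, error = function(err) NULL)
  if (is.null(X)) {
    # defective or ill-conditioned eigenbasis: vectorized (Kronecker) solve
    n2 <- nrow(A)
    if (n2 > 120)
      stop("Lyapunov solve failed: A is (nearly) defective and too large ",
           "for the dense fallback")
    K <- kronecker(diag(n2), t(A)) + kronecker(t(A), diag(n2))
    X <- matrix(solve(K, -as.vector(M)), n2, n2)
    X <- (X + t(X)) / 2
  }
  if (check) {
    res <- t(A) %*% X + X %*% A + M
    rel <- norm(res, "F") / max(norm(M, "F"), .Machine$double.eps)
    if (rel > tol)
      stop("Lyapunov solve residual too large (", signif(rel, 3), ")")
  }
  X
}
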