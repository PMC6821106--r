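#' Matrix exponential
#'
#' Thin wrapper around [Matrix::expm()] (Ward's balanced Pade approximation).
#' The closed-loop generators assembled in this package are stiff and highly
#' non-normal (1-norms of order 1e3 once the feedback gains at `R = 1e-5`
#' enter), and a balanced scaling-and-squaring scheme is required to keep the
#' monodromy constructions accurate to ~1e-12.
#'
#' @param M square numeric matrix.
#' @return `exp(M)` as a base matrix.
#' @keywords internal
expm_mat <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M)))
}

#' Spectral radius and spectral abscissa
#'
#' Decision statistics for discrete (`spectral_radius`) and continuous
#' (`spectral_abscissa`) linear systems: the maximum eigenvalue modulus and
#' the maximum eigenvalue real part, respectively.
#'
#' @param M square numeric matrix.
#' @return scalar.
#' @export
spectral_radius <- function(M) {
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' @rdname spectral_radius
#' @export
spectral_abscissa <- function(M) {
  max(Re(eigen(M, only.values = TRUE)$values))
}

#' Zero-order-hold discretization
#'
#' Discretizes `dx/dt = A x + B u` with the control held constant over each
#' step: `x[k+1] = Ad x[k] + Bd u[k]` with `Ad = exp(A dt)` and
#' `Bd = int_0^dt exp(A s) ds B`. The integral is evaluated through the
#' augmented matrix exponential `exp([[A, B], [0, 0]] dt)`, which remains
#' defined when `A` is singular (the hand plant has a zero first column, so
#' the textbook `A^-1 (exp(A dt) - I) B` formula does not apply).
#'
#' @param A n x n system matrix.
#' @param B n x m input matrix.
#' @param dt step length (s), > 0.
#' @return list with elements `Ad` (n x n) and `Bd` (n x m).
#' @export
zoh_discretize <- function(A, B, dt) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), dt > 0)
  B <- as.matrix(B)
  n <- nrow(A)
  m <- ncol(B)
  E <- expm_mat(rbind(cbind(A, B), matrix(0, m, n + m)) * dt)
  list(Ad = E[1:n, 1:n, drop = FALSE], Bd = E[1:n, (n + 1):(n + m), drop = FALSE])
}

#' Solve the Sylvester equation gamma S + S beta + alpha = 0
#'
#' The inter-sample integrals of the intermittent-control monodromy matrices
#' reduce to Sylvester equations of this form. The solution is unique iff
#' `gamma` and `-beta` share no eigenvalue.
#'
#' The solver diagonalizes `beta` and solves one shifted linear system per
#' eigenvector (columns of `S` in the eigenbasis of `beta`); if `beta`'s
#' eigenvector matrix is ill-conditioned it falls back to the dense Kronecker
#' vectorization `(I (x) gamma + beta' (x) I) vec(S) = -vec(alpha)`. The
#' residual is always checked.
#'
#' @param gamma p x p matrix.
#' @param beta r x r matrix.
#' @param alpha p x r matrix.
#' @param tol relative residual tolerance (default `1e-10`).
#' @return the p x r solution `S`.
#' @export
sylvester_solve <- function(gamma, beta, alpha, tol = 1e-10) {
  stopifnot(is.matrix(gamma), is.matrix(beta), is.matrix(alpha))
  p <- nrow(gamma)
  r <- nrow(beta)
  stopifnot(ncol(gamma) == p, ncol(beta) == r, nrow(alpha) == p, ncol(alpha) == r)

  S <- NULL
  eb <- eigen(beta)
  if (rcond_ok(eb$vectors)) {
    RHS <- -alpha %*% eb$vectors
    St <- matrix(0 + 0i, p, r)
    for (j in seq_len(r)) {
      M <- gamma + eb$values[j] * diag(p)
      if (rcond_ok(M)) {
        St[, j] <- solve(M, RHS[, j])
      } else {
        S <- NULL
        St <- NULL
        break
      }
    }
    if (!is.null(St)) {
      S <- St %*% solve(eb$vectors)
      S <- if (max(abs(Im(S))) < 1e-8 * max(1, max(abs(Re(S))))) Re(S) else NULL
    }
  }
  if (is.null(S)) {
    # Kronecker fallback (defective or near-singular cases)
    M <- kronecker(diag(r), gamma) + kronecker(t(beta), diag(p))
    if (!rcond_ok(M)) {
      stop("singular Sylvester equation: gamma and -beta share an eigenvalue ",
           "(or nearly so); no unique solution exists", call. = FALSE)
    }
    S <- matrix(solve(M, -as.vector(alpha)), p, r)
  }

  resid <- max(abs(gamma %*% S + S %*% beta + alpha))
  if (resid > tol * max(1, max(abs(alpha)))) {
    stop(sprintf(paste0("Sylvester residual %.3e exceeds tolerance; gamma and ",
                        "-beta have (near-)overlapping spectra"), resid),
         call. = FALSE)
  }
  S
}

rcond_ok <- function(M, tol = 1e-13) {
  is.finite(rcond(M)) && rcond(M) > tol
}

#' Solve the continuous-time algebraic Riccati equation
#'
#' Finds the symmetric positive-semidefinite stabilizing solution of
#' `A'S + SA - S B R^-1 B' S + Q = 0` by the Hamiltonian eigenvector method:
#' the stable invariant subspace of `H = [[A, -B R^-1 B'], [-Q, -A']]` spans
#' `[X1; X2]` and `S = X2 X1^-1`.
#'
#' @param A n x n system matrix.
#' @param B n x m input matrix.
#' @param Q n x n state weight, positive semidefinite.
#' @param R m x m input weight, positive definite.
#' @return the n x n solution `S` (symmetrized).
#' @export
solve_care <- function(A, B, Q, R) {
  B <- as.matrix(B)
  R <- as.matrix(R)
  n <- nrow(A)
  G <- B %*% solve(R, t(B))
  H <- rbind(cbind(A, -G), cbind(-Q, -t(A)))
  e <- eigen(H)
  stable <- order(Re(e$values))[1:n]
  if (any(Re(e$values[stable]) >= -.Machine$double.eps^0.5)) {
    stop("Riccati synthesis failed: Hamiltonian matrix has no ",
         "n-dimensional stable invariant subspace (pair not stabilizable ",
         "or detectable)", call. = FALSE)
  }
  X <- e$vectors[, stable, drop = FALSE]
  X1 <- X[1:n, , drop = FALSE]
  X2 <- X[(n + 1):(2 * n), , drop = FALSE]
  if (!rcond_ok(X1)) {
    stop("Riccati synthesis failed: stable subspace has no graph ",
         "representation", call. = FALSE)
  }
  S <- Re(X2 %*% solve(X1))
  (S + t(S)) / 2
}

#' Discrete eigenvalue growth over a comparison horizon
#'
#' A discrete eigenvalue `lambda` of a system sampled at `delta` multiplies
#' the state by `|lambda|^(t/delta)` after time `t`. Used to put eigenvalues
#' of systems discretized at different rates on a common footing (e.g. a
#' magnitude of 1.001 at `delta` = 1 ms grows by factor 1.22 over 0.2 s).
#'
#' @param lambda eigenvalue (possibly complex) or its modulus.
#' @param delta discretization step (s).
#' @param horizon comparison time (s).
#' @return growth factor `|lambda|^(horizon/delta)`.
#' @export
eig_growth <- function(lambda, delta = 1e-3, horizon = 0.2) {
  Mod(lambda)^(horizon / delta)
}
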