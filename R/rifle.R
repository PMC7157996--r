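#' Hard thresholding to a sparsity budget
#'
#' Keeps the `s` largest-magnitude entries of `x`, zeroes the rest, and
#' rescales the result to unit l2 norm.  Ties at the s-th magnitude are
#' broken in favour of the lower index, so the operation is deterministic.
#'
#' @param x Numeric vector, not all zero.
#' @param s Integer budget, `1 <= s <= length(x)`.
#' @return Unit-norm vector with at most `s` nonzeros.
#' @export
#' @examples
#' hard_threshold(c(3, -2, 1), 2)
hard_threshold <- function(x, s) {
  if (s < 1) stop("`s` must be at least 1")
  s <- min(s, length(x))
  if (all(x == 0)) stop("cannot threshold the zero vector")
  keep <- order(-abs(x), seq_along(x))[seq_len(s)]
  out <- numeric(length(x))
  out[keep] <- x[keep]
  out / sqrt(sum(out^2))
}

#' Shift a symmetric matrix to positive semi-definiteness
#'
#' Returns `R1 + c * I` with `c = max(0, -lambda_min(R1)) + eps`.  With an
#' identity denominator metric, adding `c * I` adds exactly `c` to every
#' Rayleigh quotient, so the maximizer (over any support) is unchanged
#' while the quotient becomes positive — which keeps the truncated
#' Rayleigh flow well-behaved on indefinite numerators such as the
#' network-penalized \eqn{N - \lambda \tilde L}.
#'
#' @param R1 Symmetric numeric matrix.
#' @param eps Small positive margin added to the shift.
#' @return List with the shifted `matrix` and the `shift` scalar `c`.
#' @export
shift_to_psd <- function(R1, eps = 1e-8) {
  R1 <- as.matrix(R1)
  check_symmetric(R1)
  lam_min <- min(eigen(R1, symmetric = TRUE, only.values = TRUE)$values)
  c_shift <- max(0, -lam_min) + eps
  list(matrix = R1 + diag(c_shift, nrow(R1)), shift = c_shift)
}

# Gershgorin upper bound on the largest eigenvalue of a symmetric matrix.
gershgorin_max <- function(M) max(Matrix::rowSums(abs(M)))

check_symmetric <- function(R1, tol = 1e-10) {
  if (!all(is.finite(R1))) stop("matrix has non-finite entries")
  if (nrow(R1) != ncol(R1) || max(abs(R1 - t(R1))) > tol * max(1, max(abs(R1)))) {
    stop("matrix must be symmetric")
  }
  invisible(TRUE)
}

#' Truncated Rayleigh flow for l0-constrained eigenvector problems
#'
#' Maximizes the Rayleigh quotient \eqn{\rho(\omega) = \omega^\top R_1
#' \omega / \omega^\top \omega} subject to \eqn{\|\omega\|_0 \le s} by
#' iterating a gradient ascent step followed by hard thresholding:
#' \deqn{\omega \leftarrow \mathrm{HT}_s\!\left(\mathrm{normalize}\left(\omega +
#'   \frac{\eta}{\rho} (R_1 \omega - \rho \omega)\right)\right),}
#' until the quotient changes by less than `tol` or `max_iter` is reached.
#' The `1/rho` factor makes the step invariant to the overall scale of
#' `R1` (it is the multiplicative truncated-Rayleigh-flow update
#' specialized to an identity denominator metric); `R1` must therefore be
#' positive semi-definite so the quotient stays positive — shift an
#' indefinite numerator with [shift_to_psd()] first, which changes no
#' iterate.  A dense indefinite `R1` is shifted automatically and the
#' returned quotient reported on the original scale.  The denominator
#' metric is the identity throughout this package, so the admissible
#' step sizes are \eqn{\eta \in (0, 1]}.
#'
#' `R1` may be a dense symmetric matrix or a factored numerator created by
#' [build_numerator()]; the factored form evaluates \eqn{R_1 \omega}
#' without materializing the p-by-p matrix.
#'
#' The flow is a local method: from a single starting point it converges
#' to a support that need not be globally optimal.  When `init` is `NULL`
#' (dense input only) the solver therefore runs a small deterministic
#' multi-start — the leading eigenvectors of `R1` plus coordinate vectors
#' on its largest diagonal entries — and returns the best end point.
#' Supplying `init` (e.g. a warm start from the non-sparse solution, as
#' the fitting routines do) runs a single flow from that point.
#'
#' @param R1 Symmetric numeric matrix, or a `"rayleigh_numerator"`.
#' @param s Sparsity budget.
#' @param eta Step size in (0, 1].
#' @param init Starting vector (renormalized internally); must be nonzero.
#'   `NULL` (the default) uses the deterministic multi-start above;
#'   required for factored numerators.
#' @param max_iter,tol Stopping rule on the change of the quotient.
#' @return List with unit-norm `vector` (at most `s` nonzeros), the final
#'   `value` of the quotient, `iterations`, and `converged`.
#' @export
#' @examples
#' rifle_solve(diag(c(3, 2, 1)), s = 1, init = rep(1, 3))
rifle_solve <- function(R1, s, eta = 0.5, init = NULL,
                        max_iter = 1000, tol = 1e-6) {
  if (!(eta > 0 && eta <= 1)) stop("`eta` must be in (0, 1]")
  offset <- 0
  if (inherits(R1, "rayleigh_numerator")) {
    if (is.null(init)) stop("factored numerators need an explicit `init`")
    p <- R1$p
    mv <- function(x) numerator_matvec(R1, x)
  } else {
    R1 <- as.matrix(R1)
    check_symmetric(R1)
    if (is.null(init)) {
      # deterministic multi-start on the raw matrix; every run reports
      # quotients on the original scale, so the best is well-defined
      p <- nrow(R1)
      if (s < 1 || s > p) stop("`s` must be in [1, p]")
      eg <- eigen(R1, symmetric = TRUE)
      inits <- lapply(seq_len(min(4, p)), function(j) eg$vectors[, j])
      for (j in utils::head(order(-diag(R1)), min(2 * s, p))) {
        v <- numeric(p); v[j] <- 1
        inits <- c(inits, list(v))
      }
      inits <- c(inits, list(rep(1, p)))
      runs <- lapply(inits, function(v) {
        rifle_solve(R1, s = s, eta = eta, init = v,
                    max_iter = max_iter, tol = tol)
      })
      return(runs[[which.max(vapply(runs, `[[`, numeric(1), "value"))]])
    }
    sh <- shift_to_psd(R1)
    R1 <- sh$matrix
    offset <- sh$shift - 1e-8  # report quotients on the original scale
    p <- nrow(R1)
    mv <- function(x) drop(R1 %*% x)
  }
  if (s < 1 || s > p) stop("`s` must be in [1, p]")
  if (!all(is.finite(init)) || all(init == 0)) stop("invalid `init`")
  omega <- hard_threshold(init, s)
  rho <- drop(crossprod(omega, mv(omega)))
  trace <- rho
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    grad_step <- omega + eta / max(rho, 1e-12) * (mv(omega) - rho * omega)
    if (all(grad_step == 0)) break  # degenerate: stay at current iterate
    omega_new <- hard_threshold(grad_step, s)
    rho_new <- drop(crossprod(omega_new, mv(omega_new)))
    delta <- abs(rho_new - rho)
    omega <- omega_new
    rho <- rho_new
    trace <- c(trace, rho)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(vector = omega, value = rho - offset, iterations = it,
       converged = converged, trace = trace - offset)
}
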