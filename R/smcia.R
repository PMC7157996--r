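#' Synthetic-center update given fixed loadings
#'
#' For fixed transformed loadings `a_list`, the optimal unit-norm center b
#' maximizing \eqn{\sum_k (b^\top \tilde X_k a_k)^2} is the leading
#' eigenvector of \eqn{\sum_k M_k} with \eqn{M_k = \tilde X_k a_k a_k^\top
#' \tilde X_k^\top}.  Since \eqn{\sum_k M_k = G G^\top} for the n-by-K
#' matrix \eqn{G = [\tilde X_1 a_1, \ldots, \tilde X_K a_K]}, the update
#' is computed from the thin SVD of `G` (cost n*K, never n^2*K).
#'
#' @param xt List of K transformed block matrices.
#' @param a_list List of K loading vectors.
#' @return Unit-norm center vector of length n, sign-fixed so its
#'   largest-magnitude entry is positive.
#' @export
update_center <- function(xt, a_list) {
  G <- vapply(seq_along(xt), function(k) drop(xt[[k]] %*% a_list[[k]]),
              numeric(nrow(xt[[1]])))
  G <- matrix(G, nrow = nrow(xt[[1]]))
  if (all(G == 0)) stop("all block scores are zero: degenerate axis")
  b <- svd(G, nu = 1, nv = 0)$u[, 1]
  fix_sign(b)
}

#' Rayleigh numerator for one block's loading update
#'
#' The matrix maximized over in a loading update is
#' \eqn{R_1 = g g^\top - \lambda \tilde L + c I} with
#' \eqn{g = \tilde X_k^\top b}: rank one for the unpenalized problem,
#' possibly indefinite once the network penalty is subtracted (`c` is a
#' diagonal shift restoring positive semi-definiteness, see
#' [shift_to_psd()]; it changes every Rayleigh quotient by the constant
#' `c` and leaves the maximizer untouched).  Stored in factored form so
#' matrix-vector products cost O(p + nnz(L)) instead of O(p^2).
#'
#' @param xt_k Transformed block matrix (n x p_k).
#' @param b Unit-norm center vector.
#' @param lambda Nonnegative network penalty weight.
#' @param Lt Transformed Laplacian (required when `lambda > 0`).
#' @param shift Nonnegative diagonal shift.
#' @return A `"rayleigh_numerator"` object usable by [rifle_solve()];
#'   `as.matrix()` materializes the dense matrix.
#' @export
build_numerator <- function(xt_k, b, lambda = 0, Lt = NULL, shift = 0) {
  if (length(b) != nrow(xt_k)) stop("`b` must have length nrow(xt_k)")
  if (lambda < 0) stop("`lambda` must be nonnegative")
  if (lambda > 0 && is.null(Lt)) stop("`Lt` is required when lambda > 0")
  if (!is.null(Lt) && nrow(Lt) != ncol(xt_k)) {
    stop("`Lt` dimension does not match the block")
  }
  structure(
    list(g = drop(crossprod(xt_k, b)), lambda = lambda, Lt = Lt,
         shift = shift, p = ncol(xt_k)),
    class = "rayleigh_numerator")
}

numerator_matvec <- function(num, x) {
  out <- num$g * drop(crossprod(num$g, x))
  if (num$lambda > 0) out <- out - num$lambda * as.numeric(num$Lt %*% x)
  if (num$shift != 0) out <- out + num$shift * x
  out
}

#' @export
as.matrix.rayleigh_numerator <- function(x, ...) {
  out <- tcrossprod(x$g)
  if (x$lambda > 0) out <- out - x$lambda * as.matrix(x$Lt)
  if (x$shift != 0) out <- out + diag(x$shift, x$p)
  out
}

# One sparse axis by block-coordinate ascent (center update by
# eigendecomposition, loading updates by truncated Rayleigh flow).
# `init` supplies b and a_list (typically the non-sparse mCIA axis);
# loadings are first projected onto the sparsity budget.  Returns the
# axis plus the penalized-objective trace.
fit_sparse_axis <- function(design, s, lambda, eta, lt_list, shifts,
                            outer_max_iter, outer_tol,
                            rifle_max_iter, rifle_tol, init) {
  xt <- design$xt
  K <- length(xt)
  a_list <- lapply(seq_len(K), function(k) hard_threshold(init$a[[k]], s[k]))
  b <- init$b

  block_obj <- function(k, b, a) {
    cv <- drop(crossprod(b, xt[[k]] %*% a))
    pen <- if (lambda[k] > 0) lambda[k] * penalty_value(a, lt_list[[k]]) else 0
    cv^2 - pen
  }
  objective <- function(b, a_list) {
    sum(vapply(seq_len(K), function(k) block_obj(k, b, a_list[[k]]), numeric(1)))
  }

  trace <- objective(b, a_list)
  converged <- FALSE
  for (iter in seq_len(outer_max_iter)) {
    b <- update_center(xt, a_list)
    for (k in seq_len(K)) {
      num <- build_numerator(xt[[k]], b, lambda[k], lt_list[[k]], shifts[k])
      if (all(num$g == 0) && lambda[k] == 0) {
        warning("block ", k, ": degenerate (zero) gradient; loading kept fixed")
        next
      }
      res <- rifle_solve(num, s = s[k], eta = eta[k], init = a_list[[k]],
                         max_iter = rifle_max_iter, tol = rifle_tol)
      # ascent safeguard: never accept a loading that lowers the quotient
      rho_old <- drop(crossprod(a_list[[k]], numerator_matvec(num, a_list[[k]])))
      if (res$value >= rho_old) a_list[[k]] <- res$vector
    }
    obj <- objective(b, a_list)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (abs(obj - prev) <= outer_tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("axis did not converge within ", outer_max_iter,
            " outer iterations; returning last iterate")
  }
  # fix signs: center first, then flip each a_k so its covariance with the
  # center scores is nonnegative
  b <- fix_sign(b)
  a_list <- lapply(seq_len(K), function(k) {
    cv <- drop(crossprod(b, xt[[k]] %*% a_list[[k]]))
    if (cv < 0) -a_list[[k]] else a_list[[k]]
  })
  axis <- finish_axis(b, design, a_list = a_list)
  axis$penalty <- sum(vapply(seq_len(K), function(k) {
    if (lambda[k] > 0) lambda[k] * penalty_value(a_list[[k]], lt_list[[k]]) else 0
  }, numeric(1)))
  axis$penalized_objective <- axis$pseudo_eigenvalue - axis$penalty
  axis$converged <- converged
  list(axis = axis, trace = trace)
}

#' Sparse and structured sparse multiple co-inertia analysis
#'
#' Fits the co-inertia model of [fit_mcia()] under an l0 cardinality
#' constraint \eqn{\|a_k\|_0 \le s_k} on every transformed loading vector
#' and, optionally, a graph-Laplacian penalty \eqn{\lambda_k a_k^\top
#' \tilde L_k a_k} discouraging loadings that disagree with a prior
#' feature network (the structured variant; any `lambda > 0` requires the
#' corresponding graph).  Each axis is fitted by block-coordinate ascent:
#' the center update is an exact eigendecomposition ([update_center()]),
#' each loading update an l0-constrained Rayleigh-quotient maximization
#' solved by truncated Rayleigh flow ([rifle_solve()]), iterated until the
#' penalized objective \eqn{\sum_k (b^\top \tilde X_k a_k)^2 - \sum_k
#' \lambda_k a_k^\top \tilde L_k a_k} stabilizes.  The non-sparse mCIA
#' axis is the starting point; the center carries no sparsity constraint.
#' Higher-order axes are extracted from deflated data as in [fit_mcia()].
#'
#' Back-transformation `u_k = Q_k^{-1/2} a_k` preserves the sparsity
#' pattern exactly because the feature metrics are diagonal.
#'
#' @param design A [cia_design()].
#' @param s Sparsity budgets: scalar or length-K vector of integers
#'   (`1 <= s_k <= p_k`).
#' @param lambda Network penalty weights: scalar or length-K vector,
#'   nonnegative; all zero gives plain sparse mCIA.
#' @param graphs Optional list of K [feature_graph()]s (or `NULL` entries
#'   for blocks without a network); required wherever `lambda > 0`.
#'   Precomputed Laplacian matrices are also accepted.
#' @param eta Rifle step size(s) in (0, 1]; scalar or length-K.
#' @param n_axes Number of axes.
#' @param laplacian_variant Passed to [build_laplacian()].
#' @param outer_max_iter,outer_tol Outer (alternating) loop control:
#'   maximum iterations and relative objective-change tolerance.
#' @param rifle_max_iter,rifle_tol Inner Rifle loop control.
#' @param deflation As in [fit_mcia()].
#' @return A `"cia_fit"` with method `"smcia"` or `"ssmcia"`; per-axis
#'   objective traces are kept in `$traces`.
#' @export
#' @examples
#' set.seed(1)
#' x <- list(a = matrix(rnorm(200), 20), b = matrix(rnorm(300), 20))
#' fit <- fit_smcia(cia_design(x), s = 3)
#' tidy(fit)
fit_smcia <- function(design, s, lambda = 0, graphs = NULL, eta = 0.5,
                      n_axes = 1,
                      laplacian_variant = c("normalized", "combinatorial"),
                      outer_max_iter = 100, outer_tol = 1e-5,
                      rifle_max_iter = 1000, rifle_tol = 1e-6,
                      deflation = c("center", "block")) {
  stopifnot(inherits(design, "cia_design"))
  laplacian_variant <- match.arg(laplacian_variant)
  deflation <- match.arg(deflation)
  K <- length(design$blocks)
  s <- rep_len(as.integer(s), K)
  lambda <- rep_len(as.numeric(lambda), K)
  eta <- rep_len(as.numeric(eta), K)
  if (any(s < 1 | s > design$p)) stop("`s` must satisfy 1 <= s_k <= p_k")
  if (any(lambda < 0)) stop("`lambda` must be nonnegative")
  if (any(lambda > 0) && is.null(graphs)) {
    stop("`graphs` is required for blocks with lambda > 0")
  }

  lt_list <- vector("list", K)
  shifts <- numeric(K)
  for (k in seq_len(K)) {
    if (lambda[k] > 0) {
      if (is.null(graphs[[k]])) stop("no graph supplied for block ", k)
      L <- if (inherits(graphs[[k]], "feature_graph")) {
        build_laplacian(graphs[[k]], laplacian_variant)
      } else {
        as.matrix(graphs[[k]])
      }
      Lt <- transform_laplacian(L, design$q[[k]])
      lt_list[[k]] <- Matrix::Matrix(Lt, sparse = TRUE)
      # Gershgorin bound on lambda_max(Lt) dominates -lambda_min(g g^T -
      # lambda Lt); the Rifle iterates are invariant to the shift value,
      # so an upper bound is as good as the exact spectral radius
      shifts[k] <- lambda[k] * gershgorin_max(Lt) + 1e-8
    }
  }

  method <- if (any(lambda > 0)) "ssmcia" else "smcia"
  work <- design
  axes <- vector("list", n_axes)
  traces <- vector("list", n_axes)
  for (r in seq_len(n_axes)) {
    init <- mcia_axis(work)
    res <- fit_sparse_axis(work, s, lambda, eta, lt_list, shifts,
                           outer_max_iter, outer_tol,
                           rifle_max_iter, rifle_tol, init)
    axes[[r]] <- res$axis
    traces[[r]] <- res$trace
    if (r < n_axes) work <- deflate_design(work, axes[[r]], deflation)
  }
  new_cia_fit(axes, design, method = method, traces = traces,
              config = list(s = s, lambda = lambda, eta = eta,
                            laplacian_variant = laplacian_variant,
                            outer_max_iter = outer_max_iter,
                            outer_tol = outer_tol,
                            rifle_max_iter = rifle_max_iter,
                            rifle_tol = rifle_tol,
                            deflation = deflation))
}

#' @rdname fit_smcia
#' @export
fit_ssmcia <- function(design, s, lambda, graphs, ...) {
  if (missing(graphs)) stop("ssmCIA requires feature graphs")
  if (all(lambda == 0)) {
    warning("all lambda are zero: this is plain sparse mCIA")
  }
  fit_smcia(design, s = s, lambda = lambda, graphs = graphs, ...)
}
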