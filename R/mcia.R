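#' Classical multiple co-inertia analysis
#'
#' Finds, for each axis, per-block loading vectors \eqn{u_k} and a common
#' synthetic center \eqn{v} maximizing the weighted sum of squared
#' covariances \eqn{\sum_k w_k (v^\top D X_k Q_k u_k)^2} subject to
#' \eqn{v^\top D v = 1} and \eqn{u_k^\top Q_k u_k = 1}.  The center is the
#' leading eigenvector of the n-by-n matrix
#' \eqn{X^\dagger Q^\dagger X^{\dagger\top} D} formed from the merged
#' weighted tables; equivalently, in the transformed (Euclidean) metric,
#' \eqn{b = D^{1/2} v} is the leading eigenvector of
#' \eqn{\sum_k \tilde X_k \tilde X_k^\top}.  Loadings follow as
#' \eqn{u_k = X_k^\top D v / \|X_k^\top D v\|_{Q_k}}.  Higher-order axes
#' are extracted after deflating every block on the preceding center
#' scores, so successive centers are D-orthogonal.
#'
#' Computation stays in the n-by-n Gram form (cost scales with
#' `n * sum(p)`); no p-by-p matrix is ever formed.
#'
#' @param design A [cia_design()].
#' @param n_axes Number of axes to extract (at most `min(n, sum(p))`, the
#'   number of nonzero eigenvalues the co-inertia operator can have; a
#'   block whose rank is exhausted earlier contributes zero loadings to
#'   later axes).
#' @param deflation `"center"` (default): residualize every block on the
#'   shared center scores of each extracted axis; `"block"`: residualize
#'   each block on its own block score vector \eqn{X_k Q_k u_k}.
#' @return A `"cia_fit"` object; see [tidy.cia_fit()], [glance.cia_fit()].
#'   Element `axes` is a list with per-axis vectors `v`, `b`, loadings
#'   `u`/`a` (lists over blocks) and `pseudo_eigenvalue`.
#' @export
#' @examples
#' set.seed(1)
#' x <- list(a = matrix(rnorm(60), 10), b = matrix(rnorm(80), 10))
#' fit <- fit_mcia(cia_design(x), n_axes = 2)
#' glance(fit)
fit_mcia <- function(design, n_axes = 1,
                     deflation = c("center", "block")) {
  stopifnot(inherits(design, "cia_design"))
  deflation <- match.arg(deflation)
  if (n_axes > min(design$n, sum(design$p))) {
    stop("`n_axes` cannot exceed min(n, sum(p)) = ",
         min(design$n, sum(design$p)))
  }
  work <- design
  axes <- vector("list", n_axes)
  for (r in seq_len(n_axes)) {
    axes[[r]] <- mcia_axis(work)
    if (r < n_axes) work <- deflate_design(work, axes[[r]], deflation)
  }
  new_cia_fit(axes, design, method = "mcia")
}

# One mCIA axis on the (possibly deflated) design: eigen of sum_k Xt Xt^T.
mcia_axis <- function(design) {
  Xt_all <- do.call(cbind, design$xt)
  if (all(Xt_all == 0)) stop("all-zero data: no leading co-inertia direction")
  M <- tcrossprod(Xt_all)
  eg <- eigen(M, symmetric = TRUE)
  b <- eg$vectors[, 1]
  b <- fix_sign(b)
  finish_axis(b, design, lambda = eg$values[1])
}

# Back-transform b into (v, u_k, a_k); a_k = normalized Xt^T b.  The
# objective value is recomputed from the returned vectors unless `lambda`
# is supplied.
finish_axis <- function(b, design, a_list = NULL, lambda = NULL) {
  v <- b / sqrt(design$d)
  if (is.null(a_list)) {
    a_list <- lapply(design$xt, function(Xt) {
      g <- drop(crossprod(Xt, b))
      nrm <- sqrt(sum(g^2))
      if (nrm > 0) g / nrm else g
    })
  }
  a_list <- lapply(seq_along(a_list), function(k) {
    stats::setNames(as.numeric(a_list[[k]]), design$feature_ids[[k]])
  })
  u_list <- lapply(seq_along(a_list), function(k) a_list[[k]] / sqrt(design$q[[k]]))
  names(a_list) <- names(u_list) <- names(design$blocks)
  cov_k <- vapply(seq_along(a_list), function(k) {
    drop(crossprod(b, design$xt[[k]] %*% a_list[[k]]))
  }, numeric(1))
  if (is.null(lambda)) lambda <- sum(cov_k^2)
  list(v = v, b = b, u = u_list, a = a_list,
       block_covariances = cov_k,
       pseudo_eigenvalue = lambda)
}

# Deterministic sign: the largest-magnitude entry is made positive.
fix_sign <- function(x) {
  i <- which.max(abs(x))
  if (x[i] < 0) -x else x
}

#' Deflate a data matrix on axis scores
#'
#' Replaces `X` by the residuals of a D-weighted regression of each column
#' on the score vector `scores`: \eqn{X - t (t^\top D X) / (t^\top D t)}.
#' Any axis extracted from the residuals has scores D-orthogonal to
#' `scores`; deflating twice on the same scores is a no-op.
#'
#' @param X Numeric matrix, n rows.
#' @param scores Numeric score vector of length n, not all zero.
#' @param d Positive sample weights (diagonal of D); default all ones.
#' @return The residual matrix, same dimensions as `X`.
#' @export
deflate <- function(X, scores, d = rep(1, nrow(X))) {
  X <- as.matrix(X)
  scores <- as.numeric(scores)
  if (length(scores) != nrow(X)) stop("`scores` must have length nrow(X)")
  denom <- sum(d * scores^2)
  if (denom == 0) stop("`scores` must not be the zero vector")
  X - scores %*% crossprod(d * scores, X) / denom
}

# Deflate every block of a design on an extracted axis.
deflate_design <- function(design, axis, deflation = "center") {
  new_blocks <- lapply(seq_along(design$blocks), function(k) {
    t_k <- if (deflation == "center") {
      axis$v
    } else {
      drop(design$blocks[[k]] %*% (design$q[[k]] * axis$u[[k]]))
    }
    deflate(design$blocks[[k]], t_k, design$d)
  })
  replace_blocks(design, new_blocks)
}

#' Pseudo-eigenvalues and percent variability explained
#'
#' Evaluates each fitted axis's co-inertia objective
#' \eqn{\sum_k w_k (v^\top D X_k Q_k u_k)^2} on an arbitrary design (the
#' training data, a held-out test set, or the whole data), together with
#' its share of the total: the ratio of the pseudo-eigenvalue to the sum
#' of all eigenvalues of the design's co-inertia operator (the squared
#' Frobenius norm of the merged transformed table).
#'
#' @param fit A `"cia_fit"`.
#' @param design A [cia_design()] dimensionally compatible with `fit`.
#' @return A tibble with columns `axis`, `pseudo_eigenvalue`,
#'   `pct_explained` and their cumulative versions.
#' @export
pseudo_eigenvalues <- function(fit, design) {
  stopifnot(inherits(fit, "cia_fit"), inherits(design, "cia_design"))
  if (!identical(unname(vapply(fit$axes[[1]]$u, length, integer(1))),
                 unname(design$p)) ||
      length(fit$axes[[1]]$v) != design$n) {
    stop("`fit` and `design` have incompatible dimensions")
  }
  total <- sum(vapply(design$xt, function(m) sum(m^2), numeric(1)))
  vals <- vapply(fit$axes, function(ax) {
    sum(vapply(seq_along(ax$u), function(k) {
      cv <- drop(crossprod(design$d * ax$v,
                           design$blocks[[k]] %*% (design$q[[k]] * ax$u[[k]])))
      design$w[k] * cv^2
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(
    axis = seq_along(vals),
    pseudo_eigenvalue = vals,
    pct_explained = vals / total,
    cum_pseudo_eigenvalue = cumsum(vals),
    cum_pct_explained = cumsum(vals) / total
  )
}

new_cia_fit <- function(axes, design, method, traces = NULL,
                        config = NULL) {
  structure(
    list(axes = axes,
         method = method,
         n = design$n, p = design$p,
         block_names = names(design$blocks),
         feature_ids = design$feature_ids,
         sample_ids = design$sample_ids,
         traces = traces,
         config = config),
    class = "cia_fit")
}

#' @export
print.cia_fit <- function(x, ...) {
  cat("<cia_fit> method = ", x$method, ", ", length(x$axes), " axis/axes, K = ",
      length(x$p), " blocks\n", sep = "")
  for (r in seq_along(x$axes)) {
    nz <- vapply(x$axes[[r]]$a, function(a) sum(a != 0), integer(1))
    cat(sprintf("  axis %d: pseudo-eigenvalue %.4g, nonzeros (%s)\n",
                r, x$axes[[r]]$pseudo_eigenvalue, paste(nz, collapse = ", ")))
  }
  invisible(x)
}
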