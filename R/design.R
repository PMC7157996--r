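#' Column-wise centering and unit-variance scaling
#'
#' Centers every column of `X` to mean zero and scales every column to unit
#' sample standard deviation (denominator `n - 1`).  Constant columns cannot
#' be standardized and raise an error naming the offending feature; filter
#' them out (e.g. with [variance_filter()]) before calling.
#'
#' @param X Numeric matrix, samples in rows, features in columns.  Column
#'   names, if present, are used in error messages and preserved.
#' @return A matrix of the same dimensions with standardized columns.
#' @export
#' @examples
#' center_standardize(cbind(a = c(1, 2, 3), b = c(2, 0, 1)))
center_standardize <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric")
  if (nrow(X) < 2) stop("standardization needs at least 2 samples")
  if (anyNA(X)) stop("`X` contains missing values; complete matrices are required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(X))) colnames(X)[bad] else as.character(bad)
    stop("constant feature(s) cannot be standardized: ",
         paste(utils::head(nm, 5), collapse = ", "))
  }
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Default feature weights from absolute column sums
#'
#' The default diagonal feature metric \eqn{Q_k}: each feature's weight is
#' its absolute column sum divided by the total absolute sum of the matrix,
#' so features with higher overall variability receive higher weight.  The
#' weights are proportions and sum to one.
#'
#' @param X Numeric matrix (typically already standardized).
#' @return Positive numeric vector of length `ncol(X)` summing to 1, named
#'   after the columns of `X`.
#' @export
#' @examples
#' feature_weights(matrix(c(1, 1, -1, 1), 2))
feature_weights <- function(X) {
  X <- as.matrix(X)
  colsums <- colSums(abs(X))
  if (any(colsums == 0)) {
    bad <- which(colsums == 0)
    nm <- if (!is.null(colnames(X))) colnames(X)[bad] else as.character(bad)
    stop("all-zero feature(s) would get weight 0 (Q must be invertible): ",
         paste(utils::head(nm, 5), collapse = ", "))
  }
  q <- colsums / sum(colsums)
  names(q) <- colnames(X)
  q
}

#' Keep the most variable features
#'
#' Returns the column indices of the `ceiling(top_fraction * p)` features
#' with the largest sample variance.  Ties at the cutoff are broken in
#' favour of the lower column index.  A common pre-filter for omics
#' matrices (e.g. retaining the top 5% most variable genes).
#'
#' @param X Numeric matrix, samples in rows.
#' @param top_fraction Fraction of columns to keep, in (0, 1].
#' @return Integer vector of retained column indices, in increasing order.
#' @export
variance_filter <- function(X, top_fraction) {
  X <- as.matrix(X)
  if (ncol(X) == 0 || nrow(X) == 0) stop("`X` is empty")
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("`top_fraction` must be in (0, 1]")
  }
  n_keep <- ceiling(top_fraction * ncol(X))
  vars <- apply(X, 2, stats::var)
  keep <- order(-vars, seq_along(vars))[seq_len(n_keep)]
  sort(keep)
}

#' Assemble a multi-block co-inertia design
#'
#' Bundles K sample-matched omics matrices with their weight metrics into
#' the design object all fitting functions operate on.  Each block k is a
#' data triplet (X_k, Q_k, w_k) sharing one diagonal sample metric D: X_k
#' is n samples by p_k features, Q_k a positive diagonal feature metric,
#' w_k a positive dataset weight with sum(w) = 1.  Internally the blocks
#' are stored together with their transformed versions
#' \deqn{\tilde X_k = \sqrt{w_k}\, D^{1/2} X_k Q_k^{1/2},}
#' the Euclidean-metric representation in which every solver works.
#'
#' @param x Named list of K numeric matrices with identical row (sample)
#'   count and order.  Data frames are coerced.
#' @param center Logical; column-wise center and standardize each block
#'   first (default `TRUE`).  Set to `FALSE` if the matrices are already
#'   standardized.
#' @param q Feature metrics: `"colsum"` (default; absolute-column-sum
#'   proportions via [feature_weights()], computed after standardization),
#'   `"identity"`, or a list of K positive vectors.
#' @param d Sample metric: `"identity"` (default), `"uniform"` (all 1/n),
#'   or a positive vector of length n.
#' @param w Dataset weights: `NULL` for equal weights 1/K, or a positive
#'   vector of length K (renormalized to sum to 1).
#' @return An object of class `"cia_design"`: a list with elements
#'   `blocks` (list of standardized matrices), `q`, `d`, `w`, `xt`
#'   (transformed blocks), `feature_ids`, `sample_ids`, `n`, `p`.
#' @export
#' @examples
#' set.seed(1)
#' x <- list(rna = matrix(rnorm(40), 8), prot = matrix(rnorm(24), 8))
#' des <- cia_design(x)
#' des
cia_design <- function(x, center = TRUE, q = "colsum", d = "identity",
                       w = NULL) {
  if (!is.list(x) || length(x) == 0) stop("`x` must be a non-empty list of matrices")
  K <- length(x)
  x <- lapply(x, as.matrix)
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0("block", seq_len(K))
  }
  n <- unique(vapply(x, nrow, integer(1)))
  if (length(n) != 1) stop("all blocks must have the same number of samples")
  if (n < 2) stop("need at least 2 samples")

  sample_ids <- rownames(x[[1]])
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  for (k in seq_len(K)) {
    if (!is.null(rownames(x[[k]])) &&
        !identical(rownames(x[[k]]), rownames(x[[1]]))) {
      stop("sample ids of block '", names(x)[k], "' do not match block 1 ",
           "(samples must be co-ordered across blocks)")
    }
    if (is.null(colnames(x[[k]]))) {
      colnames(x[[k]]) <- paste0(names(x)[k], "_f", seq_len(ncol(x[[k]])))
    }
    if (anyDuplicated(colnames(x[[k]]))) {
      stop("duplicate feature ids in block '", names(x)[k], "'")
    }
  }

  if (center) x <- lapply(x, center_standardize)

  # feature metrics Q_k (computed after standardization, see vignette)
  if (is.character(q)) {
    q <- match.arg(q, c("colsum", "identity"))
    q <- switch(q,
      colsum = lapply(x, feature_weights),
      identity = lapply(x, function(m) stats::setNames(rep(1, ncol(m)), colnames(m)))
    )
  } else {
    if (!is.list(q) || length(q) != K) stop("`q` must be a list of K vectors")
    q <- lapply(seq_len(K), function(k) {
      qk <- as.numeric(q[[k]])
      if (length(qk) != ncol(x[[k]])) stop("q[[", k, "]] has wrong length")
      if (any(qk <= 0)) stop("feature weights must be strictly positive")
      stats::setNames(qk, colnames(x[[k]]))
    })
  }
  names(q) <- names(x)

  if (is.character(d)) {
    d <- match.arg(d, c("identity", "uniform"))
    d <- switch(d, identity = rep(1, n), uniform = rep(1 / n, n))
  } else {
    d <- as.numeric(d)
    if (length(d) != n) stop("`d` must have length n")
    if (any(d <= 0)) stop("sample weights must be strictly positive")
  }

  if (is.null(w)) {
    w <- rep(1 / K, K)
  } else {
    w <- as.numeric(w)
    if (length(w) != K) stop("`w` must have length K")
    if (any(w <= 0)) stop("dataset weights must be strictly positive")
    w <- w / sum(w)
  }
  names(w) <- names(x)

  design <- structure(
    list(blocks = x, q = q, d = d, w = w,
         feature_ids = lapply(x, colnames),
         sample_ids = sample_ids,
         n = n, p = vapply(x, ncol, integer(1))),
    class = "cia_design")
  design$xt <- transform_blocks(design)
  design
}

#' Transformed working tables of a design
#'
#' Computes \eqn{\tilde X_k = \sqrt{w_k} D^{1/2} X_k Q_k^{1/2}} for every
#' block: row i is scaled by `sqrt(d[i])`, column j by `sqrt(q[j])`, the
#' whole block by `sqrt(w_k)`.  With identity weights and K = 1 this is
#' `X` itself.
#'
#' @param design A [cia_design()] object.
#' @return List of K numeric matrices, same dimensions as the blocks.
#' @export
transform_blocks <- function(design) {
  stopifnot(inherits(design, "cia_design"))
  rd <- sqrt(design$d)
  lapply(seq_along(design$blocks), function(k) {
    Xt <- sqrt(design$w[k]) * (rd * design$blocks[[k]]) *
      rep(sqrt(design$q[[k]]), each = design$n)
    dimnames(Xt) <- dimnames(design$blocks[[k]])
    Xt
  })
}

#' @export
print.cia_design <- function(x, ...) {
  cat("<cia_design> ", length(x$blocks), " block(s), ", x$n, " samples\n", sep = "")
  for (k in seq_along(x$blocks)) {
    cat(sprintf("  %-12s %5d features  w = %.3f\n",
                names(x$blocks)[k], x$p[k], x$w[k]))
  }
  invisible(x)
}

# Replace the data matrices of a design (same dims/ids), recomputing the
# transformed tables but keeping Q, D, w fixed.  Used by deflation.
replace_blocks <- function(design, new_blocks) {
  stopifnot(length(new_blocks) == length(design$blocks))
  for (k in seq_along(new_blocks)) {
    dimnames(new_blocks[[k]]) <- dimnames(design$blocks[[k]])
  }
  design$blocks <- new_blocks
  design$xt <- transform_blocks(design)
  design
}
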