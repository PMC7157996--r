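#' Deterministic k-fold sample partition
#'
#' Splits samples 1..n into `n_folds` disjoint folds of sizes differing by
#' at most one.  The same partition is applied to every block (samples are
#' matched across blocks).  Deterministic given `seed`.
#'
#' @param n Number of samples.
#' @param n_folds Number of folds, `2 <= n_folds <= n`.
#' @param seed Integer seed.
#' @return List of `n_folds` integer index vectors (disjoint, covering 1..n).
#' @export
kfold_split <- function(n, n_folds, seed = 1) {
  if (n_folds < 2 || n_folds > n) stop("`n_folds` must be in [2, n]")
  withr::with_seed(seed, {
    assignment <- rep(seq_len(n_folds), length.out = n)[sample.int(n)]
  })
  lapply(seq_len(n_folds), function(t) which(assignment == t))
}

#' Held-out co-inertia values of trained loadings
#'
#' Given loadings `a_list` trained without the test fold, computes the
#' per-block squared co-inertia on the test fold.  The printed CV formula
#' pairs a training-length center with test-fold rows; this implementation
#' recomputes the center on the test fold by a single [update_center()]
#' step with the trained loadings held fixed, keeping the loadings
#' strictly out-of-sample: \eqn{cv_k = ((\hat b^t)^\top \tilde X^t_k \hat
#' a_k)^2}.
#'
#' @param a_list Trained loading vectors (unit norm).
#' @param xt_test List of test-fold rows of the transformed blocks.
#' @return Numeric vector of K nonnegative values.
#' @export
cv_value <- function(a_list, xt_test) {
  if (nrow(xt_test[[1]]) < 2) stop("test fold must contain at least 2 samples")
  G <- vapply(seq_along(xt_test), function(k) drop(xt_test[[k]] %*% a_list[[k]]),
              numeric(nrow(xt_test[[1]])))
  G <- matrix(G, nrow = nrow(xt_test[[1]]))
  if (all(G == 0)) return(rep(0, length(xt_test)))
  b_test <- svd(G, nu = 1, nv = 0)$u[, 1]
  drop(crossprod(b_test, G))^2
}

#' Scaled cross-validation score
#'
#' Aggregates the T-by-K table of held-out co-inertia values into
#' `mean / sd` (sd with denominator `T*K - 1`).  Co-inertia values are
#' unbounded, unlike correlations, so the mean alone is not comparable
#' across tuning settings; standardizing by the spread favours
#' combinations that are both large and stable across folds.  Larger is
#' better.  If all values are identical the score is `+Inf` (with a
#' warning): a perfectly stable combination.
#'
#' @param cv_values Numeric vector or matrix of held-out values
#'   (at least 2).
#' @return Scalar score.
#' @export
cv_score <- function(cv_values) {
  v <- as.numeric(cv_values)
  if (length(v) < 2) stop("need at least 2 cross-validation values")
  s <- stats::sd(v)
  if (s == 0) {
    warning("all cross-validation values identical; score is +Inf")
    return(Inf)
  }
  mean(v) / s
}

#' Cross-validated tuning of sparse mCIA parameters
#'
#' Exhaustive grid search over sparsity budgets, network penalty weights
#' and Rifle step sizes, scored by [cv_score()] over a T-fold partition
#' shared by every combination (paired comparison).  For each fold and
#' combination one sparse axis is fitted on the training rows (mCIA warm
#' start) and evaluated on the held-out rows via [cv_value()].  Ties are
#' broken toward the sparser model (smaller total `s`), then smaller
#' total `lambda`, then smaller `eta`.
#'
#' Per-block grids are crossed (Cartesian product), which grows quickly
#' with K; `shared = TRUE` instead uses one sparsity fraction of each
#' p_k and one lambda for all blocks, the cheaper strategy for many
#' blocks.
#'
#' @param design A [cia_design()].
#' @param s_grid With `shared = FALSE`: list of K integer vectors of
#'   candidate budgets (a single vector is reused for every block); with
#'   `shared = TRUE`: numeric vector of fractions in (0, 1], each giving
#'   `s_k = max(1, round(frac * p_k))`.
#' @param lambda_grid List of K numeric vectors (or single vector reused;
#'   scalar vector with `shared = TRUE`); use `0` for plain sparse mCIA.
#' @param eta_grid Candidate step sizes in (0, 1], shared across blocks.
#' @param n_folds Fold count T (default 5).
#' @param seed Seed for the fold partition.
#' @param graphs,laplacian_variant Passed to the fitting routine when any
#'   lambda is positive.
#' @param shared Use the shared-parameter grid (see above).
#' @param ... Further arguments to the axis fitter (`outer_max_iter`,
#'   `outer_tol`, `rifle_max_iter`, `rifle_tol`).
#' @return A `"cia_cv"`: list with `table` (one row per combination:
#'   parameters, score, per-fold values), `best` (list `s`, `lambda`,
#'   `eta`), and `folds`.
#' @export
tune_smcia <- function(design, s_grid, lambda_grid = 0, eta_grid = 0.5,
                       n_folds = 5, seed = 1, graphs = NULL,
                       laplacian_variant = c("normalized", "combinatorial"),
                       shared = FALSE, ...) {
  stopifnot(inherits(design, "cia_design"))
  laplacian_variant <- match.arg(laplacian_variant)
  K <- length(design$blocks)
  dots <- list(...)
  ctrl <- list(outer_max_iter = dots$outer_max_iter %||% 100,
               outer_tol = dots$outer_tol %||% 1e-5,
               rifle_max_iter = dots$rifle_max_iter %||% 1000,
               rifle_tol = dots$rifle_tol %||% 1e-6)

  # candidate table: one row per combination, K columns each for s, lambda
  if (shared) {
    stopifnot(is.numeric(s_grid), all(s_grid > 0 & s_grid <= 1))
    lam <- if (is.list(lambda_grid)) unique(unlist(lambda_grid)) else lambda_grid
    combos <- expand.grid(frac = s_grid, lambda = lam, eta = eta_grid,
                          KEEP.OUT.ATTRS = FALSE)
    s_mat <- t(vapply(combos$frac,
                      function(f) pmax(1L, as.integer(round(f * design$p))),
                      integer(K)))
    lam_mat <- matrix(combos$lambda, nrow(combos), K)
  } else {
    if (!is.list(s_grid)) s_grid <- rep(list(s_grid), K)
    if (!is.list(lambda_grid)) lambda_grid <- rep(list(lambda_grid), K)
    stopifnot(length(s_grid) == K, length(lambda_grid) == K)
    grids <- c(stats::setNames(s_grid, paste0("s", seq_len(K))),
               stats::setNames(lambda_grid, paste0("lambda", seq_len(K))),
               list(eta = eta_grid))
    combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    s_mat <- as.matrix(combos[paste0("s", seq_len(K))])
    lam_mat <- as.matrix(combos[paste0("lambda", seq_len(K))])
  }
  if (any(lam_mat > 0) && is.null(graphs)) {
    stop("`graphs` is required when the lambda grid contains positive values")
  }

  # Laplacians and their spectral radii once per block
  lt_list <- vector("list", K)
  lt_lam_max <- numeric(K)
  for (k in seq_len(K)) {
    if (any(lam_mat[, k] > 0)) {
      L <- if (inherits(graphs[[k]], "feature_graph")) {
        build_laplacian(graphs[[k]], laplacian_variant)
      } else {
        as.matrix(graphs[[k]])
      }
      Lt <- transform_laplacian(L, design$q[[k]])
      lt_list[[k]] <- Matrix::Matrix(Lt, sparse = TRUE)
      lt_lam_max[k] <- gershgorin_max(Lt)
    }
  }

  folds <- kfold_split(design$n, n_folds, seed)
  xt <- design$xt
  # per-fold training designs and warm starts, shared by all combinations
  train_designs <- lapply(folds, function(te) subset_rows(design, setdiff(seq_len(design$n), te)))
  warm <- lapply(train_designs, mcia_axis)

  n_combo <- nrow(combos)
  scores <- numeric(n_combo)
  cv_tables <- vector("list", n_combo)
  for (i in seq_len(n_combo)) {
    s_i <- as.integer(s_mat[i, ])
    lam_i <- as.numeric(lam_mat[i, ])
    eta_i <- rep_len(combos$eta[i], K)
    shifts <- ifelse(lam_i > 0, lam_i * lt_lam_max + 1e-8, 0)
    lt_i <- lapply(seq_len(K), function(k) if (lam_i[k] > 0) lt_list[[k]] else NULL)
    cv_mat <- matrix(NA_real_, n_folds, K)
    for (t in seq_len(n_folds)) {
      res <- suppressWarnings(
        fit_sparse_axis(train_designs[[t]], s_i, lam_i, eta_i, lt_i, shifts,
                        ctrl$outer_max_iter, ctrl$outer_tol,
                        ctrl$rifle_max_iter, ctrl$rifle_tol, warm[[t]]))
      xt_test <- lapply(xt, function(m) m[folds[[t]], , drop = FALSE])
      cv_mat[t, ] <- cv_value(res$axis$a, xt_test)
    }
    scores[i] <- suppressWarnings(cv_score(cv_mat))
    cv_tables[[i]] <- cv_mat
  }

  # argmax with deterministic tie-breaking: score desc, total s asc,
  # total lambda asc, eta asc
  ord <- order(-scores, rowSums(s_mat), rowSums(lam_mat), combos$eta)
  best_i <- ord[1]

  table <- tibble::as_tibble(combos)
  table$score <- scores
  table$cv_values <- cv_tables
  structure(
    list(table = table,
         best = list(s = as.integer(s_mat[best_i, ]),
                     lambda = as.numeric(lam_mat[best_i, ]),
                     eta = combos$eta[best_i]),
         best_index = best_i,
         folds = folds,
         interpretation = c(cv_center = "recomputed on test fold",
                            cv_scale = "mean/sd over all T*K values")),
    class = "cia_cv")
}

#' @export
print.cia_cv <- function(x, ...) {
  cat("<cia_cv> ", nrow(x$table), " combinations, ", length(x$folds),
      " folds\n  best: s = (", paste(x$best$s, collapse = ", "),
      "), lambda = (", paste(x$best$lambda, collapse = ", "),
      "), eta = ", x$best$eta, "\n", sep = "")
  invisible(x)
}

# Row subset of a design (standardization and weights stay as computed on
# the full data; transformed tables are row subsets because D is diagonal).
subset_rows <- function(design, rows) {
  design$blocks <- lapply(design$blocks, function(m) m[rows, , drop = FALSE])
  design$xt <- lapply(design$xt, function(m) m[rows, , drop = FALSE])
  design$d <- design$d[rows]
  design$sample_ids <- design$sample_ids[rows]
  design$n <- length(rows)
  design
}

`%||%` <- function(a, b) if (is.null(a)) b else a
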