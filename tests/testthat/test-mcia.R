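test_that("single-block mCIA with identity weights matches the SVD", {
  X <- withr::with_seed(3, matrix(rnorm(8 * 6), 8, 6))
  des <- cia_design(list(b = X), center = FALSE, q = "identity")
  fit <- fit_mcia(des)
  sv <- svd(X)
  ax <- fit$axes[[1]]
  expect_gte(abs(sum(ax$v * sv$u[, 1])), 1 - 1e-8)
  expect_gte(abs(sum(ax$u[[1]] * sv$v[, 1])), 1 - 1e-8)
  expect_equal(ax$pseudo_eigenvalue, sv$d[1]^2, tolerance = 1e-10)
})

test_that("identical blocks with identical weights get identical loadings", {
  X <- withr::with_seed(4, matrix(rnorm(60), 10, 6))
  des <- cia_design(list(a = X, b = X), center = FALSE, q = "identity")
  fit <- fit_mcia(des)
  expect_equal(unname(fit$axes[[1]]$u[[1]]), unname(fit$axes[[1]]$u[[2]]),
               tolerance = 1e-10)
})

test_that("the reported eigenvalue is self-consistent with the returned vectors", {
  des <- random_design(n = 10, p = c(5, 7, 6), seed = 5)
  fit <- fit_mcia(des, n_axes = 2)
  for (ax in fit$axes) {
    recomputed <- sum(vapply(seq_along(ax$u), function(k) {
      cv <- drop(crossprod(des$d * ax$v,
                           des$blocks[[k]] %*% (des$q[[k]] * ax$u[[k]])))
      des$w[k] * cv^2
    }, numeric(1)))
    expect_equal(ax$pseudo_eigenvalue,
                 sum(vapply(seq_along(ax$a), function(k)
                   drop(crossprod(ax$b, des$xt[[k]] %*% ax$a[[k]]))^2,
                   numeric(1))),
                 tolerance = 1e-8)
    # only axis 1 is evaluated on the undeflated data
    if (identical(ax, fit$axes[[1]])) {
      expect_equal(ax$pseudo_eigenvalue, recomputed, tolerance = 1e-8)
    }
    expect_equal(sum(des$d * ax$v^2), 1, tolerance = 1e-8)
    for (k in seq_along(ax$u)) {
      expect_equal(sum(des$q[[k]] * ax$u[[k]]^2), 1, tolerance = 1e-8)
      expect_unit_norm(ax$a[[k]])
    }
    expect_unit_norm(ax$b)
  }
})

test_that("transformed- and original-metric formulations agree", {
  des <- random_design(n = 9, p = c(5, 6), seed = 6, d = "uniform")
  fit <- fit_mcia(des)
  # original parameterization: leading eigenvalue of sum_k w_k X_k Q_k X_k' D
  M <- Reduce(`+`, lapply(seq_along(des$blocks), function(k) {
    des$w[k] * des$blocks[[k]] %*% (des$q[[k]] * t(des$blocks[[k]]))
  }))
  lam <- eigen(M %*% diag(des$d))$values[1]
  expect_equal(fit$axes[[1]]$pseudo_eigenvalue, Re(lam), tolerance = 1e-8)
})

test_that("axis 1 beats random unit-norm directions", {
  des <- random_design(n = 8, p = c(5, 6), seed = 7)
  fit <- fit_mcia(des)
  best <- fit$axes[[1]]$pseudo_eigenvalue
  objective <- function(v, u) {
    sum(vapply(seq_along(u), function(k) {
      cv <- drop(crossprod(des$d * v, des$blocks[[k]] %*% (des$q[[k]] * u[[k]])))
      des$w[k] * cv^2
    }, numeric(1)))
  }
  withr::with_seed(8, {
    for (i in 1:100) {
      v <- rnorm(des$n); v <- v / sqrt(sum(des$d * v^2))
      u <- lapply(des$q, function(qk) {
        uu <- rnorm(length(qk)); uu / sqrt(sum(qk * uu^2))
      })
      expect_lte(objective(v, u), best + 1e-10)
    }
  })
})

test_that("deflation residuals are D-orthogonal to the scores and idempotent", {
  withr::with_seed(9, {
    X <- matrix(rnorm(40), 8, 5)
    t_scores <- rnorm(8)
    d <- runif(8, 0.5, 2)
  })
  Xr <- deflate(X, t_scores, d)
  expect_lt(max(abs(crossprod(d * t_scores, Xr))), 1e-10)
  expect_equal(deflate(Xr, t_scores, d), Xr, tolerance = 1e-12)
  expect_error(deflate(X, rep(0, 8)), "zero")
})

test_that("deflating on an in-span score vector drops the rank by one", {
  withr::with_seed(10, {
    X <- matrix(rnorm(7 * 4), 7, 4)
    t_scores <- drop(X %*% rnorm(4))
  })
  expect_equal(qr(deflate(X, t_scores))$rank, qr(X)$rank - 1)
})

test_that("successive axes have D-orthogonal centers", {
  des <- random_design(n = 10, p = c(6, 7), seed = 11, d = "uniform")
  fit <- fit_mcia(des, n_axes = 3)
  for (r in 2:3) {
    for (rp in seq_len(r - 1)) {
      expect_lt(abs(sum(des$d * fit$axes[[r]]$v * fit$axes[[rp]]$v)), 1e-8)
    }
  }
})

test_that("pseudo_eigenvalues reproduces training eigenvalues and sums to one", {
  # uncentered data keep the sample-space rank at n, so all min(n, sum p)
  # axes are genuine
  des <- random_design(n = 6, p = c(4, 5), seed = 12, center = FALSE)
  r_max <- min(des$n, sum(des$p))
  fit <- fit_mcia(des, n_axes = r_max)
  pe <- pseudo_eigenvalues(fit, des)
  expect_equal(pe$pseudo_eigenvalue[1], fit$axes[[1]]$pseudo_eigenvalue,
               tolerance = 1e-8)
  # every exact axis of a design whose rank is min(n, p) together explains
  # all co-inertia
  expect_equal(pe$cum_pct_explained[r_max], 1, tolerance = 1e-6)
  expect_error(pseudo_eigenvalues(fit, random_design(n = 6, p = c(3, 5))),
               "incompatible")
})

test_that("all-zero loadings give a zero pseudo-eigenvalue", {
  des <- random_design(n = 6, p = c(4, 5), seed = 13)
  fit <- fit_mcia(des)
  fit$axes[[1]]$u <- lapply(fit$axes[[1]]$u, function(u) u * 0)
  expect_equal(pseudo_eigenvalues(fit, des)$pseudo_eigenvalue[1], 0)
})

test_that("fit_mcia rejects impossible requests", {
  des <- random_design(n = 6, p = c(4, 5), seed = 14)
  expect_error(fit_mcia(des, n_axes = 7), "n_axes")
  zero <- cia_design(list(z = matrix(0, 4, 3)), center = FALSE,
                     q = list(rep(1, 3)))
  expect_error(fit_mcia(zero), "zero")
})

test_that("tidiers expose loadings, scores and axis summaries", {
  des <- random_design(n = 8, p = c(4, 6), seed = 15)
  fit <- fit_mcia(des, n_axes = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * (4 + 6))
  expect_setequal(unique(td$block), c("blk1", "blk2"))
  gl <- glance(fit)
  expect_equal(gl$axis, 1:2)
  expect_true(all(c("nnz_blk1", "nnz_blk2") %in% names(gl)))
  sc <- sample_scores(fit)
  expect_equal(nrow(sc), 16)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
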