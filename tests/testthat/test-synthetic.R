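test_that("the scenario grid maps ids to design parameters", {
  c1 <- scenario_config(1)
  expect_equal(c(c1$sigma2, c1$n_el), c(1.2, 10))
  expect_equal(c1$n_en, c(3, 4, 5))
  c8 <- scenario_config(8)
  expect_equal(c(c8$sigma2, c8$n_el), c(2.5, 20))
  expect_equal(c8$n_en, c(5, 5, 5))
  expect_error(scenario_config(NULL, p = c(30, 40), n_el = 10),
               "must fit")
})

test_that("true loadings are the normalized network indicators", {
  tr1 <- true_loadings(scenario_config(1))
  expect_length(tr1[[1]], 300)
  expect_equal(sum(tr1[[1]] != 0), 30)
  expect_equal(unique(tr1[[1]][1:30]), 1 / sqrt(30))

  tr8 <- true_loadings(scenario_config(8))
  expect_length(tr8[[3]], 500)
  expect_equal(sum(tr8[[3]] != 0), 100)
  expect_equal(unique(tr8[[3]][1:100]), 0.1)

  for (sc in 1:8) {
    for (a in true_loadings(scenario_config(sc))) expect_unit_norm(a)
  }
})

test_that("the spiked covariance has the prescribed eigenstructure", {
  a <- withr::with_seed(51, rnorm(12))
  a <- a / sqrt(sum(a^2))
  S <- build_sigma_block(a, gamma_extra = 1.5)
  eg <- eigen(S, symmetric = TRUE)
  expect_equal(eg$values, c(2.5, rep(1, 11)), tolerance = 1e-10)
  expect_gte(abs(sum(eg$vectors[, 1] * a)), 1 - 1e-10)
  expect_equal(sum(diag(S)), 12 + 1.5)
  expect_error(build_sigma_block(a * 2), "unit norm")
})

test_that("sampling is seed-deterministic and decouples when sigma2 is zero", {
  cfg <- tiny_config()
  expect_identical(sample_dataset(cfg, seed = 3), sample_dataset(cfg, seed = 3))
  expect_false(identical(sample_dataset(cfg, seed = 3),
                         sample_dataset(cfg, seed = 4)))

  cfg0 <- tiny_config(sigma2 = 1e-12, n = 4000, p = c(6, 5), n_el = 1,
                      n_en = c(1, 1), n_networks = 2)
  x0 <- sample_dataset(cfg0, seed = 5)
  cross <- crossprod(x0[[1]], x0[[2]]) / (cfg0$n - 1)
  # entrywise 3-standard-error bound; spiked coordinates have variance 2
  expect_lt(max(abs(cross)), 3 * 2 / sqrt(cfg0$n))
})

test_that("empirical covariances match the latent-model blocks", {
  # small-p, large-n check of the implied joint covariance, against the
  # closed-form diagonal and off-diagonal blocks
  cfg <- tiny_config(sigma2 = 2, n = 50000, p = c(8, 6), n_el = 2,
                     n_en = c(2, 2), n_networks = 3)
  tr <- true_loadings(cfg)
  x <- sample_dataset(cfg, seed = 6)
  n <- cfg$n
  # entrywise Monte-Carlo standard error bound for covariances of
  # variables with variance <= v_max
  v_max <- 1 + cfg$sigma2 + cfg$gamma_extra
  tol <- 3 * v_max / sqrt(n)

  emp_12 <- crossprod(x[[1]], x[[2]]) / (n - 1)
  theo_12 <- cfg$sigma2 * tcrossprod(tr[[1]], tr[[2]])
  expect_lt(max(abs(emp_12 - theo_12)), tol)

  for (k in 1:2) {
    emp <- crossprod(x[[k]]) / (n - 1)
    theo <- cfg$sigma2 * tcrossprod(tr[[k]]) +
      build_sigma_block(tr[[k]], cfg$gamma_extra)
    expect_lt(max(abs(emp - theo)), tol)
  }
})

test_that("the population matrix has the true loading as leading eigenvector", {
  cfg <- tiny_config()
  tr <- true_loadings(cfg)
  for (k in 1:2) {
    M <- cfg$sigma2 * tcrossprod(tr[[k]]) +
      build_sigma_block(tr[[k]], cfg$gamma_extra)
    eg <- eigen(M, symmetric = TRUE)
    expect_gte(abs(sum(eg$vectors[, 1] * tr[[k]])), 1 - 1e-10)
    expect_equal(eg$values[1], cfg$sigma2 + 1 + cfg$gamma_extra,
                 tolerance = 1e-10)
  }
})

test_that("scenario graphs are stars with penalty-free truths", {
  cfg <- scenario_config(1)
  gs <- scenario_graphs(cfg)
  tr <- true_loadings(cfg)
  for (k in 1:3) {
    expect_equal(nrow(gs[[k]]$edges), 5 * 9)   # 5 stars, 9 edges each
    hubs <- sort(unique(gs[[k]]$edges$from))
    expect_equal(hubs, seq(1, 41, by = 10))
    Lc <- build_laplacian(gs[[k]], "combinatorial")
    expect_equal(penalty_value(tr[[k]], Lc), 0, tolerance = 1e-12)
  }
})

test_that("every scenario truth is penalty-free on its own graph", {
  for (sc in 1:8) {
    cfg <- scenario_config(sc)
    gs <- scenario_graphs(cfg)
    tr <- true_loadings(cfg)
    for (k in 1:3) {
      Lc <- build_laplacian(gs[[k]], "combinatorial")
      expect_equal(penalty_value(tr[[k]], Lc), 0, tolerance = 1e-12)
    }
  }
})

test_that("run_scenario summarizes replicates per method and block", {
  cfg <- tiny_config()
  out <- run_scenario(cfg, methods = c("mcia", "smcia"), n_mc = 3, seed = 31)
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 2 * 2)       # 2 methods x 2 blocks
  expect_true(all(is.na(out$sens[out$method == "mcia"])))
  expect_true(all(!is.na(out$angle)))
  expect_identical(out, run_scenario(cfg, methods = c("mcia", "smcia"),
                                     n_mc = 3, seed = 31))

  out1 <- run_scenario(cfg, methods = "mcia", n_mc = 1, seed = 32)
  expect_true(all(is.na(out1$angle_se)))
})

test_that("mCIA loading recovery is consistent as n grows", {
  # same block dimensions, increasing sample size: the mean angle to the
  # truth must rise well toward 1
  p <- c(60, 80, 100)
  mean_angle <- function(n) {
    cfg <- scenario_config(NULL, n = n, p = p, sigma2 = 1.2, n_el = 10,
                           n_en = c(3, 4, 5))
    tr <- true_loadings(cfg)
    mean(vapply(1:3, function(seed) {
      fit <- fit_mcia(cia_design(sample_dataset(cfg, seed = seed)))
      mean(vapply(1:3, function(k)
        loading_angle(fit$axes[[1]]$a[[k]], tr[[k]]), numeric(1)))
    }, numeric(1)))
  }
  small <- mean_angle(150)
  big <- mean_angle(1500)
  expect_gt(big, small)
  expect_gt(big, 0.95)
})

test_that("sparse recovery is strong at high latent variance", {
  # oracle-budget smCIA on a strong-signal configuration; a scaled-down
  # analogue of the full benchmark regime
  cfg <- tiny_config(sigma2 = 2.5, n = 60, p = c(30, 36), n_el = 5,
                     n_en = c(2, 3), n_networks = 3)
  tr <- true_loadings(cfg)
  angles <- replicate(10, NA_real_)
  for (r in 1:10) {
    x <- sample_dataset(cfg, seed = 400 + r)
    des <- cia_design(x)
    fit <- fit_smcia(des, s = cfg$n_en * cfg$n_el)
    angles[r] <- mean(vapply(1:2, function(k)
      loading_angle(fit$axes[[1]]$a[[k]], tr[[k]]), numeric(1)))
  }
  expect_gte(mean(angles), 0.8)
})
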