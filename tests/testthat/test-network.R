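# Component counter used as an independent oracle for the Laplacian
# null-space multiplicity.
n_components <- function(graph) {
  p <- length(graph$node_ids)
  adj <- lapply(seq_len(p), function(i) integer(0))
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[e]; j <- graph$edges$to[e]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, p)
  comps <- 0
  for (start in seq_len(p)) {
    if (seen[start]) next
    comps <- comps + 1
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, adj[[v]][!seen[adj[[v]]]])
    }
  }
  comps
}

random_graph <- function(p, m, seed) {
  pairs <- utils::combn(p, 2)
  pick <- withr::with_seed(seed, sample(ncol(pairs), m))
  feature_graph(data.frame(from = pairs[1, pick], to = pairs[2, pick],
                           weight = withr::with_seed(seed + 1, runif(m, 0.5, 2))),
                paste0("f", seq_len(p)))
}

test_that("feature_graph validates its edge list", {
  ids <- c("a", "b", "c")
  g <- feature_graph(data.frame(from = "a", to = "b"), ids)
  expect_equal(g$edges$weight, 1)
  expect_error(feature_graph(data.frame(from = "a", to = "a"), ids), "self-loop")
  expect_error(feature_graph(data.frame(from = c("a", "b"), to = c("b", "a")),
                             ids), "duplicate")
  expect_error(feature_graph(data.frame(from = "a", to = "z"), ids), "endpoints")
  expect_error(feature_graph(data.frame(from = "a", to = "b", weight = -1),
                             ids), "positive")
})

test_that("the normalized Laplacian follows its defining entries", {
  g2 <- feature_graph(data.frame(from = 1, to = 2), c("x", "y"))
  expect_equal(unname(build_laplacian(g2)), rbind(c(1, -1), c(-1, 1)))

  # isolated third node: all-zero row and column
  g3 <- feature_graph(data.frame(from = 1, to = 2), c("x", "y", "z"))
  L3 <- build_laplacian(g3)
  expect_equal(unname(L3[3, ]), c(0, 0, 0))
  expect_equal(unname(L3[, 3]), c(0, 0, 0))
  expect_equal(diag(L3), c(x = 1, y = 1, z = 0))

  # 3-node star: D^{1/2} 1 spans the null space of the normalized Laplacian
  star <- feature_graph(data.frame(from = c(1, 1), to = c(2, 3)),
                        c("hub", "l1", "l2"))
  Ls <- build_laplacian(star, "normalized")
  u0 <- c(sqrt(2), 1, 1) / 2
  expect_equal(drop(crossprod(u0, Ls %*% u0)), 0, tolerance = 1e-12)
})

test_that("the combinatorial Laplacian is degree-minus-adjacency", {
  star <- feature_graph(data.frame(from = c(1, 1), to = c(2, 3)),
                        c("hub", "l1", "l2"))
  Lc <- build_laplacian(star, "combinatorial")
  expect_equal(unname(Lc), rbind(c(2, -1, -1), c(-1, 1, 0), c(-1, 0, 1)))
  # constant vectors are penalty-free
  expect_equal(penalty_value(rep(1, 3), Lc), 0, tolerance = 1e-12)
})

test_that("both variants are PSD with null multiplicity = component count", {
  for (seed in 1:6) {
    g <- random_graph(p = 9, m = 7, seed = seed)
    for (variant in c("normalized", "combinatorial")) {
      L <- build_laplacian(g, variant)
      ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8)
      expect_equal(sum(abs(ev) < 1e-8), n_components(g))
    }
  }
})

test_that("transform_laplacian is the change of metric it claims to be", {
  g <- random_graph(p = 6, m = 5, seed = 3)
  L <- build_laplacian(g)
  expect_equal(transform_laplacian(L, rep(1, 6)), L)
  q <- withr::with_seed(4, runif(6, 0.2, 2))
  Lt <- transform_laplacian(L, q)
  expect_equal(Lt, t(Lt))
  for (seed in 1:5) {
    u <- withr::with_seed(seed, rnorm(6))
    a <- sqrt(q) * u
    expect_equal(penalty_value(a, Lt), drop(crossprod(u, L %*% u)),
                 tolerance = 1e-12)
  }
  expect_error(transform_laplacian(L, c(1, 0, 1, 1, 1, 1)), "positive")
})

test_that("penalty_value evaluates the quadratic form", {
  path <- feature_graph(data.frame(from = c(1, 2), to = c(2, 3)),
                        c("a", "b", "c"))
  Lc <- build_laplacian(path, "combinatorial")
  expect_equal(penalty_value(c(1, 0, -1), Lc), 2)
  expect_equal(penalty_value(c(0, 0, 0), Lc), 0)
  expect_error(penalty_value(c(1, 0), Lc), "dimension")
})

test_that("penalty_value is invariant under node relabeling", {
  g <- random_graph(p = 7, m = 6, seed = 9)
  L <- build_laplacian(g)
  a <- withr::with_seed(10, rnorm(7))
  perm <- withr::with_seed(11, sample(7))
  gp <- feature_graph(data.frame(from = match(g$edges$from, perm),
                                 to = match(g$edges$to, perm),
                                 weight = g$edges$weight),
                      g$node_ids)
  Lp <- build_laplacian(gp)
  expect_equal(penalty_value(a[perm], Lp), penalty_value(a, L),
               tolerance = 1e-12)
})

test_that("perturb_graph rewires deterministically and without duplicates", {
  g <- random_graph(p = 10, m = 5, seed = 20)
  expect_identical(perturb_graph(g, 0), g)

  key <- function(gr) paste(gr$edges$from, gr$edges$to)
  full <- perturb_graph(g, 1, seed = 5)
  expect_equal(nrow(full$edges), 5)
  expect_false(anyDuplicated(key(full)) > 0)

  half_a <- perturb_graph(g, 0.5, seed = 7)
  expect_identical(half_a, perturb_graph(g, 0.5, seed = 7))
  expect_equal(nrow(half_a$edges), 5)
  # ceil(2.5) = 3 rewired, so at least the 2 kept edges survive
  expect_gte(length(intersect(key(half_a), key(g))), 2)
  expect_false(anyDuplicated(key(half_a)) > 0)
})

test_that("edge lists and SIF files are parsed and unknown nodes dropped", {
  ids <- c("g1", "g2", "g3")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2\t2.5", "g2\tg3\t1"), f)
  g <- read_edge_list(f, ids)
  expect_equal(g$edges$weight, c(2.5, 1))

  writeLines(c("g1\tpp\tg2", "g3\tpp\tg1"), f)
  gs <- read_edge_list(f, ids)
  expect_equal(nrow(gs$edges), 2)
  expect_true(all(gs$edges$weight == 1))

  writeLines(c("g1\tg2", "g1\tunknown"), f)
  expect_warning(g2 <- read_edge_list(f, ids), "absent")
  expect_equal(nrow(g2$edges), 1)
})
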