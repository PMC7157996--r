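#' Benchmark scenario configuration
#'
#' The built-in simulation grid crosses the latent-variable variance
#' \eqn{\sigma^2 \in \{1.2, 2.5\}}, the network size \eqn{n_{el} \in
#' \{10, 20\}} and the number of effective networks per block
#' \eqn{n_{en} \in \{(3,4,5), (5,5,5)\}} into eight scenarios on three
#' blocks of dimensions 300, 400 and 500 with n = 200 samples and five
#' star networks per block:
#'
#' | scenario | sigma2 | n_el | n_en    |
#' |----------|--------|------|---------|
#' | 1        | 1.2    | 10   | (3,4,5) |
#' | 2        | 1.2    | 20   | (3,4,5) |
#' | 3        | 2.5    | 10   | (3,4,5) |
#' | 4        | 2.5    | 20   | (3,4,5) |
#' | 5        | 1.2    | 10   | (5,5,5) |
#' | 6        | 1.2    | 20   | (5,5,5) |
#' | 7        | 2.5    | 10   | (5,5,5) |
#' | 8        | 2.5    | 20   | (5,5,5) |
#'
#' Every field can be overridden for custom (e.g. scaled-down) studies.
#'
#' @param scenario Integer 1-8 selecting a row of the grid, or `NULL`
#'   when all fields are supplied manually.
#' @param n,p,sigma2,n_el,n_en,n_networks,gamma_extra Overrides: sample
#'   count, block dimensions, latent variance, elements per network,
#'   effective networks per block, networks per block, and the spike
#'   added to the noise covariance (see [build_sigma_block()]).
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(scenario = NULL, n = 200, p = c(300, 400, 500),
                            sigma2 = 1.2, n_el = 10, n_en = c(3, 4, 5),
                            n_networks = 5, gamma_extra = 1) {
  if (!is.null(scenario)) {
    stopifnot(scenario %in% 1:8)
    sigma2 <- c(1.2, 1.2, 2.5, 2.5, 1.2, 1.2, 2.5, 2.5)[scenario]
    n_el <- c(10, 20, 10, 20, 10, 20, 10, 20)[scenario]
    n_en <- if (scenario <= 4) c(3, 4, 5) else c(5, 5, 5)
  }
  n_en <- rep_len(n_en, length(p))
  if (any(n_en > n_networks)) stop("n_en cannot exceed n_networks")
  if (any(n_networks * n_el > p)) {
    stop("n_networks * n_el must fit within every block dimension")
  }
  structure(list(scenario = scenario, n = n, p = p, sigma2 = sigma2,
                 n_el = n_el, n_en = n_en, n_networks = n_networks,
                 gamma_extra = gamma_extra),
            class = "scenario_config")
}

#' True loading vectors of a scenario
#'
#' Block k's true transformed loading is the indicator of its first
#' `n_en[k] * n_el` coordinates (the effective networks, each of `n_el`
#' consecutive features) scaled to unit l2 norm — constant within the
#' active networks, zero elsewhere.
#'
#' @param config A [scenario_config()].
#' @return List of K unit-norm numeric vectors.
#' @export
true_loadings <- function(config) {
  lapply(seq_along(config$p), function(k) {
    nnz <- config$n_en[k] * config$n_el
    a <- c(rep(1, nnz), rep(0, config$p[k] - nnz))
    a / sqrt(nnz)
  })
}

#' Spiked noise covariance with a prescribed leading eigenvector
#'
#' \eqn{\Sigma_k = I + \gamma\, a a^\top} for a unit vector `a`: leading
#' eigenpair \eqn{(1 + \gamma, a)}, all other eigenvalues 1.  This is the
#' simplest covariance whose first eigenvector is the true loading, which
#' the generative model requires; the spike height `gamma` (default 1)
#' controls how strongly the noise itself is aligned with the signal.
#'
#' @param a_true Unit-norm vector.
#' @param gamma_extra Positive spike height.
#' @return Symmetric positive-definite matrix.
#' @export
build_sigma_block <- function(a_true, gamma_extra = 1) {
  if (abs(sum(a_true^2) - 1) > 1e-8) stop("`a_true` must have unit norm")
  if (gamma_extra <= 0) stop("`gamma_extra` must be positive")
  diag(length(a_true)) + gamma_extra * tcrossprod(a_true)
}

#' Draw multi-block data from the latent-factor model
#'
#' Per sample, a latent score \eqn{\theta \sim N(0, \sigma^2)} drives all
#' blocks: \eqn{x_k = \theta a_k + \epsilon_k} with independent noise
#' \eqn{\epsilon_k \sim N(0, \Sigma_k)}, \eqn{\Sigma_k = I + \gamma a_k
#' a_k^\top}.  The concatenated vector is exactly N(0, \eqn{\Sigma_T})
#' with diagonal blocks \eqn{\sigma^2 a_k a_k^\top + \Sigma_k} and
#' off-diagonal blocks \eqn{\sigma^2 a_l a_m^\top}.  Noise is drawn
#' constructively (\eqn{\epsilon = z + (\sqrt{1+\gamma}-1) a (a^\top z)},
#' z standard normal), so cost scales with n * p, not p^2.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; draws are reproducible.
#' @param truth Optional list of true loadings (defaults to
#'   [true_loadings()] of the config).
#' @return Named list of K raw (uncentered) n-by-p_k matrices.
#' @export
sample_dataset <- function(config, seed = 1, truth = true_loadings(config)) {
  stopifnot(inherits(config, "scenario_config"))
  cfac <- sqrt(1 + config$gamma_extra) - 1
  withr::with_seed(seed, {
    theta <- stats::rnorm(config$n, sd = sqrt(config$sigma2))
    out <- lapply(seq_along(config$p), function(k) {
      p_k <- config$p[k]
      a <- truth[[k]]
      z <- matrix(stats::rnorm(config$n * p_k), config$n, p_k)
      eps <- z + cfac * tcrossprod(drop(z %*% a), a)
      X <- tcrossprod(theta, a) + eps
      dimnames(X) <- list(paste0("s", seq_len(config$n)),
                          paste0("b", k, "_f", seq_len(p_k)))
      X
    })
    names(out) <- paste0("block", seq_along(out))
    out
  })
}

#' Star feature networks of a scenario
#'
#' Each block carries `n_networks` star graphs on consecutive index
#' ranges of `n_el` features starting at coordinate 1; the first feature
#' of each range is the hub, connected to the other `n_el - 1` members
#' with unit edge weight.  Features beyond the networks are isolated.
#'
#' @param config A [scenario_config()].
#' @return List of K [feature_graph()]s.
#' @export
scenario_graphs <- function(config) {
  lapply(seq_along(config$p), function(k) {
    p_k <- config$p[k]
    ids <- paste0("b", k, "_f", seq_len(p_k))
    edges <- do.call(rbind, lapply(seq_len(config$n_networks), function(j) {
      hub <- (j - 1) * config$n_el + 1
      data.frame(from = hub, to = hub + seq_len(config$n_el - 1))
    }))
    feature_graph(edges, ids)
  })
}

#' Monte-Carlo benchmark of mCIA, smCIA and ssmCIA on a scenario
#'
#' For each replicate: draw a dataset from the latent-factor model,
#' standardize, build the default design (identity D, absolute-column-sum
#' Q, equal block weights), fit the requested methods, and score the
#' first-axis transformed loadings against the truth (angle; plus
#' sensitivity/specificity/MCC of support recovery for the sparse
#' methods; mCIA is non-sparse, so only its angle is meaningful).
#' Replicates use independent sub-seeds spawned from `seed`, so any
#' single replicate is reproducible on its own.
#'
#' @param config A [scenario_config()].
#' @param methods Subset of `c("mcia", "smcia", "ssmcia")`.
#' @param n_mc Number of Monte-Carlo replicates.
#' @param s Sparsity budgets for the sparse fits: `"oracle"` (true
#'   support sizes), a vector of budgets, or a [tune_smcia()]-style grid
#'   given as a list with entries `s_grid`, `lambda_grid`, `eta_grid`,
#'   `n_folds` (cross-validated per replicate, `shared` grids).
#' @param lambda Network penalty weight(s) for ssmCIA.  The default
#'   1e-3 makes the penalty term commensurate with the co-inertia term
#'   under the default column-sum feature metric, whose inverse square
#'   root inflates the transformed Laplacian by roughly a factor p; pass
#'   a vector to have it cross-validated when `s` is a tuning grid.
#' @param eta Rifle step size for fixed-parameter fits.
#' @param laplacian_variant Laplacian used for ssmCIA on the scenario
#'   graphs; the default `"combinatorial"` makes the scenario truths
#'   exactly penalty-free (constant on each star), which is the regime
#'   the benchmark is designed around.  See the vignette.
#' @param seed Master seed.
#' @return A tibble: one row per (method, block), columns `sens`, `spec`,
#'   `mcc`, `angle` means with standard errors (`*_se`) over replicates,
#'   plus `n_mc` and `failed` (replicates that errored).
#' @export
run_scenario <- function(config, methods = c("mcia", "smcia", "ssmcia"),
                         n_mc = 100, s = "oracle", lambda = 1e-3, eta = 0.5,
                         laplacian_variant = "combinatorial", seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  methods <- match.arg(methods, c("mcia", "smcia", "ssmcia"), several.ok = TRUE)
  truth <- true_loadings(config)
  graphs <- if ("ssmcia" %in% methods) scenario_graphs(config) else NULL
  oracle_s <- config$n_en * config$n_el
  K <- length(config$p)
  sub_seeds <- withr::with_seed(seed, sample.int(2^31 - 2, n_mc))

  rows <- list()
  failed <- 0L
  for (rep in seq_len(n_mc)) {
    res <- tryCatch(
      run_one_replicate(config, methods, truth, graphs, oracle_s, s, lambda,
                        eta, laplacian_variant, sub_seeds[rep]),
      error = function(e) {
        warning("replicate ", rep, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) { failed <- failed + 1L; next }
    res$replicate <- rep
    rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("all replicates failed")
  per_rep <- dplyr::bind_rows(rows)

  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- per_rep |>
    dplyr::group_by(.data$method, .data$block) |>
    dplyr::summarise(dplyr::across(c("sens", "spec", "mcc", "angle"),
                                   list(mean = ~ mean(.x), se = ~ se(.x)),
                                   .names = "{.col}_{.fn}"),
                     .groups = "drop") |>
    dplyr::rename(sens = "sens_mean", spec = "spec_mean", mcc = "mcc_mean",
                  angle = "angle_mean")
  out$n_mc <- n_mc - failed
  out$failed <- failed
  if (!is.null(config$scenario)) out$scenario <- config$scenario
  attr(out, "per_replicate") <- per_rep
  out
}

run_one_replicate <- function(config, methods, truth, graphs, oracle_s, s,
                              lambda, eta, laplacian_variant, sub_seed) {
  x <- sample_dataset(config, seed = sub_seed)
  design <- cia_design(x, center = TRUE, q = "colsum", d = "identity")
  K <- length(config$p)
  score_fit <- function(fit, method, sparse) {
    tibble::tibble(
      method = method,
      block = seq_len(K),
      sens = vapply(seq_len(K), function(k) {
        if (!sparse) return(NA_real_)
        selection_metrics(fit$axes[[1]]$a[[k]], truth[[k]])[["sens"]]
      }, numeric(1)),
      spec = vapply(seq_len(K), function(k) {
        if (!sparse) return(NA_real_)
        selection_metrics(fit$axes[[1]]$a[[k]], truth[[k]])[["spec"]]
      }, numeric(1)),
      mcc = vapply(seq_len(K), function(k) {
        if (!sparse) return(NA_real_)
        selection_metrics(fit$axes[[1]]$a[[k]], truth[[k]])[["mcc"]]
      }, numeric(1)),
      angle = vapply(seq_len(K), function(k) {
        loading_angle(fit$axes[[1]]$a[[k]], truth[[k]])
      }, numeric(1)))
  }

  pick_params <- function(lam_grid) {
    if (is.list(s)) {
      cv <- tune_smcia(design, s_grid = s$s_grid,
                       lambda_grid = lam_grid,
                       eta_grid = s$eta_grid %||% eta,
                       n_folds = s$n_folds %||% 5,
                       seed = sub_seed, graphs = graphs,
                       laplacian_variant = laplacian_variant, shared = TRUE)
      cv$best
    } else if (identical(s, "oracle")) {
      list(s = oracle_s, lambda = max(unlist(lam_grid)), eta = eta)
    } else {
      list(s = rep_len(s, K), lambda = max(unlist(lam_grid)), eta = eta)
    }
  }

  out <- list()
  for (m in methods) {
    fit <- switch(m,
      mcia = fit_mcia(design, n_axes = 1),
      smcia = {
        par <- pick_params(0)
        suppressWarnings(
          fit_smcia(design, s = par$s, eta = par$eta, n_axes = 1))
      },
      ssmcia = {
        par <- pick_params(lambda)
        suppressWarnings(
          fit_smcia(design, s = par$s, lambda = par$lambda, graphs = graphs,
                    eta = par$eta, n_axes = 1,
                    laplacian_variant = laplacian_variant))
      })
    out[[m]] <- score_fit(fit, m, sparse = m != "mcia")
  }
  dplyr::bind_rows(out)
}
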