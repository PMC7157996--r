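#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the loadings of a co-inertia fit
#'
#' @param x A `"cia_fit"`.
#' @param metric `"original"` for loadings u_k (the Q-metric coefficients
#'   applied to the data as given) or `"transformed"` for a_k (the
#'   Euclidean-metric vectors the sparsity budget applies to); the two
#'   share the same support.
#' @param ... Unused.
#' @return A tibble with columns `axis`, `block`, `feature`, `loading`.
#' @export
tidy.cia_fit <- function(x, metric = c("original", "transformed"), ...) {
  metric <- match.arg(metric)
  purrr::map_dfr(seq_along(x$axes), function(r) {
    ax <- x$axes[[r]]
    vecs <- if (metric == "original") ax$u else ax$a
    purrr::map_dfr(seq_along(vecs), function(k) {
      tibble::tibble(axis = r,
                     block = x$block_names[k],
                     feature = x$feature_ids[[k]],
                     loading = unname(vecs[[k]]))
    })
  })
}

#' One-row-per-axis summary of a co-inertia fit
#'
#' @param x A `"cia_fit"`.
#' @param ... Unused.
#' @return A tibble with `axis`, `pseudo_eigenvalue`, per-block nonzero
#'   counts (`nnz_*`), and for sparse fits the penalized objective and
#'   convergence flag.
#' @export
glance.cia_fit <- function(x, ...) {
  out <- purrr::map_dfr(seq_along(x$axes), function(r) {
    ax <- x$axes[[r]]
    nz <- vapply(ax$a, function(a) sum(a != 0), integer(1))
    row <- tibble::tibble(axis = r, method = x$method,
                          pseudo_eigenvalue = ax$pseudo_eigenvalue)
    for (k in seq_along(nz)) row[[paste0("nnz_", x$block_names[k])]] <- nz[k]
    if (!is.null(ax$penalized_objective)) {
      row$penalized_objective <- ax$penalized_objective
      row$converged <- ax$converged
    }
    row
  })
  out
}

#' Tidy the sample scores (synthetic centers) of a fit
#'
#' @param fit A `"cia_fit"`.
#' @return A tibble with `axis`, `sample`, `center` (the entries of v).
#' @export
sample_scores <- function(fit) {
  stopifnot(inherits(fit, "cia_fit"))
  purrr::map_dfr(seq_along(fit$axes), function(r) {
    tibble::tibble(axis = r, sample = fit$sample_ids,
                   center = unname(fit$axes[[r]]$v))
  })
}

#' Plot the loadings of a co-inertia fit
#'
#' Per-block needle plot of the loading coefficients of one or more axes;
#' for sparse fits most coefficients are exactly zero and the selected
#' features stand out.
#'
#' @param object A `"cia_fit"`.
#' @param axes Which axes to show (default all).
#' @param metric Passed to [tidy.cia_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cia_fit <- function(object, axes = NULL,
                             metric = c("original", "transformed"), ...) {
  metric <- match.arg(metric)
  df <- tidy(object, metric = metric)
  if (!is.null(axes)) df <- dplyr::filter(df, .data$axis %in% !!axes)
  df <- df |>
    dplyr::group_by(.data$axis, .data$block) |>
    dplyr::mutate(index = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$loading)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0),
                          linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$axis), ggplot2::vars(.data$block),
                        scales = "free_x") +
    ggplot2::labs(x = "feature index", y = paste0("loading (", metric, ")"),
                  title = paste0(object$method, " loadings")) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation surface
#'
#' Score of every tuning combination against its total sparsity budget,
#' colored by the network penalty weight and faceted by step size.
#'
#' @param object A `"cia_cv"` from [tune_smcia()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cia_cv <- function(object, ...) {
  tab <- object$table
  s_cols <- grep("^(s[0-9]+|frac)$", names(tab), value = TRUE)
  lam_cols <- grep("^lambda", names(tab), value = TRUE)
  tab$total_s <- if (identical(s_cols, "frac")) tab$frac else rowSums(tab[s_cols])
  tab$total_lambda <- if (length(lam_cols)) rowSums(tab[lam_cols]) else 0
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$total_s, y = .data$score,
                                    colour = factor(.data$total_lambda))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$eta), labeller = "label_both") +
    ggplot2::labs(x = "total sparsity budget", y = "CV score (mean/sd)",
                  colour = "total lambda") +
    ggplot2::theme_minimal()
}
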