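#' Weighted undirected feature graph
#'
#' A prior network among the features of one block: nodes are the block's
#' features, edges carry positive weights.  Self-loops and duplicate
#' undirected edges are rejected.
#'
#' @param edges Data frame (or tibble) with columns `from`, `to` and
#'   optionally `weight` (default 1).  `from`/`to` may be feature names
#'   (matched against `node_ids`) or integer indices.
#' @param node_ids Character vector of feature ids, length p; defines the
#'   node order used by [build_laplacian()].
#' @return A `"feature_graph"`: list with `node_ids` and an integer edge
#'   tibble (`from`, `to`, `weight`) with `from < to`.
#' @export
feature_graph <- function(edges, node_ids) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("`node_ids` must be unique")
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` needs columns `from` and `to`")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  idx <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    match(as.character(x), node_ids)
  }
  from <- idx(edges$from); to <- idx(edges$to)
  if (anyNA(from) || anyNA(to) ||
      any(from < 1 | from > length(node_ids) | to < 1 | to > length(node_ids))) {
    stop("edge endpoints outside the node set")
  }
  if (any(edges$weight <= 0)) stop("edge weights must be strictly positive")
  if (any(from == to)) stop("self-loops are not allowed")
  lo <- pmin(from, to); hi <- pmax(from, to)
  if (anyDuplicated(cbind(lo, hi))) stop("duplicate undirected edges")
  structure(
    list(node_ids = node_ids,
         edges = tibble::tibble(from = lo, to = hi,
                                weight = as.numeric(edges$weight))),
    class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat("<feature_graph> ", length(x$node_ids), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Read a feature graph from an edge-list file
#'
#' Accepts 2- or 3-column delimited text (`node_a node_b [weight]`) or SIF
#' (`node_a interaction node_b`, detected when the middle column is
#' non-numeric).  Edges whose endpoints are not in `node_ids` are dropped
#' with a warning; features without edges stay isolated.
#'
#' @param path File path.
#' @param node_ids Feature ids of the block the graph belongs to.
#' @param delim Field delimiter (default any whitespace/tab via
#'   [readr::read_table()] for `NULL`, otherwise passed to
#'   [readr::read_delim()]).
#' @return A [feature_graph()].
#' @export
read_edge_list <- function(path, node_ids, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           show_col_types = FALSE, trim_ws = TRUE,
                           col_types = readr::cols(.default = "c"))
  if (ncol(raw) < 2) stop("edge list needs at least two columns")
  if (ncol(raw) >= 3 && any(is.na(suppressWarnings(as.numeric(raw[[3]]))))) {
    # SIF: node_a interaction node_b
    df <- tibble::tibble(from = raw[[1]], to = raw[[3]], weight = 1)
  } else if (ncol(raw) >= 3) {
    df <- tibble::tibble(from = raw[[1]], to = raw[[2]],
                         weight = as.numeric(raw[[3]]))
  } else {
    df <- tibble::tibble(from = raw[[1]], to = raw[[2]], weight = 1)
  }
  known <- df$from %in% node_ids & df$to %in% node_ids
  if (any(!known)) {
    warning(sum(!known), " edge(s) reference features absent from the block; dropped")
    df <- df[known, ]
  }
  feature_graph(df, node_ids)
}

#' Graph Laplacian of a feature network
#'
#' The `"normalized"` variant (default) has entries
#' \eqn{1 - w(i,j)/d_i} on the diagonal for connected nodes (0 for
#' isolated nodes, whose rows and columns are all zero),
#' \eqn{-w(i,j)/\sqrt{d_i d_j}} for adjacent pairs, and 0 otherwise,
#' where \eqn{d_i} is the weighted degree.  The `"combinatorial"` variant
#' is \eqn{\mathrm{diag}(d) - W}; its null space is spanned by the
#' component-wise constant vectors, so loadings that are constant within
#' each network component incur zero penalty.  Both are symmetric positive
#' semi-definite.
#'
#' @param graph A [feature_graph()].
#' @param variant `"normalized"` or `"combinatorial"`.
#' @return Symmetric p-by-p matrix with dimnames from the node ids.
#' @export
build_laplacian <- function(graph, variant = c("normalized", "combinatorial")) {
  stopifnot(inherits(graph, "feature_graph"))
  variant <- match.arg(variant)
  p <- length(graph$node_ids)
  W <- matrix(0, p, p, dimnames = list(graph$node_ids, graph$node_ids))
  e <- graph$edges
  W[cbind(e$from, e$to)] <- e$weight
  W[cbind(e$to, e$from)] <- e$weight
  d <- rowSums(W)
  if (variant == "combinatorial") {
    L <- diag(d, p) - W
  } else {
    rd <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- -W * tcrossprod(rd)
    diag(L) <- as.numeric(d > 0)   # no self-loops, so 1 - w(i,i)/d_i = 1
  }
  dimnames(L) <- list(graph$node_ids, graph$node_ids)
  L
}

#' Transform a Laplacian into the Euclidean working metric
#'
#' \eqn{\tilde L = Q^{-1/2} L Q^{-1/2}} with the diagonal feature metric
#' `q`, so that \eqn{a^\top \tilde L a = u^\top L u} when
#' \eqn{a = Q^{1/2} u}: the penalty evaluated on transformed loadings
#' equals the penalty on the original loadings.
#'
#' @param L Symmetric Laplacian matrix.
#' @param q Strictly positive feature weights (diagonal of Q).
#' @return The transformed symmetric matrix.
#' @export
transform_laplacian <- function(L, q) {
  q <- as.numeric(q)
  if (length(q) != nrow(L)) stop("`q` must have length nrow(L)")
  if (any(q <= 0)) stop("feature weights must be strictly positive")
  rq <- 1 / sqrt(q)
  Lt <- L * tcrossprod(rq)
  (Lt + t(Lt)) / 2
}

#' Quadratic network penalty of a loading vector
#'
#' Evaluates \eqn{a^\top \tilde L a}: zero exactly when the loading (in
#' the original metric) lies in the Laplacian's null space, i.e. agrees
#' with the encoded network structure.
#'
#' @param a Numeric loading vector.
#' @param Lt (Transformed) Laplacian matrix.
#' @return Nonnegative scalar (up to roundoff).
#' @export
penalty_value <- function(a, Lt) {
  a <- as.numeric(a)
  if (length(a) != nrow(Lt)) stop("dimension mismatch between `a` and `Lt`")
  sum(a * as.numeric(Lt %*% a))
}

#' Randomly rewire a fraction of a graph's edges
#'
#' Removes `ceiling(rewire_fraction * |E|)` randomly chosen edges and adds
#' the same number of uniformly random new edges (unit weight, no
#' self-loops, no duplicates of surviving or newly added edges; a removed
#' pair may be drawn again).  Used to
#' study robustness of the network penalty to partially incorrect prior
#' networks.  Deterministic given `seed`.
#'
#' @param graph A [feature_graph()].
#' @param rewire_fraction Fraction of edges to rewire, in \[0, 1\].
#' @param seed Integer seed.
#' @return A [feature_graph()] with the same node set.
#' @export
perturb_graph <- function(graph, rewire_fraction, seed = 1) {
  stopifnot(inherits(graph, "feature_graph"))
  if (rewire_fraction < 0 || rewire_fraction > 1) {
    stop("`rewire_fraction` must be in [0, 1]")
  }
  m <- nrow(graph$edges)
  n_rewire <- ceiling(rewire_fraction * m)
  if (n_rewire == 0) return(graph)
  p <- length(graph$node_ids)
  withr::with_seed(seed, {
    drop_idx <- sample.int(m, n_rewire)
    kept <- graph$edges[-drop_idx, ]
    key <- function(i, j) pmin(i, j) * (p + 1) + pmax(i, j)
    occupied <- key(kept$from, kept$to)
    max_edges <- p * (p - 1) / 2
    if (max_edges - nrow(kept) < n_rewire) {
      stop("not enough free node pairs to add ", n_rewire, " new edges")
    }
    new_from <- integer(0); new_to <- integer(0)
    while (length(new_from) < n_rewire) {
      i <- sample.int(p, 1); j <- sample.int(p, 1)
      if (i == j) next
      k <- key(i, j)
      if (k %in% occupied) next
      occupied <- c(occupied, k)
      new_from <- c(new_from, min(i, j)); new_to <- c(new_to, max(i, j))
    }
    feature_graph(
      tibble::tibble(from = c(kept$from, new_from),
                     to = c(kept$to, new_to),
                     weight = c(kept$weight, rep(1, n_rewire))),
      graph$node_ids)
  })
}
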